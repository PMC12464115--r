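# pavbias

Simulation and model-based analysis of **intertemporal Pavlovian biases** in
go/no-go learning tasks.

## The problem

Cues that predict rewards pull behaviour toward approach, whether or not
approach is the instrumentally correct response. In the intertemporal
go/no-go paradigm, the required action (press within 600 ms / withhold) is
crossed with the *timing* of the reward a correct response earns — an
immediate amount today versus a fixed EUR 28 in 120 days, preference-matched
per participant by an adaptive choice-titration staircase. Extra
go-responding on immediate-reward cues, beyond what instrumental learning
explains, is a Pavlovian bias driven by reward timing: a candidate
mechanism behind intertemporal impatience and its links to mental health.

`pavbias` is for researchers who want to run, validate, or extend this
analysis chain on simulated or real trial data:

- **Task design** — pseudorandom schedules (4 conditions x 50 trials, no
  condition more than twice in a row, 80% valid feedback) and probabilistic
  feedback resolution.
- **Titration** — monetary-choice-questionnaire scoring to a hyperbolic
  discount rate, staircase with stability and exclusion rules, impatience
  score.
- **RL models** — six nested Rescorla-Wagner models M0-M5 with inverse
  temperature `tau`, irreducible noise `xi`, go bias `b`, cue-response bias
  `pi`, and an outcome-contingent learning-rate pair `alpha0/alpha1`, as
  both likelihood evaluators and generative agents.
- **MAP fitting** — per-participant posterior modes under Gamma(3, 0.3) /
  Gaussian(0, 1) priors via box-constrained differential evolution; AIC and
  model-frequency comparison.
- **Validation** — parameter recovery, model-recovery confusion matrices,
  posterior predictive checks.
- **Statistics** — hierarchical logistic response-bias and shifted-lognormal
  RT models with sum-to-zero coding, mental-health moderation scans with
  Benjamini-Hochberg control, Pearson correlation tables.
- **Synthetic cohorts** — full study datasets with known ground truth,
  plus a direct generator for power analysis (`power_scan()`).

The core model (M3) gives the go action weight of cue $s$ value
$w_\text{go} = Q(\text{go}, s) + b + \pi V(s)$ with $V = +1$ for
immediate-reward and $-1$ for delayed-reward cues, and chooses with
$p(\text{go}) = \text{softmax}(\tau w)_\text{go}(1 - \xi) + \xi/2$.

## Worked example

Simulate one agent at reference cohort-scale parameters and fit it:

```r
library(pavbias)

sched   <- generate_schedule(n_per_condition = 50, max_run = 2,
                             feedback_validity = 0.8, seed = 11)
true    <- c(alpha = 0.21, tau = 7.33, xi = 0.17, b = 0.09, pi = 0.05)
session <- simulate_agent(true, model_spec("M3"), sched, seed = 12)
gng_fit(session, model = "M3", seed = 13)
#> MAP fit of model M3 (200 trials)
#>  alpha    tau     xi      b     pi
#>  0.155 10.112  0.113  0.147  0.043
#> logLik -54.30, log-posterior -58.86, AIC 118.59
```

The fitted values are MAP estimates from a single 200-trial session: the
cue-response bias `pi = 0.043` is close to its generating value, while
`tau` is pulled toward the Gamma prior's mode — expected behaviour at this
session length (see the vignette on identifiability).

Generate a 20-agent cohort with a clearly expressed bias (`pi` location
0.4, other parameters at the reference scales), then test for the bias and
compare models:

```r
cfg    <- cohort_config(n_participants = 20,
                        param_mean = c(alpha = 0.21, tau = 7.33, xi = 0.17,
                                       b = 0.09, pi = 0.4))
cohort <- generate_cohort(cfg, seed = 21)
cohort
#> Synthetic go/no-go cohort: 20 participants, 200 trials each (model M3)
#>   overall go rate 0.543; titration converged for 20/20

tab <- fit_response_bias(build_design(cohort$trials))
tab[tab$effect %in% c("action_code", "reward_code"),
    c("effect", "estimate", "lower", "upper", "significant")]
#>       effect estimate lower upper significant
#>  action_code    0.969 0.716 1.222        TRUE
#>  reward_code    0.753 0.393 1.112        TRUE

fits <- fit_cohort(cohort, models = c("M2", "M3"), seed = 31)
tapply(fits$aic, fits$model, median)
#>     M2     M3
#> 215.94 196.76
model_frequency(fits)
#>   M2   M3
#> 0.05 0.95
```

`action_code = 0.97` says agents respond go far more on go-required trials
(they learned the task); `reward_code = 0.75` with an interval excluding 0
is the Pavlovian response bias on the log-odds scale (+1 immediate / -1
delayed coding). The cue-response-bias model M3 beats its nested parent M2
by median AIC and wins for 19 of 20 agents.

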