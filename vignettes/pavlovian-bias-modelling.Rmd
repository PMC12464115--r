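---
title: "Modelling intertemporal Pavlovian biases in go/no-go learning"
author: "pavbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intertemporal Pavlovian biases in go/no-go learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavbias)
```

## The scientific problem

Anticipated rewards shape instrumental behaviour in two distinct ways. The
instrumental route learns cue-action-outcome contingencies; the Pavlovian
route attaches approach tendencies directly to reward-predicting cues,
regardless of whether approach is instrumentally useful. In an intertemporal
go/no-go task, the cue signals *when* the reward would arrive — today
(immediate) or months from now (delayed) — while the required action (press
or withhold) must be learned from trial and error under probabilistic
feedback. Because the immediate and delayed rewards are preference-matched
per participant through a choice-titration staircase, any extra go-responding
toward immediate-reward cues isolates a *Pavlovian bias driven by reward
timing* rather than by subjective reward value.

`pavbias` implements this full analysis chain — task simulation, titration,
a nested family of reinforcement-learning (RL) models fit by per-participant
MAP, model comparison and validation, and the hierarchical statistical layer
— together with a synthetic-cohort generator with known ground truth, so
every inferential step can be exercised and calibrated end to end.

## The task and its schedule

Four cue conditions cross required action (go/no-go) with reward timing
(immediate/delayed). Each condition appears 50 times in pseudorandom order
with no condition more than twice in a row, split into four contiguous
blocks of 50 trials; feedback is congruent with response correctness on 80%
of trials, independently per trial. `generate_schedule()` draws sequences by
rejection sampling — uniform shuffles of the condition multiset, rejecting
run-limit violations — which is exactly uniform over admissible sequences at
study-scale session lengths. For much longer sessions the acceptance
probability of a whole shuffle vanishes, so sequences beyond 400 trials fall
back to sequential count-weighted sampling with restart; this preserves all
invariants (exact counts, run limit) at the cost of exact uniformity over
admissible orders, which none of the downstream analyses depend on.
Feedback validity is drawn independently per trial rather than balanced per
condition; with 50 trials per condition the realized congruence rate is
within a few percent of its target, and the independent-draw convention is
the natural reading of "valid on 80% of trials".

## Choice titration and the impatience score

The staircase offers an immediate amount (an even number of euros between 0
and 28) against a fixed delayed reward of EUR 28 in 120 days. An immediate
choice lowers the next offer by EUR 2, a delayed choice raises it, clipped
to the range. The procedure stops once six consecutive offers span at most
EUR 2 — the matched amount is the rounded mean of that window, a summary the
original procedure leaves unspecified — or unconverged after 50 trials.
Accepting EUR 0 triggers one confirmation trial (counted toward the 50); a
repeated EUR 0 preference is an exclusion, since it undermines the premise
that the task rewards are rewarding. The staircase's starting offer is the
hyperbolic present value 28/(1 + 120k) of the delayed reward, rounded to the
nearest even integer (exact ties round down), where k is scored from the
standard 27-item monetary choice questionnaire by consistency maximisation:
each item implies an indifference rate, the nine rate levels tile the axis
into ten regions, and the scored k is the candidate (geometric midpoints of
adjacent levels, geometrically extended endpoints) most consistent with the
observed choices, ties broken by geometric mean. The impatience score
reverse-codes the matched amount as `29 - X`, mapping the 1-28 range onto
1-28 with higher values indicating more impatience.

## The RL model family

All six models share the Rescorla-Wagner value update for the taken action
$a_t$ at the presented cue $s_t$,

$$Q_t(a_t, s_t) = Q_{t-1}(a_t, s_t) + \alpha\,(r_{t-1} - Q_{t-1}(a_t, s_t)),$$

with reward coded $r \in \{0, 1\}$ and values tracked separately for each of
the four cues. Action weights $w$ enter a softmax with inverse temperature
$\tau$; the go probability of the full model is

$$p(\text{go}) = \frac{e^{\tau w_\text{go}}}{e^{\tau w_\text{go}} +
e^{\tau w_\text{nogo}}}\,(1 - \xi) + \frac{\xi}{2},$$

where $\xi$ is irreducible noise (attentional or motor lapses) bounding
$p$ inside $[\xi/2,\, 1 - \xi/2]$. The nested family is:

| model | added mechanism | free parameters |
|---|---|---|
| M0 | value-driven choice only | $\alpha, \tau$ |
| M1 | irreducible noise $\xi$ | 3 |
| M2 | go bias $b$ (constant go-weight increment) | 4 |
| M3 | cue-response bias $\pi$: go weight gains $\pi V(s)$, $V = +1$ immediate, $-1$ delayed | 5 |
| M4 | learning bias $\alpha_0/\alpha_1$ instead of $\pi$ | 5 |
| M5 | both $\pi$ and $\alpha_0/\alpha_1$ | 6 |

The learning bias applies the faster rate $\alpha_0$ when a go response
obtained an immediate reward or a no-go response obtained a delayed reward,
and $\alpha_1$ otherwise — including every no-reward outcome, which is the
literal reading of the defining case split (the alternative, classifying
no-reward trials by the cue's reward identity, would make the "else" branch
nearly empty on no-go-heavy sessions). M4 retains the go bias of M2, so the
family is strictly nested: at $\pi = 0$, M3 and M5 collapse onto M2 and M4;
at $\alpha_0 = \alpha_1$, M4 and M5 collapse onto M2 and M3. These
identities hold to machine precision in the implementation and are enforced
by tests, as is the property that response-sequence probabilities sum to one
on exhaustively enumerable short schedules.

Numerical choices: action values start at 0 for every cue-action pair (the
initial trial of each cue is then an even-odds choice before biases); the
softmax subtracts the maximum scaled weight before exponentiating, so
$\tau = 50$ with saturated values cannot overflow; and the per-trial choice
probability is floored at $10^{-12}$ inside the log — reachable only when
$\xi = 0$, since any positive lapse rate already bounds probabilities away
from zero.

## MAP estimation and model comparison

Each model is fitted per participant by maximising the log posterior: the
session log-likelihood plus log priors — Gamma(shape 3, rate 0.3) on $\tau$
(mean 10, weakly regularising against the flat ridge at large $\tau$),
Gaussian(0, 1) on $b$ and $\pi$, and implicit uniforms over the unit boxes
of $\alpha$ and $\xi$. The rate parameterisation of the Gamma prior is the
one consistent with $\tau$ bounded at 50 and cohort-level estimates near 7;
a scale parameterisation would put the prior mean at 1000, outside the box.
Optimization uses the package's own box-constrained differential evolution
(rand/1/bin; population 10 x dimension, up to 250 generations, stopping
after 50 stalled generations, mutation weight 0.8, crossover 0.9, reflection
at the box), with the likelihood evaluated population-wise in compiled code.
On spot checks the DE mode coincides exactly with a 200-start L-BFGS-B
search of the same objective. Fits are deterministic given a seed.

Models are compared by AIC ($2k - 2\log L$, computed from the pure
likelihood at the posterior mode, since AIC is defined on likelihoods) and
by model frequency — the proportion of participants for whom a model attains
the lowest AIC, with exact ties split equally.

## Validation battery

`parameter_recovery()` draws true parameters, simulates sessions, refits,
and reports per-parameter correlation, bias, and RMSE. The generative ranges
default to moderate, study-realistic intervals ($\alpha \in [0.05, 0.5]$,
$\tau \in [1, 15]$, $\xi \in [0, 0.4]$, $b, \pi \in [-1, 1]$). Drawing
instead from lightly shrunken versions of the full constraint boxes was
evaluated and rejected: lapse rates up to 0.9 make most sessions pure noise
and recovery collapses for every parameter, which measures the generative
design rather than the estimator. Even under the realistic ranges, $\tau$
recovery at the 200-trial session length is intrinsically marginal (around
r = 0.45 at 50 agents, against an acceptance threshold of 0.5 that the other
parameters clear comfortably): for high-lapse agents the likelihood is
nearly flat in $\tau$ and the posterior mode falls to the Gamma prior's
mode, compressing estimates toward a constant. This is a property of the
estimation problem — weak identifiability of the softmax temperature in
lapse models at this trial count — not of the optimizer, and it is reported
rather than hidden by widening the generative spread of $\tau$.

`model_recovery()` simulates from each model, fits all, and tabulates the
row-normalised confusion matrix of AIC winners. `posterior_predictive()`
simulates replicate sessions at fitted parameters and reports per-condition
binned go-rate trajectories with two bands: the predictive quantile band
(used for the coverage check — the observed single-session trajectory should
fall inside it at roughly the nominal rate when the model is right) and the
Monte-Carlo uncertainty of the simulated mean (which shrinks as replicate
simulations grow). The two answer different questions and the report carries
both.

## The statistical layer

The response-bias model is a hierarchical logistic regression of the go
response on sum-to-zero coded required action (+1 go), reward timing (+1
immediate), centred block (-1.5 ... +1.5), and all interactions, with
by-participant random effects. The reported scale follows the +1/-1 coding:
a reward coefficient of 0.19 means immediate-reward trials sit 0.19 log-odds
above the grand mean. Trials are aggregated to binomial counts per
covariate cell before fitting, which leaves the likelihood unchanged and
makes the mixed-model fits fast enough for replicate-based calibration.

Estimation uses maximum likelihood (`lme4`), and the effect-table surface
reports Wald 95% intervals and two-sided normal tail probabilities in place
of posterior highest-density intervals and tail probabilities; at the
cohort sizes involved the Gaussian approximation to the fixed-effect
posterior under weak priors is excellent, and the package's calibration
tests check exactly this surface (planted effects covered, null
false-positive rates near nominal). The default random-effects structure is
the reduced one (intercept plus main-effect slopes); the maximal structure
(all interaction slopes) is available behind the `re` argument, and an
intercept-plus-reward-slope structure (`re = "reward"`) is the minimal one
that still gives valid reward-effect inference when reward-effect
heterogeneity is present. Calibration measurements during development made
the importance of the slope explicit: with an intercept-only structure and
heterogeneous true reward effects, the reward-by-covariate interaction test
produced about half the covariates as false positives under the null,
against approximately nominal rates with random slopes.

Response times of go responses are modelled as shifted lognormal:
`log(rt - shift)` is regressed on the same fixed-effect structure with
participant random effects, and the global onset shift is estimated by
profiling the exact likelihood — including the transformation Jacobian
`-sum(log(rt - shift))`, without which profile comparisons across shifts
would be meaningless — over a grid below the smallest observed RT. A single
global shift (rather than per-participant shifts) keeps the model
identifiable at desk-scale cohorts. Adding a constant to every RT moves the
estimated shift, not the slopes.

Mental-health moderation fits one model per covariate (the covariate
mean-centred, interacting with all task fixed effects); the primary test is
the reward-by-covariate interaction. The correction across covariates
operationalises "multiplicity-corrected intervals" as: Benjamini-Hochberg
on the two-sided tail probabilities across covariates at FDR q, then
intervals for the selected effects re-widened to the false-coverage level
`1 - kq/m` (k selected of m), the standard selection-adjusted coverage
companion of BH. With a single covariate this reduces exactly to the
unadjusted 95% rule. Pearson correlations of per-participant quantities
(impatience score, fitted model parameters) with covariates use the same BH
control.

## The synthetic cohort generator

`cohort_config()` defines the study conditions the generator emulates.
Per-agent RL parameters are truncated-normal draws centred on the cohort
summary estimates of the winning cue-response-bias model
($\alpha$ 0.21, $\tau$ 7.33, $\xi$ 0.17, $b$ 0.09, $\pi$ 0.05); the
dispersions (0.15, 2.9, 0.15, 0.30, 0.30) are the cohort-level standard
deviations implied by the reported interval half-widths at the study's
sample size. Discount rates are lognormal with median 0.008/day, which puts
the typical matched amount in the mid-teens of euros, matching the reported
cohort mean; questionnaire and staircase choices are logistic in the
present-value difference with a half-euro temperature (noiseless agents are
available for exact staircase tests). Go-response times are shifted
lognormal (onset 150 ms, median body 180 ms, log-sd 0.25) truncated into
the 600 ms response window, with log-scale condition effects expressed
directly in the design codes of the statistical layer. Symptom-like
covariates are gamma-quantile transforms of Gaussian latents correlated
with the agent's true $\pi$ at a configurable level — the monotone transform
approximately preserves the Pearson correlation and reproduces the
floor-heavy marginals of general-population symptom scores.

What the generator does *not* emulate: questionnaire item-level structure,
attention checks and practice rounds, within-session drift or fatigue, RT
autocorrelation, dropout, and the deposited dataset's exact covariance
structure between symptom scales. Passing calibration on these synthetic
cohorts therefore demonstrates that the pipeline recovers what it assumes,
not that those assumptions exhaust real data.

A separate direct generator, `simulate_bias_cohort()`, draws responses
straight from the hierarchical logistic model (no learning), which is the
appropriate generative counterpart for power analysis of the statistical
test itself. Its defaults reproduce the study's reported aggregates (overall
go log-odds 0.33, action effect 1.3) and its reward-effect heterogeneity
(sd 0.95) is calibrated so that the design's own power statement — 90-95%
power for a reward effect of 0.17 at 389 participants — is reproduced by
simulation; `power_scan()` then measures power at any effect size and
cohort-size grid.

## Problem sizes and reproducibility

Desk-scale defaults are used throughout the tests and the acceptance
script: cohorts of 60 agents for the end-to-end pipeline, 50 agents for
recovery at the 200-trial session length, six agents per generating model
for the confusion matrix, and 12-24 replicates for calibration and power
estimates; these sizes are the package's own choices balancing Monte-Carlo
error against iteration speed, and every number reported by the acceptance
script is recomputed from scratch at run time. All stochastic steps are
seeded, and identical seeds reproduce identical schedules, sessions, fits,
and reports.

## Known limitations

- $\tau$ recovery at the study's session length is marginal (discussed
  above); inferences about individual softmax temperatures at T = 200
  should be treated with caution even though cohort-level estimates are
  stable.
- The statistical layer is maximum-likelihood with Wald summaries, not full
  posterior inference; with very small cohorts (tens of participants) the
  Wald intervals for variance-component-adjacent effects can be slightly
  liberal.
- The RT model estimates one global onset shift; per-participant shifts
  would require richer data than the desk-scale cohorts provide.
- Joint response-RT modelling (sequential-sampling likelihoods with
  learning) is out of scope.
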