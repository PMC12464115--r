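#' Configuration of a synthetic study cohort
#'
#' Defines the generative study conditions: cohort size, the task schedule
#' (4 conditions x `n_per_condition` trials, run limit 2, 80% valid
#' feedback), per-agent reinforcement-learning parameters drawn from
#' truncated normals centred on the cohort summary estimates of the winning
#' cue-response bias model (alpha 0.21, tau 7.33, xi 0.17, b 0.09, pi 0.05),
#' a lognormal hyperbolic discount-rate distribution, a shifted-lognormal
#' response-time model bounded by the 600 ms response window, and
#' mental-health covariates with configurable marginals and a configurable
#' correlation with the true cue-response bias.
#'
#' @param n_participants Number of agents.
#' @param model Generating RL model id (default `"M3"`).
#' @param param_mean,param_sd Named location/scale vectors for the truncated
#'   normal parameter draws (defaults on reference cohort scales; scales
#'   chosen as cohort-level dispersions, see the package vignette).
#' @param n_per_condition,max_run,feedback_validity Schedule settings.
#' @param k_meanlog,k_sdlog Lognormal discount-rate hyperparameters (1/day).
#' @param mcq_temperature,titration_temperature Logistic choice noise (euros)
#'   for the simulated questionnaire and staircase choices; 0 = noiseless.
#' @param rt Response-time model: `shift` (ms), `meanlog`, `sdlog` on the log
#'   scale, and additive log-scale effects of the reward code (+1 immediate),
#'   action code (+1 go trial), their interaction, and centred block.
#' @param mh Mental-health covariates: `names`, per-covariate `cor_pi`
#'   (target correlation with true pi), `dist` (`"normal"` or `"skew"`),
#'   `mean`, `sd`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 60,
                          model = "M3",
                          param_mean = c(alpha = 0.21, tau = 7.33, xi = 0.17,
                                         b = 0.09, pi = 0.05),
                          param_sd = c(alpha = 0.15, tau = 2.9, xi = 0.15,
                                       b = 0.30, pi = 0.30),
                          n_per_condition = 50, max_run = 2,
                          feedback_validity = 0.8,
                          k_meanlog = log(0.008), k_sdlog = 1.0,
                          mcq_temperature = 0.5, titration_temperature = 0.5,
                          rt = list(shift = 150, meanlog = log(180),
                                    sdlog = 0.25, eff_reward = -0.02,
                                    eff_action = 0.03, eff_interaction = 0,
                                    eff_block = -0.01),
                          mh = list(names = "symptom_score",
                                    cor_pi = 0,
                                    dist = "skew", mean = 5, sd = 5)) {
  spec <- model_spec(model)
  missing <- setdiff(spec$par_names, names(param_mean))
  if (length(missing))
    stop("invalid configuration: param_mean lacks ", paste(missing, collapse = ", "))
  if (any(abs(rep(mh$cor_pi, length.out = length(mh$names))) > 1))
    stop("invalid configuration: correlations must lie in [-1, 1]")
  structure(list(n_participants = n_participants, model = model,
                 param_mean = param_mean, param_sd = param_sd,
                 n_per_condition = n_per_condition, max_run = max_run,
                 feedback_validity = feedback_validity,
                 k_meanlog = k_meanlog, k_sdlog = k_sdlog,
                 mcq_temperature = mcq_temperature,
                 titration_temperature = titration_temperature,
                 rt = rt, mh = mh),
            class = "cohort_config")
}

# truncated-normal draw by rejection with an inverse-cdf fallback
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  for (tries in 1:50) {
    if (!length(bad)) break
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  if (length(bad)) {
    u <- runif(length(bad), pnorm(lower, mean, sd), pnorm(upper, mean, sd))
    out[bad] <- qnorm(u, mean, sd)
  }
  out
}

#' Draw true RL parameters for a cohort
#'
#' Truncated-normal draws inside each parameter's box, centred on the
#' configured locations.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Data frame of true parameters, one row per participant.
#' @export
sample_params <- function(config, seed = 1L) {
  spec <- model_spec(config$model)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n <- config$n_participants
  out <- data.frame(participant_id = sprintf("p%03d", seq_len(n)))
  for (j in seq_along(spec$par_names)) {
    pn <- spec$par_names[j]
    out[[pn]] <- rtruncnorm(n, config$param_mean[[pn]], config$param_sd[[pn]],
                            spec$lower[j], spec$upper[j])
  }
  out
}

#' Draw mental-health covariates with a configured link to the true bias
#'
#' Each covariate is built from a Gaussian latent correlated with the
#' standardized true cue-response bias at the configured level, then mapped
#' to its marginal: `"normal"` (location-scale) or `"skew"` (gamma quantile
#' transform, emulating the floor-heavy symptom-score distributions of
#' general-population samples; the monotone map approximately preserves the
#' configured correlation).
#'
#' @param config A [cohort_config()].
#' @param true_pi Numeric vector of true cue-response bias values.
#' @param seed Integer seed.
#' @return Data frame: `participant_id` and one column per covariate.
#' @export
sample_mh <- function(config, true_pi, seed = 1L) {
  mh <- config$mh
  n <- length(true_pi)
  k <- length(mh$names)
  cor_pi <- rep(mh$cor_pi, length.out = k)
  dist <- rep(mh$dist, length.out = k)
  mean_ <- rep(mh$mean, length.out = k)
  sd_ <- rep(mh$sd, length.out = k)
  if (any(sd_ <= 0)) stop("invalid configuration: constant covariate requested")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  zpi <- as.numeric(scale(true_pi))
  if (any(!is.finite(zpi)))
    stop("invalid configuration: true pi has zero variance; cannot target a correlation")
  out <- data.frame(participant_id = sprintf("p%03d", seq_len(n)))
  for (j in seq_len(k)) {
    r <- cor_pi[j]
    z <- r * zpi + sqrt(1 - r^2) * rnorm(n)
    out[[mh$names[j]]] <- switch(
      dist[j],
      normal = mean_[j] + sd_[j] * z,
      skew = {
        shape <- (mean_[j] / sd_[j])^2        # gamma with target mean/sd
        qgamma(pnorm(z), shape = shape, rate = shape / mean_[j])
      },
      stop("invalid configuration: unknown marginal ", dist[j]))
  }
  out
}

#' Draw go-response times from the shifted-lognormal task model
#'
#' `rt = shift + lognormal(meanlog + effects, sdlog)`, resampled into the
#' response window `(shift, window]`. Log-scale effects follow the
#' sum-to-zero design codes of the statistical layer: reward (+1 immediate),
#' action (+1 go trial), their product, and centred block.
#'
#' @param reward_code,action_code,block_c Numeric design codes (vectorized).
#' @param rt_config The `rt` component of a [cohort_config()].
#' @param window Response window in ms (default 600).
#' @return Vector of response times in ms.
#' @export
sample_rt <- function(reward_code, action_code, block_c, rt_config,
                      window = 600) {
  n <- length(reward_code)
  mu <- rt_config$meanlog +
    rt_config$eff_reward * reward_code +
    rt_config$eff_action * action_code +
    rt_config$eff_interaction * reward_code * action_code +
    rt_config$eff_block * block_c
  if (rt_config$sdlog == 0) {
    rt <- rt_config$shift + exp(mu)
    if (any(rt > window))
      stop("invalid configuration: degenerate RT exceeds the response window")
    return(rt)
  }
  rt <- rt_config$shift + exp(rnorm(n, mu, rt_config$sdlog))
  bad <- which(rt > window)
  for (tries in 1:1000) {
    if (!length(bad)) break
    rt[bad] <- rt_config$shift + exp(rnorm(length(bad), mu[bad], rt_config$sdlog))
    bad <- which(rt > window)
  }
  if (length(bad)) stop("invalid configuration: RT truncation not feasible")
  rt
}

#' Generate a complete synthetic study cohort
#'
#' For each agent: a hyperbolic discount rate is drawn; monetary-choice
#' questionnaire responses are simulated and scored to seed the adaptive
#' choice titrator, which is run with a logistic-choice discounting agent;
#' true RL parameters are drawn and a full go/no-go session is simulated on
#' an agent-specific pseudorandom schedule; go responses receive
#' shifted-lognormal response times; mental-health covariates are drawn with
#' the configured correlation to the true cue-response bias. Ground truth is
#' retained alongside all observables.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed; all component seeds derive from it.
#' @return A `gng_cohort` list: `trials` (long trial table over all agents),
#'   `params_true`, `titration` (per-agent matched amount, convergence,
#'   impatience score, true and recovered discount rate), `mh`, `config`,
#'   `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  n <- config$n_participants
  params <- sample_params(config, seed = seed)
  spec <- model_spec(config$model)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)

  trials <- vector("list", n)
  titr <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- params$participant_id[i]
    seed_i <- (seed + 7717L * i) %% .Machine$integer.max
    set.seed(seed_i)
    k_true <- exp(rnorm(1, config$k_meanlog, config$k_sdlog))
    mcq <- simulate_mcq_choices(k_true, config$mcq_temperature)
    k_hat <- score_mcq(mcq)$k
    agent <- make_discount_agent(k_true, config$titration_temperature)
    tit <- run_titration(agent, start = starting_amount(k_hat))
    titr[[i]] <- data.frame(
      participant_id = pid, k_true = k_true, k_hat = k_hat,
      start = starting_amount(k_hat), matched_amount = tit$matched_amount,
      n_trials = tit$n_trials, converged = tit$converged,
      excluded_reason = tit$excluded_reason,
      impatience = if (tit$converged && !is.na(tit$matched_amount) &&
                       tit$matched_amount >= 1)
        impatience_score(tit$matched_amount) else NA_real_,
      stringsAsFactors = FALSE)

    sched <- generate_schedule(config$n_per_condition, config$max_run,
                               config$feedback_validity, seed = seed_i + 1L)
    tp <- unlist(params[i, spec$par_names])
    ses <- simulate_agent(tp, spec, sched, seed = seed_i + 2L,
                          participant_id = pid)
    set.seed(seed_i + 3L)
    go <- ses$response == "go"
    ses$rt_ms[go] <- sample_rt(
      reward_code = ifelse(ses$reward_timing[go] == "immediate", 1, -1),
      action_code = ifelse(ses$required_action[go] == "go", 1, -1),
      block_c = ses$block[go] - mean(unique(ses$block)),
      rt_config = config$rt)
    trials[[i]] <- ses
  }
  mh <- sample_mh(config, params$pi, seed = (seed + 13L) %% .Machine$integer.max)
  structure(list(trials = do.call(rbind, trials),
                 params_true = params,
                 titration = do.call(rbind, titr),
                 mh = mh, config = config, seed = seed),
            class = "gng_cohort")
}

#' @export
print.gng_cohort <- function(x, ...) {
  cat(sprintf("Synthetic go/no-go cohort: %d participants, %d trials each (model %s)\n",
              x$config$n_participants, nrow(x$trials) / x$config$n_participants,
              x$config$model))
  cat(sprintf("  overall go rate %.3f; titration converged for %d/%d\n",
              mean(x$trials$response == "go"), sum(x$titration$converged),
              nrow(x$titration)))
  invisible(x)
}

#' Write a cohort's tables to a directory as CSV
#'
#' Writes `trials.csv`, `params_true.csv`, `titration.csv`,
#' `mental_health.csv`, and a JSON echo of the configuration and seed.
#'
#' @param cohort A `gng_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(cohort$params_true, file.path(dir, "params_true.csv"), row.names = FALSE)
  write.csv(cohort$titration, file.path(dir, "titration.csv"), row.names = FALSE)
  write.csv(cohort$mh, file.path(dir, "mental_health.csv"), row.names = FALSE)
  cfg <- unclass(cohort$config)
  cfg$param_mean <- as.list(cfg$param_mean)
  cfg$param_sd <- as.list(cfg$param_sd)
  cfg$seed <- cohort$seed
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort trial table written by [write_cohort()]
#'
#' @param path Path to a `trials.csv`.
#' @return Long trial data frame.
#' @export
read_trials <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$feedback_valid <- as.logical(out$feedback_valid)
  out$correct <- as.logical(out$correct)
  out
}
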