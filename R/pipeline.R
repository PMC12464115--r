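#' Simulate a cohort directly from the hierarchical response-bias model
#'
#' Fast generative counterpart of the statistical layer, used for power
#' analysis and calibration: per-trial go responses are drawn from a logistic
#' model with population fixed effects (intercept, required-action and
#' reward-timing codes) and by-participant Gaussian random intercepts and
#' slopes. Defaults reproduce the task's reported aggregates: overall go
#' rate near 0.58 (intercept 0.33 on the log-odds scale), a required-action
#' effect of 1.3, and between-participant reward-effect heterogeneity
#' calibrated so that the design's reported power analysis (90-95% power for
#' a reward effect of 0.17 at n = 389) is reproduced.
#'
#' @param n_agents Number of participants.
#' @param effect_reward Population reward effect on the log-odds scale
#'   (sum-to-zero +1/-1 coding).
#' @param effect_action Population required-action effect.
#' @param intercept Population intercept (log-odds of go).
#' @param sd_intercept,sd_action,sd_reward Between-participant standard
#'   deviations of the random intercept and slopes.
#' @param mh Optional per-participant covariate vector (length `n_agents`);
#'   when given, `beta_mh` scales its interaction with the reward code.
#' @param beta_mh Reward-by-covariate moderation coefficient.
#' @param n_per_condition Trials per condition (default 50).
#' @param seed Integer seed.
#' @return Long trial table compatible with [build_design()].
#' @export
simulate_bias_cohort <- function(n_agents, effect_reward = 0.17,
                                 effect_action = 1.3, intercept = 0.33,
                                 sd_intercept = 1.0, sd_action = 0.5,
                                 sd_reward = 0.95, mh = NULL, beta_mh = 0,
                                 n_per_condition = 50, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  b0 <- rnorm(n_agents, intercept, sd_intercept)
  ba <- rnorm(n_agents, effect_action, sd_action)
  br <- rnorm(n_agents, effect_reward, sd_reward)
  if (!is.null(mh)) {
    stopifnot(length(mh) == n_agents)
    br <- br + beta_mh * (mh - mean(mh))
  }
  rows <- vector("list", n_agents)
  # trial order is irrelevant to this (non-learning) generative model, so a
  # single pseudorandom schedule is shared by all agents of a cohort
  sched <- generate_schedule(n_per_condition, 2, 0.8,
                             seed = (seed + 131L) %% .Machine$integer.max)
  ac <- ifelse(sched$required_action == "go", 1, -1)
  rc <- ifelse(sched$reward_timing == "immediate", 1, -1)
  for (i in seq_len(n_agents)) {
    eta <- b0[i] + ba[i] * ac + br[i] * rc
    go <- rbinom(nrow(sched), 1, plogis(eta)) == 1
    rows[[i]] <- data.frame(
      participant_id = sprintf("s%04d", i), trial = sched$index,
      block = sched$block, condition = sched$condition,
      required_action = sched$required_action,
      reward_timing = sched$reward_timing,
      feedback_valid = sched$feedback_valid,
      response = ifelse(go, "go", "nogo"),
      correct = go == (sched$required_action == "go"),
      outcome = NA_character_, rt_ms = NA_real_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulation-based power scan for the reward effect
#'
#' For each cohort size, simulates replicate cohorts from the hierarchical
#' response-bias model with the planted reward effect, fits the reduced
#' response-bias model, and reports the fraction of replicates in which the
#' reward effect's interval excludes zero.
#'
#' @param effect Planted reward effect on the log-odds scale (0 gives the
#'   null calibration).
#' @param n_grid Cohort sizes to scan.
#' @param replicates Simulated cohorts per size.
#' @param seed Integer seed.
#' @param re Random-effects structure used in the test model.
#' @param ... Further arguments to [simulate_bias_cohort()].
#' @return Data frame: `n`, `power` (fraction significant), `replicates`,
#'   `effect`.
#' @export
power_scan <- function(effect = 0.17, n_grid = c(50, 100, 200), replicates = 20,
                       seed = 1L, re = "reward", ...) {
  stopifnot(replicates >= 1)
  out <- lapply(n_grid, function(n) {
    hits <- 0L
    for (r in seq_len(replicates)) {
      trials <- simulate_bias_cohort(
        n_agents = n, effect_reward = effect,
        seed = (seed + 7817L * n + r) %% .Machine$integer.max, ...)
      tab <- fit_response_bias(build_design(trials), re = re)
      row <- tab[tab$effect == "reward_code", ]
      hits <- hits + as.integer(row$significant)
    }
    data.frame(n = n, power = hits / replicates, replicates = replicates,
               effect = effect)
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in dependency order -- simulate a cohort,
#' fit the RL model family per participant, validate the winning model
#' (parameter recovery and posterior predictive checks), and run the
#' behavioral statistics (response bias, impatience and parameter
#' correlations with the mental-health covariates) -- writing each stage's
#' tables to `out_dir` together with a machine-readable summary.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param stages Named logical toggles: `simulate`, `fit`, `validate`,
#'   `stats`. Later stages require the earlier ones in the same call.
#' @param models Model ids fitted in the `fit` stage.
#' @param validate_model Model validated in the `validate` stage.
#' @param recovery_agents Agents used for parameter recovery.
#' @param control Optimizer settings for all fits.
#' @return A `pipeline_result` list with the stage outputs (`cohort`,
#'   `fits`, `comparison`, `recovery`, `ppc`, `effects`, `correlations`) and
#'   the `summary` written to `out_dir/summary.json`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = tempfile("gngrun"),
                         seed = 1L,
                         stages = c(simulate = TRUE, fit = TRUE,
                                    validate = TRUE, stats = TRUE),
                         models = gng_models, validate_model = "M3",
                         recovery_agents = 20, control = de_control()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list(out_dir = out_dir, seed = seed)
  summary <- list(seed = seed, n_participants = config$n_participants)

  if (isTRUE(stages[["simulate"]])) {
    res$cohort <- generate_cohort(config, seed = seed)
    write_cohort(res$cohort, file.path(out_dir, "cohort"))
    summary$go_rate <- mean(res$cohort$trials$response == "go")
    summary$titration_converged <- mean(res$cohort$titration$converged)
  }

  if (isTRUE(stages[["fit"]])) {
    stopifnot(!is.null(res$cohort))
    res$fits <- fit_cohort(res$cohort, models = models, control = control,
                           seed = seed + 1L)
    write.csv(res$fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    med_aic <- tapply(res$fits$aic, res$fits$model, median)[models]
    freq <- model_frequency(res$fits)[models]
    res$comparison <- list(median_aic = as.list(med_aic),
                           model_frequency = as.list(freq))
    jsonlite::write_json(res$comparison,
                         file.path(out_dir, "model_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    summary$median_aic <- as.list(med_aic)
    summary$model_frequency <- as.list(freq)
  }

  if (isTRUE(stages[["validate"]])) {
    sched <- generate_schedule(config$n_per_condition, config$max_run,
                               config$feedback_validity, seed = seed + 2L)
    res$recovery <- parameter_recovery(validate_model,
                                       n_agents = recovery_agents,
                                       schedule = sched, control = control,
                                       seed = seed + 3L)
    write.csv(as.data.frame(res$recovery),
              file.path(out_dir, "parameter_recovery.csv"), row.names = FALSE)
    summary$recovery_cor <- setNames(as.list(res$recovery$cor),
                                     res$recovery$parameter)
    if (!is.null(res$fits)) {
      w <- res$fits[res$fits$model == validate_model, ]
      idx <- order(w$aic)[seq_len(min(5, nrow(w)))]
      sessions <- as_session_list(res$cohort)
      ppc_fits <- lapply(w$participant_id[idx], function(pid)
        gng_fit(sessions[[pid]], validate_model, control = control,
                seed = seed + 4L))
      res$ppc <- posterior_predictive(ppc_fits, n_sims = 30, seed = seed + 5L)
      write.csv(as.data.frame(res$ppc), file.path(out_dir, "ppc.csv"),
                row.names = FALSE)
      summary$ppc_coverage <- attr(res$ppc, "coverage")
    }
  }

  if (isTRUE(stages[["stats"]])) {
    stopifnot(!is.null(res$cohort))
    design <- build_design(res$cohort$trials)
    res$effects <- fit_response_bias(design)
    write.csv(as.data.frame(res$effects), file.path(out_dir, "effects.csv"),
              row.names = FALSE)
    reward <- res$effects[res$effects$effect == "reward_code", ]
    summary$reward_effect <- reward$estimate
    summary$reward_significant <- reward$significant
    if (!is.null(res$fits)) {
      w <- res$fits[res$fits$model == validate_model,
                    c("participant_id", "pi")]
      res$correlations <- correlate_with_mh(w, res$cohort$mh)
      write.csv(res$correlations, file.path(out_dir, "correlations.csv"),
                row.names = FALSE)
    }
  }

  summary$config_echo <- file.path(out_dir, "cohort", "config.json")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res$summary <- summary
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n")
  if (!is.null(x$summary$go_rate))
    cat(sprintf("  go rate %.3f\n", x$summary$go_rate))
  if (!is.null(x$summary$median_aic)) {
    aics <- unlist(x$summary$median_aic)
    cat("  median AIC:", paste(sprintf("%s=%.1f", names(aics), aics),
                               collapse = ", "), "\n")
  }
  if (!is.null(x$summary$reward_effect))
    cat(sprintf("  reward effect %.3f (significant: %s)\n",
                x$summary$reward_effect, x$summary$reward_significant))
  invisible(x)
}
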