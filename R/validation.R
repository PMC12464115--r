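#' Parameter recovery for one model
#'
#' Samples true parameters uniformly over generative ranges, simulates a
#' session per agent, refits the same model by MAP, and summarizes the
#' true-versus-recovered correspondence per parameter.
#'
#' @param model Model id or [model_spec()].
#' @param n_agents Number of simulated agents (>= 2).
#' @param schedule Task schedule used for all agents.
#' @param ranges Named list of `c(lower, upper)` generative ranges; defaults
#'   to each parameter's box shrunk away from its boundaries (see
#'   [default_ranges()]).
#' @param priors,control Passed to [gng_fit()].
#' @param seed Integer seed controlling draws, simulation, and fits.
#' @return A `recovery_report`: data frame (`parameter`, `cor`, `bias`,
#'   `rmse`) plus attributes `true`, `recovered`, `n_agents`, `seed`.
#'   Correlations are `NA` (undefined) when the true values do not vary.
#' @export
parameter_recovery <- function(model, n_agents = 50, schedule,
                               ranges = default_ranges(model),
                               priors = prior_spec(), control = de_control(),
                               seed = 1L) {
  if (n_agents < 2) stop("invalid input: n_agents must be >= 2")
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  bad <- setdiff(spec$par_names, names(ranges))
  if (length(bad)) stop("invalid input: ranges lack ", paste(bad, collapse = ", "))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  true <- sapply(spec$par_names, function(pn)
    runif(n_agents, ranges[[pn]][1], ranges[[pn]][2]))
  true <- matrix(true, nrow = n_agents,
                 dimnames = list(NULL, spec$par_names))
  est <- matrix(NA_real_, n_agents, spec$n_free,
                dimnames = list(NULL, spec$par_names))
  for (i in seq_len(n_agents)) {
    ses <- simulate_agent(true[i, ], spec, schedule,
                          seed = (seed + 31L * i) %% .Machine$integer.max,
                          participant_id = sprintf("rec%03d", i))
    fit <- gng_fit(ses, spec, priors = priors, control = control,
                   seed = (seed + 31L * i + 1L) %% .Machine$integer.max)
    est[i, ] <- fit$par
  }
  rep_df <- data.frame(
    parameter = spec$par_names,
    cor = vapply(spec$par_names, function(pn) {
      if (sd(true[, pn]) < 1e-12 || sd(est[, pn]) < 1e-12) NA_real_
      else cor(true[, pn], est[, pn])
    }, numeric(1)),
    bias = colMeans(est - true),
    rmse = sqrt(colMeans((est - true)^2)),
    row.names = NULL)
  structure(rep_df, true = true, recovered = est, n_agents = n_agents,
            seed = seed, model = spec$id,
            class = c("recovery_report", "data.frame"))
}

#' Default generative ranges for recovery studies
#'
#' Uniform ranges over each parameter's box, shrunk away from the boundaries
#' to avoid estimate pile-up at the constraints: learning rates 0.05-0.5,
#' inverse temperature 1-15, noise 0-0.4, biases -1 to 1.
#'
#' @param model Model id or [model_spec()].
#' @return Named list of `c(lower, upper)` ranges.
#' @export
default_ranges <- function(model) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  all <- list(alpha = c(0.05, 0.5), alpha0 = c(0.05, 0.5),
              alpha1 = c(0.05, 0.5), tau = c(1, 15), xi = c(0, 0.4),
              b = c(-1, 1), pi = c(-1, 1))
  all[spec$par_names]
}

#' Model recovery confusion matrix
#'
#' Simulates agents from each candidate model, fits every candidate to every
#' simulated session, assigns the winner by lowest AIC (exact ties split
#' equally), and tabulates row-normalized proportions of winners per
#' generating model.
#'
#' @param models Character vector of model ids.
#' @param n_per_model Simulated agents per generating model.
#' @param schedule Task schedule.
#' @param ranges Named list (per model id) of generative ranges; defaults to
#'   [default_ranges()] per model.
#' @param priors,control Passed to [gng_fit()].
#' @param seed Integer seed.
#' @return A `confusion_matrix`: numeric matrix, rows = generating model,
#'   columns = winning model, each row summing to 1.
#' @export
model_recovery <- function(models = gng_models, n_per_model = 6, schedule,
                           ranges = NULL, priors = prior_spec(),
                           control = de_control(), seed = 1L) {
  specs <- lapply(models, model_spec)
  names(specs) <- models
  conf <- matrix(0, length(models), length(models),
                 dimnames = list(generating = models, winner = models))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  for (g in seq_along(models)) {
    gspec <- specs[[g]]
    rng <- if (is.null(ranges)) default_ranges(gspec) else ranges[[models[g]]]
    set.seed((seed + 577L * g) %% .Machine$integer.max)
    for (i in seq_len(n_per_model)) {
      true <- vapply(gspec$par_names, function(pn)
        runif(1, rng[[pn]][1], rng[[pn]][2]), numeric(1))
      sim_seed <- (seed + 577L * g + 13L * i) %% .Machine$integer.max
      ses <- simulate_agent(true, gspec, schedule, seed = sim_seed,
                            participant_id = sprintf("g%s_%02d", models[g], i))
      aics <- vapply(seq_along(specs), function(f)
        gng_fit(ses, specs[[f]], priors = priors, control = control,
                seed = (sim_seed + f) %% .Machine$integer.max)$aic,
        numeric(1))
      win <- which(aics == min(aics))
      conf[g, win] <- conf[g, win] + 1 / length(win)
    }
  }
  conf <- conf / n_per_model
  class(conf) <- c("confusion_matrix", class(conf))
  conf
}

#' Posterior predictive check of fitted models
#'
#' For each fitted session, simulates replicate sessions at the MAP
#' parameters and compares the observed per-condition go-rate trajectory
#' (binned by condition presentation) against the Monte-Carlo band of the
#' simulations.
#'
#' @param fits A single `gng_fit` or a list of them.
#' @param n_sims Replicate simulations per fit (>= 1).
#' @param bin Condition presentations per trajectory bin.
#' @param level Width of the Monte-Carlo interval (default 0.9).
#' @param seed Integer seed.
#' @return A `ppc_report` data frame: `participant_id`, `condition`, `bin`,
#'   `observed`, `sim_mean`, the predictive band `sim_lo`/`sim_hi`
#'   (quantiles across replicate sessions, used for the coverage check),
#'   the Monte-Carlo uncertainty of the simulated mean `mean_lo`/`mean_hi`
#'   (shrinks as `n_sims` grows), and `inside`; attribute `coverage` gives
#'   the overall fraction of bins whose observed go rate falls inside the
#'   predictive band.
#' @export
posterior_predictive <- function(fits, n_sims = 50, bin = 5, level = 0.9,
                                 seed = 1L) {
  if (n_sims < 1) stop("invalid input: n_sims must be >= 1")
  if (inherits(fits, "gng_fit")) fits <- list(fits)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- list()
  for (f in seq_along(fits)) {
    fit <- fits[[f]]
    ses <- fit$session
    sims <- simulate.gng_fit(fit, nsim = n_sims,
                             seed = (seed + 97L * f) %% .Machine$integer.max)
    for (cnd in gng_conditions) {
      sel <- ses$condition == cnd
      if (!any(sel)) next
      bins <- ceiling(seq_len(sum(sel)) / bin)
      obs <- tapply(ses$response[sel] == "go", bins, mean)
      simmat <- sapply(sims, function(s)
        tapply(s$response[sel] == "go", bins, mean))
      simmat <- matrix(simmat, nrow = length(obs))
      lo <- apply(simmat, 1, quantile, qs[1])
      hi <- apply(simmat, 1, quantile, qs[2])
      mn <- rowMeans(simmat)
      mc <- qnorm(1 - (1 - level) / 2) * apply(simmat, 1, sd) / sqrt(n_sims)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ses$participant_id[1], condition = cnd,
        bin = as.integer(names(obs)), observed = as.numeric(obs),
        sim_mean = mn, sim_lo = lo, sim_hi = hi,
        mean_lo = mn - mc, mean_hi = mn + mc,
        inside = obs >= lo & obs <= hi, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, coverage = mean(out$inside), n_sims = n_sims, level = level,
            class = c("ppc_report", "data.frame"))
}
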