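#' Priors for MAP estimation
#'
#' Inverse temperature: Gamma(shape 3, rate 0.3) (mean 10) on the natural
#' scale. Go bias and cue-response bias: Gaussian(0, 1). Learning rates and
#' irreducible noise carry implicit uniform priors over their unit boxes and
#' contribute only a constant to the log posterior.
#'
#' @param tau_shape,tau_rate Gamma prior for `tau`.
#' @param b_mean,b_sd Gaussian prior for the go bias.
#' @param pi_mean,pi_sd Gaussian prior for the cue-response bias.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(tau_shape = 3, tau_rate = 0.3, b_mean = 0, b_sd = 1,
                       pi_mean = 0, pi_sd = 1) {
  structure(list(tau_shape = tau_shape, tau_rate = tau_rate, b_mean = b_mean,
                 b_sd = b_sd, pi_mean = pi_mean, pi_sd = pi_sd),
            class = "prior_spec")
}

# Log prior density over the active parameters; rows of `parmat` are free
# parameter vectors in spec$par_names order.
log_prior_mat <- function(parmat, spec, priors) {
  lp <- dgamma(parmat[, match("tau", spec$par_names)],
               shape = priors$tau_shape, rate = priors$tau_rate, log = TRUE)
  if (spec$has_go_bias)
    lp <- lp + dnorm(parmat[, match("b", spec$par_names)],
                     priors$b_mean, priors$b_sd, log = TRUE)
  if (spec$has_cue_response_bias)
    lp <- lp + dnorm(parmat[, match("pi", spec$par_names)],
                     priors$pi_mean, priors$pi_sd, log = TRUE)
  lp
}

# Expand a matrix of free parameters (spec order) to the full 6-column
# internal layout.
full_par_mat <- function(parmat, spec) {
  n <- nrow(parmat)
  get <- function(nm, default) {
    j <- match(nm, spec$par_names)
    if (!is.na(j)) return(parmat[, j])
    if (length(default) == 1) rep(default, n) else default
  }
  a <- get("alpha", NA_real_)
  cbind(get("alpha0", a), get("alpha1", a), parmat[, match("tau", spec$par_names)],
        get("xi", 0), get("b", 0), get("pi", 0))
}

#' Log posterior of a session under a model
#'
#' Session log-likelihood plus the log prior densities of the active
#' parameters (uniform box priors contribute a constant, taken as 0).
#'
#' @inheritParams session_loglik
#' @param priors A [prior_spec()].
#' @return Scalar log-posterior value.
#' @export
log_posterior <- function(params, spec, session, priors = prior_spec()) {
  params <- check_params(params, spec)
  session_loglik(params, spec, session) +
    log_prior_mat(matrix(params, 1), spec, priors)
}

#' Fit a reinforcement-learning model to one session by MAP
#'
#' Maximizes the per-session posterior (likelihood times priors) over the
#' model's box-constrained parameter space with differential evolution. The
#' reported `loglik` is the pure likelihood at the posterior mode; `aic` is
#' computed from it.
#'
#' @param session Session data frame (see [simulate_agent()]).
#' @param model Model identifier `"M0"` ... `"M5"`, or a [model_spec()].
#' @param priors A [prior_spec()].
#' @param control Optimizer settings from [de_control()].
#' @param seed Integer seed for the optimizer; fits are deterministic given
#'   the seed.
#' @return A `gng_fit` object with components `model`, `spec`, `par` (named
#'   MAP estimates), `loglik`, `logpost`, `aic`, `n_free`, `diagnostics`,
#'   and the fitted `session`.
#' @export
#' @examples
#' sched <- generate_schedule(10, 2, 0.8, seed = 1)
#' ses <- simulate_agent(c(alpha = 0.3, tau = 5), model_spec("M0"), sched, seed = 2)
#' fit <- gng_fit(ses, "M0", seed = 3)
#' coef(fit)
gng_fit <- function(session, model = "M3", priors = prior_spec(),
                    control = de_control(), seed = 1L) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  if (is.null(session) || nrow(session) == 0)
    stop("invalid input: empty session")
  enc <- encode_trials(session)
  resp <- as.integer(session$response == "go")
  outc <- as.integer(session$outcome == "reward")
  objective <- function(parmat) {
    ll <- cpp_session_loglik_batch(full_par_mat(parmat, spec), enc$cond,
                                   enc$vs, resp, outc)
    -(ll + log_prior_mat(parmat, spec, priors))
  }
  opt <- de_optim(objective, spec$lower, spec$upper, control = control,
                  seed = seed)
  par <- setNames(opt$par, spec$par_names)
  ll <- session_loglik(par, spec, session)
  structure(list(model = spec$id, spec = spec, par = par, loglik = ll,
                 logpost = -opt$value, aic = aic(ll, spec$n_free),
                 n_free = spec$n_free,
                 diagnostics = list(iterations = opt$iterations,
                                    converged = opt$converged,
                                    n_eval = opt$n_eval, seed = seed),
                 session = session),
            class = "gng_fit")
}

#' Akaike's information criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @return `2 * k - 2 * loglik`; smaller values indicate better fit.
#' @export
aic <- function(loglik, k) {
  stopifnot(k >= 0)
  2 * k - 2 * loglik
}

#' @export
print.gng_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MAP fit of model %s (%d trials)\n", x$model, nrow(x$session)))
  print(round(x$par, digits))
  cat(sprintf("logLik %.2f, log-posterior %.2f, AIC %.2f\n",
              x$loglik, x$logpost, x$aic))
  invisible(x)
}

#' @export
summary.gng_fit <- function(object, ...) {
  out <- list(model = object$model, par = object$par, loglik = object$loglik,
              logpost = object$logpost, aic = object$aic,
              n_trials = nrow(object$session),
              go_rate = mean(object$session$response == "go"),
              accuracy = mean(object$session$correct),
              diagnostics = object$diagnostics)
  class(out) <- "summary.gng_fit"
  out
}

#' @export
print.summary.gng_fit <- function(x, ...) {
  cat(sprintf("Model %s fitted to %d trials (go rate %.2f, accuracy %.2f)\n",
              x$model, x$n_trials, x$go_rate, x$accuracy))
  print(round(x$par, 3))
  cat(sprintf("logLik %.2f, AIC %.2f; DE: %d generations, converged: %s\n",
              x$loglik, x$aic, x$diagnostics$iterations,
              x$diagnostics$converged))
  invisible(x)
}

#' @export
coef.gng_fit <- function(object, ...) object$par

#' @export
logLik.gng_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = nrow(object$session),
            class = "logLik")
}

#' Per-trial fitted go probabilities
#'
#' Evolves the fitted model along the observed responses and outcomes of a
#' session and returns the model's go probability on every trial.
#'
#' @param object A `gng_fit`.
#' @param newdata Optional session data frame (defaults to the fitted one).
#' @param ... Unused.
#' @return Numeric vector of go probabilities, one per trial.
#' @export
predict.gng_fit <- function(object, newdata = NULL, ...) {
  session <- if (is.null(newdata)) object$session else newdata
  enc <- encode_trials(session)
  cpp_session_pgo(unname(full_par(object$par, object$spec)), enc$cond, enc$vs,
                  as.integer(session$response == "go"),
                  as.integer(session$outcome == "reward"))
}

#' @export
residuals.gng_fit <- function(object, ...) {
  as.integer(object$session$response == "go") - predict(object)
}

#' Simulate sessions from a fitted model
#'
#' @param object A `gng_fit`.
#' @param nsim Number of replicate sessions.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of session data frames simulated at the MAP parameters on
#'   the fitted session's schedule.
#' @export
simulate.gng_fit <- function(object, nsim = 1, seed = 1L, ...) {
  sched <- object$session
  lapply(seq_len(nsim), function(i)
    simulate_agent(object$par, object$spec, sched, seed = seed + i - 1L,
                   participant_id = sched$participant_id[1]))
}

#' Plot observed against model-predicted go rates
#'
#' Draws per-condition observed go-rate learning curves (binned by condition
#' presentation) with the mean of replicate simulations at the fitted
#' parameters overlaid.
#'
#' @param x A `gng_fit`.
#' @param n_sims Number of replicate simulations for the predicted curves.
#' @param bin Number of condition presentations per bin.
#' @param seed Seed for the replicate simulations.
#' @param ... Passed to `matplot`.
#' @return Invisibly, the binned observed and simulated go rates.
#' @export
plot.gng_fit <- function(x, n_sims = 20, bin = 5, seed = 1L, ...) {
  ses <- x$session
  sims <- simulate.gng_fit(x, nsim = n_sims, seed = seed)
  conds <- gng_conditions
  obs <- sim <- list()
  for (cnd in conds) {
    sel <- ses$condition == cnd
    reps <- seq_len(sum(sel))
    bins <- ceiling(reps / bin)
    obs[[cnd]] <- tapply(ses$response[sel] == "go", bins, mean)
    simmat <- sapply(sims, function(s) s$response[sel] == "go")
    sim[[cnd]] <- tapply(rowMeans(simmat), bins, mean)
  }
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (cnd in conds) {
    graphics::matplot(cbind(obs[[cnd]], sim[[cnd]]), type = "b",
                      pch = c(1, 16), lty = c(1, 2), ylim = c(0, 1),
                      xlab = sprintf("bin of %d presentations", bin),
                      ylab = "p(go)", main = cnd, ...)
  }
  invisible(list(observed = obs, simulated = sim))
}

#' Fit all requested models to every participant of a cohort
#'
#' @param sessions Either a `gng_cohort` (see [generate_cohort()]), a list of
#'   session data frames, or one long trial table with a `participant_id`
#'   column.
#' @param models Character vector of model ids (default all six).
#' @param priors A [prior_spec()].
#' @param control Optimizer settings.
#' @param seed Master seed; per-fit seeds are derived deterministically from
#'   it and the participant/model indices.
#' @param store_fits Keep the full `gng_fit` objects (attribute `"fits"`).
#' @param progress Print one line per participant.
#' @return Data frame with one row per participant x model: MAP estimates
#'   (`alpha`, `alpha0`, `alpha1`, `tau`, `xi`, `b`, `pi`, inactive ones NA),
#'   `loglik`, `logpost`, `aic`, `n_free`, `converged`.
#' @export
fit_cohort <- function(sessions, models = gng_models, priors = prior_spec(),
                       control = de_control(), seed = 1L, store_fits = FALSE,
                       progress = FALSE) {
  sessions <- as_session_list(sessions)
  specs <- lapply(models, model_spec)
  rows <- list()
  fits <- list()
  all_pars <- c("alpha", "alpha0", "alpha1", "tau", "xi", "b", "pi")
  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    pid <- as.character(ses$participant_id[1])
    if (progress) message(sprintf("fitting participant %s (%d/%d)", pid, i,
                                  length(sessions)))
    for (j in seq_along(specs)) {
      fit_seed <- (seed + 7919L * i + 101L * j) %% .Machine$integer.max
      fit <- tryCatch(
        gng_fit(ses, specs[[j]], priors = priors, control = control,
                seed = fit_seed),
        error = function(e) e)
      if (inherits(fit, "error")) {
        row <- c(setNames(rep(NA_real_, length(all_pars)), all_pars),
                 loglik = NA_real_, logpost = NA_real_, aic = NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, model = specs[[j]]$id, t(row),
          n_free = specs[[j]]$n_free, converged = FALSE,
          error = conditionMessage(fit), stringsAsFactors = FALSE)
        next
      }
      pv <- setNames(rep(NA_real_, length(all_pars)), all_pars)
      pv[names(fit$par)] <- fit$par
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, model = fit$model, t(pv), loglik = fit$loglik,
        logpost = fit$logpost, aic = fit$aic, n_free = fit$n_free,
        converged = fit$diagnostics$converged, error = NA_character_,
        stringsAsFactors = FALSE)
      if (store_fits) fits[[paste(pid, fit$model, sep = ".")]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (store_fits) attr(out, "fits") <- fits
  out
}

as_session_list <- function(sessions) {
  if (inherits(sessions, "gng_cohort")) sessions <- sessions$trials
  if (is.data.frame(sessions)) {
    return(split(sessions, factor(sessions$participant_id,
                                  levels = unique(sessions$participant_id))))
  }
  sessions
}

#' Model frequency from a per-participant AIC table
#'
#' The proportion of participants for which each model attains the lowest
#' AIC; exact ties split a participant's weight equally among the tied
#' models.
#'
#' @param fits A `fit_cohort()` result, or any data frame with columns
#'   `participant_id`, `model`, `aic`.
#' @return Named numeric vector of proportions (one per model, summing to 1).
#' @export
model_frequency <- function(fits) {
  models <- unique(fits$model)
  tab <- tapply(fits$aic, list(fits$participant_id, fits$model), identity)
  tab <- tab[, models, drop = FALSE]
  if (anyNA(tab)) stop("invalid input: missing participant x model AIC cells")
  freq <- setNames(numeric(length(models)), models)
  for (i in seq_len(nrow(tab))) {
    a <- tab[i, ]
    win <- which(a == min(a))
    freq[win] <- freq[win] + 1 / length(win)
  }
  freq / nrow(tab)
}
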