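#' Build the sum-to-zero design table for the bias models
#'
#' Codes the two-level factors as +1/-1 (required action: go = +1; reward
#' timing: immediate = +1), centres the linear block predictor, and
#' optionally merges a mean-centred per-participant mental-health score.
#'
#' @param trials Long trial table (see [generate_cohort()]); must contain
#'   `participant_id`, `required_action`, `reward_timing`, `block`,
#'   `response`, `rt_ms`.
#' @param mh_score Optional per-participant covariate: a data frame with
#'   `participant_id` and one score column, or a vector named by participant.
#' @return Design data frame: `participant_id`, `response` (0/1 go), `rt_ms`,
#'   `action_code`, `reward_code`, `block_c`, and `mh` when supplied.
#' @export
build_design <- function(trials, mh_score = NULL) {
  need <- c("participant_id", "required_action", "reward_timing", "block",
            "response")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("invalid input: trials lack ", paste(miss, collapse = ", "))
  if (!all(c("go", "nogo") %in% trials$required_action) ||
      !all(c("immediate", "delayed") %in% trials$reward_timing))
    stop("invalid input: missing condition labels")
  out <- data.frame(
    participant_id = as.character(trials$participant_id),
    response = as.integer(trials$response == "go"),
    rt_ms = if ("rt_ms" %in% names(trials)) trials$rt_ms else NA_real_,
    action_code = ifelse(trials$required_action == "go", 1, -1),
    reward_code = ifelse(trials$reward_timing == "immediate", 1, -1),
    block_c = trials$block - mean(unique(trials$block)),
    stringsAsFactors = FALSE)
  if (!is.null(mh_score)) {
    if (is.data.frame(mh_score)) {
      sc <- setNames(mh_score[[2]], as.character(mh_score[[1]]))
    } else sc <- mh_score
    if (sd(sc, na.rm = TRUE) == 0)
      stop("invalid input: covariate has zero variance")
    sc <- sc - mean(sc, na.rm = TRUE)
    out$mh <- unname(sc[out$participant_id])
  }
  out
}

re_formula <- function(re) {
  switch(re,
         intercept = "(1 | participant_id)",
         reward = "(1 + reward_code | participant_id)",
         reduced = "(1 + action_code + reward_code + block_c | participant_id)",
         maximal = "(action_code * reward_code * block_c | participant_id)",
         stop("unknown random-effects structure ", re))
}

fixed_formula <- function(design) {
  if ("mh" %in% names(design)) "action_code * reward_code * block_c * mh"
  else "action_code * reward_code * block_c"
}

# Collapse Bernoulli rows into binomial counts per unique covariate cell;
# the fixed covariates are constant within cells, so the likelihood is
# unchanged and mixed-model fits are much faster.
aggregate_binary <- function(design) {
  vars <- intersect(c("participant_id", "action_code", "reward_code",
                      "block_c", "mh"), names(design))
  agg <- aggregate(design$response, by = c(design[vars]), FUN = sum)
  names(agg)[ncol(agg)] <- "successes"
  agg$n <- aggregate(design$response, by = c(design[vars]), FUN = length)$x
  agg
}

effect_table <- function(fit, level, messages = character()) {
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- fe / se
  p <- 2 * pnorm(-abs(z))
  zc <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(effect = names(fe), estimate = unname(fe),
                    se = unname(se), lower = unname(fe - zc * se),
                    upper = unname(fe + zc * se), tail_p = unname(p),
                    significant = unname(fe - zc * se > 0 | fe + zc * se < 0),
                    stringsAsFactors = FALSE)
  structure(out, level = level, messages = messages, fit = fit,
            class = c("effect_table", "data.frame"))
}

#' Hierarchical response-bias model
#'
#' Mixed-effects logistic regression of the go response on the sum-to-zero
#' coded required action, reward timing, centred block, and all their
#' interactions (times the mental-health score when present), with
#' by-participant random effects. Estimates are reported with Wald 95%
#' intervals and two-sided normal tail probabilities at the effect-table
#' surface. Trials are aggregated to binomial counts per covariate cell
#' before fitting (likelihood-identical, much faster).
#'
#' @param design A [build_design()] table.
#' @param re Random-effects structure: `"reduced"` (intercept +
#'   main-effect slopes; default), `"intercept"`, `"reward"` (intercept +
#'   reward slope, the minimal structure giving valid reward-effect
#'   inference under slope heterogeneity), or `"maximal"` (all interaction
#'   slopes).
#' @param level Interval level (default 0.95).
#' @param seed Unused by the deterministic fit; kept for interface stability.
#' @return An `effect_table` data frame (one row per fixed effect):
#'   `estimate`, `se`, `lower`, `upper`, `tail_p`, `significant`. Convergence
#'   messages, if any, are attached as attribute `"messages"`.
#' @export
fit_response_bias <- function(design, re = "reduced", level = 0.95,
                              seed = NULL) {
  agg <- aggregate_binary(design)
  form <- as.formula(paste("cbind(successes, n - successes) ~",
                           fixed_formula(design), "+", re_formula(re)))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::glmer(form, data = agg, family = binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  effect_table(fit, level, msgs)
}

#' Hierarchical shifted-lognormal response-time model
#'
#' Models go-response times (correct and incorrect go responses) as
#' `log(rt - shift)` with the same sum-to-zero fixed-effect structure as the
#' response-bias model and by-participant random effects. The global onset
#' shift is estimated by profiling the exact likelihood (including the
#' transformation Jacobian) over a grid below the minimum observed RT.
#' Effects are reported on the log scale.
#'
#' @param design A [build_design()] table; only rows with `response == 1`
#'   and a finite `rt_ms` are used.
#' @param re Random-effects structure (see [fit_response_bias()]).
#' @param level Interval level.
#' @param shift `"profile"` (default) or a fixed numeric shift in ms.
#' @param n_shift Number of profile grid points.
#' @return An `effect_table` with attributes `"shift"` (estimated onset, ms)
#'   and `"shift_profile"` (grid and profile log-likelihoods).
#' @export
fit_rt_bias <- function(design, re = "reduced", level = 0.95,
                        shift = "profile", n_shift = 9) {
  d <- design[design$response == 1 & is.finite(design$rt_ms), ]
  if (!nrow(d)) stop("invalid input: no go responses with response times")
  form <- as.formula(paste("y ~", fixed_formula(d), "+", re_formula(re)))
  fit_at <- function(s) {
    d$y <- log(d$rt_ms - s)
    lme4::lmer(form, data = d, REML = FALSE,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           calc.derivs = FALSE))
  }
  msgs <- character()
  profile <- NULL
  withCallingHandlers({
    if (identical(shift, "profile")) {
      grid <- seq(0, 0.98 * min(d$rt_ms), length.out = n_shift)
      # profile log-likelihood on the RT scale includes the log-Jacobian
      ll <- vapply(grid, function(s)
        as.numeric(logLik(fit_at(s))) - sum(log(d$rt_ms - s)), numeric(1))
      profile <- data.frame(shift = grid, loglik = ll)
      shift <- grid[which.max(ll)]
    }
    fit <- fit_at(shift)
  }, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) {
    msgs <<- c(msgs, conditionMessage(m))
    invokeRestart("muffleMessage")
  })
  out <- effect_table(fit, level, msgs)
  attr(out, "shift") <- shift
  attr(out, "shift_profile") <- profile
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of two-sided probabilities in `[0, 1]`.
#' @param q False discovery rate (default 0.05).
#' @return List: `adjusted` (BH-adjusted values), `rejected` (logical flags),
#'   `threshold` (largest raw p rejected; `NA` when none).
#' @export
bh_adjust <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- p.adjust(p, method = "BH")
  rej <- !is.na(adj) & adj <= q
  list(adjusted = adj, rejected = rej,
       threshold = if (any(rej)) max(p[rej]) else NA_real_)
}

#' Mental-health moderation scan
#'
#' Fits one bias model per mental-health covariate, each including the
#' covariate's main effect and its interactions with all task fixed effects.
#' The primary test is the reward-by-covariate two-way interaction; the
#' three-way interactions with required action and block are reported
#' alongside. Two-sided tail probabilities of the primary terms are
#' Benjamini-Hochberg adjusted across covariates, and intervals for the
#' selected effects are re-widened to the matching false-coverage-adjusted
#' level `1 - k * q / m` (k = number selected, m = number of covariates).
#'
#' @param trials Long trial table.
#' @param mh_table Data frame: `participant_id` plus one column per
#'   covariate.
#' @param which `"response"` or `"rt"`.
#' @param q False discovery rate (default 0.05).
#' @param re Random-effects structure passed to the underlying fit.
#' @return A `moderation_scan` list: `summary` (per-covariate primary-term
#'   estimate, `tail_p`, `p_adj`, `significant`, adjusted interval),
#'   `tables` (full effect tables per covariate), `q`, `which`.
#' @export
moderation_scan <- function(trials, mh_table, which = c("response", "rt"),
                            q = 0.05, re = "reduced") {
  which <- match.arg(which)
  covs <- setdiff(names(mh_table), "participant_id")
  if (!length(covs)) stop("invalid input: no covariates in mh_table")
  tables <- list()
  prim <- data.frame()
  for (cv in covs) {
    design <- build_design(trials, mh_table[, c("participant_id", cv)])
    tab <- if (which == "response") fit_response_bias(design, re = re)
           else fit_rt_bias(design, re = re)
    tables[[cv]] <- tab
    row <- tab[tab$effect == "reward_code:mh", ]
    if (!nrow(row)) stop("internal: primary term missing for ", cv)
    prim <- rbind(prim, data.frame(covariate = cv, estimate = row$estimate,
                                   se = row$se, tail_p = row$tail_p,
                                   stringsAsFactors = FALSE))
  }
  bh <- bh_adjust(prim$tail_p, q)
  k <- sum(bh$rejected)
  m <- length(covs)
  adj_level <- if (k > 0) 1 - k * q / m else 0.95
  zc <- qnorm(1 - (1 - adj_level) / 2)
  prim$p_adj <- bh$adjusted
  prim$significant <- bh$rejected
  prim$lower_adj <- prim$estimate - zc * prim$se
  prim$upper_adj <- prim$estimate + zc * prim$se
  structure(list(summary = prim, tables = tables, q = q, which = which,
                 adj_level = adj_level),
            class = "moderation_scan")
}

#' @export
print.moderation_scan <- function(x, ...) {
  cat(sprintf("Mental-health moderation scan (%s bias), %d covariates, FDR %.2f\n",
              x$which, nrow(x$summary), x$q))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Pearson correlations with mental-health covariates
#'
#' Correlates a per-participant quantity (impatience score or an RL model
#' parameter) with each mental-health covariate, with Benjamini-Hochberg
#' adjustment across covariates.
#'
#' @param values Data frame (`participant_id`, value) or vector named by
#'   participant.
#' @param mh_table Data frame: `participant_id` plus covariate columns.
#' @param q False discovery rate.
#' @return Data frame: `covariate`, `n`, `r`, `tail_p`, `p_adj`,
#'   `significant`.
#' @export
correlate_with_mh <- function(values, mh_table, q = 0.05) {
  if (is.data.frame(values)) {
    v <- setNames(values[[2]], as.character(values[[1]]))
  } else v <- values
  covs <- setdiff(names(mh_table), "participant_id")
  x <- unname(v[as.character(mh_table$participant_id)])
  rows <- lapply(covs, function(cv) {
    y <- mh_table[[cv]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) stop("invalid input: fewer than 3 complete pairs for ", cv)
    ct <- cor.test(x[ok], y[ok])
    data.frame(covariate = cv, n = sum(ok), r = unname(ct$estimate),
               tail_p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bh <- bh_adjust(out$tail_p, q)
  out$p_adj <- bh$adjusted
  out$significant <- bh$rejected
  rownames(out) <- NULL
  out
}
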