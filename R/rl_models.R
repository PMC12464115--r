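#' Specification of the six nested go/no-go reinforcement-learning models
#'
#' The family nests a basic Rescorla-Wagner learner (M0: learning rate
#' `alpha`, inverse temperature `tau`) under increasingly rich choice and
#' learning mechanisms: M1 adds irreducible noise `xi` (lapses mixing the
#' softmax policy with uniform responding), M2 adds a constant go bias `b`,
#' M3 adds the Pavlovian cue-response bias `pi` (a go-weight increment scaled
#' by the cue's reward-timing value, +1 immediate / -1 delayed), M4 replaces
#' the single learning rate with an outcome-contingent pair `alpha0`/`alpha1`
#' (learning bias), and M5 combines the cue-response and learning biases.
#'
#' @param id One of `"M0"` ... `"M5"`.
#' @return A `model_spec` list: `id`, feature flags (`has_noise`,
#'   `has_go_bias`, `has_cue_response_bias`, `has_learning_bias`),
#'   `par_names`, box constraints `lower`/`upper`, and `n_free`.
#' @export
#' @examples
#' model_spec("M3")$n_free  # 5
model_spec <- function(id = c("M0", "M1", "M2", "M3", "M4", "M5")) {
  id <- match.arg(id)
  has_noise <- id != "M0"
  has_go_bias <- !id %in% c("M0", "M1")
  has_cue <- id %in% c("M3", "M5")
  has_lbias <- id %in% c("M4", "M5")
  par_names <- c(if (has_lbias) c("alpha0", "alpha1") else "alpha",
                 "tau",
                 if (has_noise) "xi",
                 if (has_go_bias) "b",
                 if (has_cue) "pi")
  box <- list(alpha = c(0, 1), alpha0 = c(0, 1), alpha1 = c(0, 1),
              tau = c(0, 50), xi = c(0, 1), b = c(-3, 3), pi = c(-3, 3))
  lower <- vapply(par_names, function(p) box[[p]][1], numeric(1))
  upper <- vapply(par_names, function(p) box[[p]][2], numeric(1))
  structure(list(id = id, has_noise = has_noise, has_go_bias = has_go_bias,
                 has_cue_response_bias = has_cue, has_learning_bias = has_lbias,
                 par_names = par_names, lower = lower, upper = upper,
                 n_free = length(par_names)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("RL model %s: %d free parameters (%s)\n", x$id, x$n_free,
              paste(x$par_names, collapse = ", ")))
  invisible(x)
}

#' All six model identifiers, simplest first
#' @export
gng_models <- c("M0", "M1", "M2", "M3", "M4", "M5")

# Expand a named free-parameter vector to the full internal layout
# c(alpha0, alpha1, tau, xi, b, pi); inactive components take neutral values.
full_par <- function(params, spec) {
  params <- check_params(params, spec)
  g <- function(nm, default) if (nm %in% names(params)) params[[nm]] else default
  a <- g("alpha", NA_real_)
  c(alpha0 = g("alpha0", a), alpha1 = g("alpha1", a),
    tau = params[["tau"]], xi = g("xi", 0), b = g("b", 0), pi = g("pi", 0))
}

check_params <- function(params, spec) {
  params <- unlist(params)
  missing <- setdiff(spec$par_names, names(params))
  if (length(missing))
    stop("invalid parameter: missing ", paste(missing, collapse = ", "),
         " for model ", spec$id)
  params <- params[spec$par_names]
  bad <- params < spec$lower - 1e-12 | params > spec$upper + 1e-12
  if (any(bad))
    stop("invalid parameter: ", paste(spec$par_names[bad], collapse = ", "),
         " outside box constraints")
  params
}

#' Rescorla-Wagner action-value update
#'
#' Moves the taken action's value toward the obtained reward by a fraction
#' `alpha_eff` of the prediction error: `q + alpha_eff * (r - q)`.
#'
#' @param q Current action value.
#' @param r Obtained reward, 0 or 1.
#' @param alpha_eff Effective learning rate in `[0, 1]`.
#' @return Updated action value.
#' @export
update_q <- function(q, r, alpha_eff) {
  if (any(alpha_eff < 0 | alpha_eff > 1))
    stop("invalid parameter: alpha must lie in [0, 1]")
  q + alpha_eff * (r - q)
}

#' Effective learning rate under the learning bias
#'
#' In learning-bias models (M4, M5) the faster rate `alpha0` applies when a
#' go response obtained an immediate reward or a no-go response obtained a
#' delayed reward; every other case -- including all no-reward outcomes
#' (`outcome_timing = "none"`) -- uses `alpha1`. Models without the bias
#' return the single rate `alpha`.
#'
#' @param action `"go"` or `"nogo"` (the taken action).
#' @param outcome_timing `"immediate"`, `"delayed"`, or `"none"` (no reward).
#' @param params Named parameter vector.
#' @param spec A [model_spec()].
#' @return The learning rate to apply on this trial.
#' @export
effective_learning_rate <- function(action, outcome_timing, params, spec) {
  p <- full_par(params, spec)
  if (!spec$has_learning_bias) return(unname(p[["alpha0"]]))
  fast <- (action == "go" & outcome_timing == "immediate") |
          (action == "nogo" & outcome_timing == "delayed")
  unname(ifelse(fast, p[["alpha0"]], p[["alpha1"]]))
}

#' Action weight of a response given the current action value
#'
#' The go weight adds the go bias `b` (when active) and the Pavlovian
#' cue-response term `pi * V_s` (when active), where `V_s` is +1 for
#' immediate-reward cues and -1 for delayed-reward cues; the no-go weight is
#' the bare action value.
#'
#' @param action `"go"` or `"nogo"`.
#' @param q Action value of `action` for the presented cue.
#' @param params Named parameter vector.
#' @param V_s Cue reward-timing value, +1 or -1.
#' @param spec A [model_spec()].
#' @return The action weight.
#' @export
action_weight <- function(action, q, params, V_s, spec) {
  p <- full_par(params, spec)
  ifelse(action == "go", q + p[["b"]] + p[["pi"]] * V_s, q)
}

#' Probability of a go response from action weights
#'
#' Softmax over `tau`-scaled weights mixed with a uniform lapse: `p =
#' softmax(tau * w)[go] * (1 - xi) + xi / 2`, bounded in
#' `[xi/2, 1 - xi/2]`.
#'
#' @param w_go,w_nogo Action weights.
#' @param tau Inverse temperature, in `[0, 50]`.
#' @param xi Irreducible noise (lapse probability), in `[0, 1]`.
#' @return Probability of responding go.
#' @export
#' @examples
#' choice_prob_go(1, 0, tau = 2, xi = 0.1)  # 0.9 * e^2/(e^2+1) + 0.05
choice_prob_go <- function(w_go, w_nogo, tau, xi = 0) {
  stopifnot(tau >= 0, xi >= 0, xi <= 1)
  m <- pmax(tau * w_go, tau * w_nogo)
  eg <- exp(tau * w_go - m)
  en <- exp(tau * w_nogo - m)
  eg / (eg + en) * (1 - xi) + xi / 2
}

# Encode a session/schedule into the integer covariates the C++ core expects.
encode_trials <- function(trials) {
  cond <- match(trials$condition, gng_conditions) - 1L
  if (anyNA(cond)) stop("invalid input: unknown condition labels")
  list(cond = cond,
       vs = ifelse(cond_timing(trials$condition) == "immediate", 1L, -1L))
}

#' Log-likelihood of one session under a model
#'
#' Evolves the model's action values along the observed trial sequence
#' (using the observed responses and outcomes) and sums the log-probability
#' of each observed response.
#'
#' @param params Named parameter vector for the model.
#' @param spec A [model_spec()].
#' @param session Session data frame with columns `condition`, `response`
#'   (`"go"`/`"nogo"`), `outcome` (`"reward"`/`"no-reward"`), in trial order.
#' @return The session log-likelihood (scalar).
#' @export
session_loglik <- function(params, spec, session) {
  if (is.null(session) || nrow(session) == 0)
    stop("invalid input: empty session")
  p <- full_par(params, spec)
  enc <- encode_trials(session)
  cpp_session_loglik(unname(p), enc$cond, enc$vs,
                     as.integer(session$response == "go"),
                     as.integer(session$outcome == "reward"))
}

#' Simulate an agent on a task schedule
#'
#' Generates responses generatively: per trial the model's go probability is
#' computed from the current action values, an action is drawn, correctness
#' is determined against the required action, probabilistic feedback is
#' resolved, and the taken action's value is updated with the effective
#' learning rate.
#'
#' @param params Named parameter vector.
#' @param spec A [model_spec()].
#' @param schedule A [generate_schedule()] result.
#' @param seed Integer seed; identical seeds reproduce the session.
#' @param participant_id Identifier stored in the output.
#' @return Session data frame: `participant_id`, `trial`, `block`,
#'   `condition`, `required_action`, `reward_timing`, `feedback_valid`,
#'   `response`, `correct`, `outcome`, `p_go`, `rt_ms` (NA here; filled by
#'   the cohort generator).
#' @export
simulate_agent <- function(params, spec, schedule, seed = 1L,
                           participant_id = "agent1") {
  p <- full_par(params, spec)
  enc <- encode_trials(schedule)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  sim <- cpp_simulate_agent(unname(p), enc$cond, enc$vs,
                            as.integer(schedule$required_action == "go"),
                            as.integer(schedule$feedback_valid))
  idx <- if (!is.null(schedule$index)) schedule$index else schedule$trial
  data.frame(
    participant_id = participant_id,
    trial = idx,
    block = schedule$block,
    condition = schedule$condition,
    required_action = schedule$required_action,
    reward_timing = schedule$reward_timing,
    feedback_valid = schedule$feedback_valid,
    response = ifelse(sim$response == 1, "go", "nogo"),
    correct = sim$correct == 1,
    outcome = ifelse(sim$outcome == 1, "reward", "no-reward"),
    p_go = sim$p_go,
    rt_ms = NA_real_,
    stringsAsFactors = FALSE
  )
}
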