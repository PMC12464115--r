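# Shared test helpers: a deliberately plain, loop-and-data-frame R
# implementation of the model family, kept independent of the package's
# computational path, plus small constructors for hand-built sessions.

# Reference log-likelihood: direct transcription of the update, weight and
# choice equations with explicit per-trial state.
oracle_loglik <- function(params, model_id, session) {
  p <- as.list(params)
  a0 <- if (!is.null(p$alpha0)) p$alpha0 else p$alpha
  a1 <- if (!is.null(p$alpha1)) p$alpha1 else p$alpha
  xi <- if (!is.null(p$xi)) p$xi else 0
  b <- if (!is.null(p$b)) p$b else 0
  pp <- if (!is.null(p$pi)) p$pi else 0
  tau <- p$tau
  Q <- matrix(0, nrow = 4, ncol = 2,
              dimnames = list(gng_conditions, c("nogo", "go")))
  ll <- 0
  for (t in seq_len(nrow(session))) {
    cnd <- session$condition[t]
    vs <- if (grepl("immediate", cnd)) 1 else -1
    wg <- Q[cnd, "go"] + b + pp * vs
    wn <- Q[cnd, "nogo"]
    pg <- exp(tau * wg) / (exp(tau * wg) + exp(tau * wn)) * (1 - xi) + xi / 2
    pobs <- if (session$response[t] == "go") pg else 1 - pg
    ll <- ll + log(max(pobs, 1e-12))
    r <- as.integer(session$outcome[t] == "reward")
    act <- session$response[t]
    fast <- r == 1 && ((act == "go" && vs == 1) || (act == "nogo" && vs == -1))
    ae <- if (model_id %in% c("M4", "M5")) { if (fast) a0 else a1 } else a0
    Q[cnd, act] <- Q[cnd, act] + ae * (r - Q[cnd, act])
  }
  ll
}

# Minimal session constructor from parallel vectors.
make_session <- function(condition, response, outcome, participant_id = "t1") {
  n <- length(condition)
  data.frame(
    participant_id = participant_id, trial = seq_len(n),
    block = rep(1L, n), condition = condition,
    required_action = ifelse(grepl("^go-", condition), "go", "nogo"),
    reward_timing = ifelse(grepl("immediate", condition), "immediate", "delayed"),
    feedback_valid = rep(TRUE, n), response = response,
    correct = response == ifelse(grepl("^go-", condition), "go", "nogo"),
    outcome = outcome, rt_ms = NA_real_, stringsAsFactors = FALSE)
}

# Outcomes implied by a response sequence on a schedule with fixed
# feedback-validity flags.
outcomes_for <- function(condition, feedback_valid, response) {
  required <- ifelse(grepl("^go-", condition), "go", "nogo")
  correct <- response == required
  ifelse(feedback_valid, ifelse(correct, "reward", "no-reward"),
         ifelse(correct, "no-reward", "reward"))
}

# Default parameter sets giving every model its own non-neutral values.
test_params <- function(model_id) {
  switch(model_id,
         M0 = c(alpha = 0.3, tau = 4),
         M1 = c(alpha = 0.3, tau = 4, xi = 0.15),
         M2 = c(alpha = 0.3, tau = 4, xi = 0.15, b = 0.4),
         M3 = c(alpha = 0.3, tau = 4, xi = 0.15, b = 0.4, pi = 0.3),
         M4 = c(alpha0 = 0.45, alpha1 = 0.2, tau = 4, xi = 0.15, b = 0.4),
         M5 = c(alpha0 = 0.45, alpha1 = 0.2, tau = 4, xi = 0.15, b = 0.4,
                pi = 0.3))
}

# Quick optimizer settings for tests where full precision is unnecessary.
fast_control <- de_control(maxiter = 120, stall = 30)
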