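test_that("model specifications encode the nesting structure", {
  expect_equal(vapply(gng_models, function(m) model_spec(m)$n_free, 1L),
               c(M0 = 2L, M1 = 3L, M2 = 4L, M3 = 5L, M4 = 5L, M5 = 6L))
  m3 <- model_spec("M3")
  expect_true(m3$has_cue_response_bias && !m3$has_learning_bias)
  m4 <- model_spec("M4")
  expect_true(m4$has_learning_bias && m4$has_go_bias && !m4$has_cue_response_bias)
  expect_equal(unname(m3$lower), c(0, 0, 0, -3, -3))
  expect_equal(unname(m3$upper), c(1, 50, 1, 3, 3))
})

test_that("value update follows the prediction-error rule", {
  expect_equal(update_q(0, 1, 0.5), 0.5)
  expect_equal(update_q(0.7, 0.7, 0.3), 0.7)  # zero prediction error
  expect_equal(update_q(0.5, 0, 0.2), 0.4)
  expect_error(update_q(0, 1, 1.5), "invalid parameter")
})

test_that("effective learning rate applies the outcome-contingent bias", {
  m4 <- model_spec("M4")
  p4 <- test_params("M4")
  expect_equal(effective_learning_rate("go", "immediate", p4, m4), 0.45)
  expect_equal(effective_learning_rate("go", "delayed", p4, m4), 0.2)
  expect_equal(effective_learning_rate("nogo", "delayed", p4, m4), 0.45)
  expect_equal(effective_learning_rate("nogo", "immediate", p4, m4), 0.2)
  expect_equal(effective_learning_rate("go", "none", p4, m4), 0.2)
  # inactive without the learning bias
  m3 <- model_spec("M3")
  expect_equal(effective_learning_rate("go", "immediate", test_params("M3"), m3),
               0.3)
})

test_that("action weights add the go and cue-response biases to go only", {
  m3 <- model_spec("M3")
  p <- c(alpha = 0.2, tau = 5, xi = 0, b = 0.09, pi = 0.05)
  expect_equal(action_weight("go", 0.3, p, 1, m3), 0.44)
  expect_equal(action_weight("go", 0.3, p, -1, m3), 0.34)
  expect_equal(action_weight("nogo", 0.3, p, 1, m3), 0.3)
  p0 <- c(alpha = 0.2, tau = 5, xi = 0, b = 0, pi = 0)
  expect_equal(action_weight("go", 0.3, p0, 1, m3), 0.3)
})

test_that("choice probabilities obey the lapse-bounded softmax", {
  expect_equal(choice_prob_go(0.4, 0.4, 3, 0), 0.5)
  expect_equal(choice_prob_go(5, -5, 10, 1), 0.5)  # pure lapse
  expect_equal(choice_prob_go(1, 0, 2, 0.1),
               0.9 * exp(2) / (exp(2) + 1) + 0.05, tolerance = 1e-12)
  expect_equal(choice_prob_go(1, 0, 2, 0.1), 0.8427, tolerance = 1e-4)
  # probability conservation and noise bounding over random settings
  set.seed(2)
  for (i in 1:200) {
    wg <- rnorm(1, 0, 2); wn <- rnorm(1, 0, 2)
    tau <- runif(1, 0, 50); xi <- runif(1)
    pg <- choice_prob_go(wg, wn, tau, xi)
    pn <- choice_prob_go(wn, wg, tau, xi)
    expect_equal(pg + pn, 1, tolerance = 1e-12)
    expect_gte(pg, xi / 2 - 1e-12)
    expect_lte(pg, 1 - xi / 2 + 1e-12)
  }
  # numerically stable at extreme weights
  expect_equal(choice_prob_go(300, -300, 50, 0), 1)
})

test_that("session log-likelihood matches the independent reference implementation", {
  sched <- generate_schedule(5, 2, 0.8, seed = 4)
  for (m in gng_models) {
    spec <- model_spec(m)
    p <- test_params(m)
    ses <- simulate_agent(p, spec, sched, seed = 9)
    expect_equal(session_loglik(p, spec, ses), oracle_loglik(p, m, ses),
                 tolerance = 1e-10)
  }
  # single symmetric trial is forced to probability one half
  ses1 <- make_session("go-immediate", "go", "reward")
  expect_equal(session_loglik(c(alpha = 0.3, tau = 5), model_spec("M0"), ses1),
               log(0.5))
  expect_error(session_loglik(test_params("M0"), model_spec("M0"),
                              ses1[0, ]), "invalid input")
})

test_that("each model reduces to its parent at the neutral parameter value", {
  sched <- generate_schedule(8, 2, 0.8, seed = 6)
  ses <- simulate_agent(test_params("M5"), model_spec("M5"), sched, seed = 10)
  pairs <- list(
    list(child = "M1", parent = "M0", childp = c(alpha = 0.3, tau = 4, xi = 0),
         parentp = c(alpha = 0.3, tau = 4)),
    list(child = "M2", parent = "M1",
         childp = c(alpha = 0.3, tau = 4, xi = 0.15, b = 0),
         parentp = c(alpha = 0.3, tau = 4, xi = 0.15)),
    list(child = "M3", parent = "M2",
         childp = c(alpha = 0.3, tau = 4, xi = 0.15, b = 0.4, pi = 0),
         parentp = c(alpha = 0.3, tau = 4, xi = 0.15, b = 0.4)),
    list(child = "M4", parent = "M2",
         childp = c(alpha0 = 0.3, alpha1 = 0.3, tau = 4, xi = 0.15, b = 0.4),
         parentp = c(alpha = 0.3, tau = 4, xi = 0.15, b = 0.4)),
    list(child = "M5", parent = "M3",
         childp = c(alpha0 = 0.3, alpha1 = 0.3, tau = 4, xi = 0.15, b = 0.4,
                    pi = 0.3),
         parentp = c(alpha = 0.3, tau = 4, xi = 0.15, b = 0.4, pi = 0.3)),
    list(child = "M5", parent = "M4",
         childp = c(alpha0 = 0.45, alpha1 = 0.2, tau = 4, xi = 0.15, b = 0.4,
                    pi = 0),
         parentp = c(alpha0 = 0.45, alpha1 = 0.2, tau = 4, xi = 0.15, b = 0.4)))
  for (pr in pairs) {
    expect_equal(
      session_loglik(pr$childp, model_spec(pr$child), ses),
      session_loglik(pr$parentp, model_spec(pr$parent), ses),
      tolerance = 1e-12, label = paste(pr$child, "vs", pr$parent))
  }
})

test_that("response-sequence probabilities sum to one on short schedules", {
  # random 3- and 4-trial schedules with mixed feedback validity
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(3:4, 1)
    cnd <- sample(gng_conditions, n, replace = TRUE)
    valid <- runif(n) < 0.7
    seqs <- expand.grid(rep(list(c("go", "nogo")), n),
                        stringsAsFactors = FALSE)
    for (m in gng_models) {
      spec <- model_spec(m)
      p <- test_params(m)
      total <- sum(apply(seqs, 1, function(resp) {
        ses <- make_session(cnd, unname(resp), outcomes_for(cnd, valid, resp))
        exp(session_loglik(p, spec, ses))
      }))
      expect_equal(total, 1, tolerance = 1e-10, label = m)
    }
  }
})

test_that("simulation is seed-reproducible and respects degenerate parameters", {
  sched <- generate_schedule(50, 2, 0.8, seed = 15)
  spec <- model_spec("M3")
  p <- test_params("M3")
  a <- simulate_agent(p, spec, sched, seed = 77)
  b <- simulate_agent(p, spec, sched, seed = 77)
  expect_identical(a, b)

  # pure lapse: go rate near one half in every condition
  lapse <- simulate_agent(c(alpha = 0.3, tau = 4, xi = 1), model_spec("M1"),
                          sched, seed = 3)
  expect_lt(abs(mean(lapse$response == "go") - 0.5), 0.12)

  # frozen symmetric state: no learning, no biases
  frozen <- do.call(rbind, lapply(1:20, function(s)
    simulate_agent(c(alpha = 0, tau = 4, xi = 0, b = 0, pi = 0),
                   model_spec("M3"), sched, seed = 100 + s)))
  expect_lt(abs(mean(frozen$response == "go") - 0.5), 0.03)
})

test_that("the cue-response bias shifts go rates by reward timing", {
  sched <- generate_schedule(25, 2, 0.8, seed = 16)
  spec <- model_spec("M3")
  p <- c(alpha = 0.1, tau = 10, xi = 0, b = 0, pi = 1)
  sims <- do.call(rbind, lapply(1:60, function(s)
    simulate_agent(p, spec, sched, seed = 500 + s)))
  go <- sims$response == "go"
  imm <- mean(go[sims$reward_timing == "immediate"])
  del <- mean(go[sims$reward_timing == "delayed"])
  expect_gt(imm, del + 0.2)

  # monotonicity in pi
  rates <- vapply(c(0, 0.5, 1), function(pi_val) {
    sims <- do.call(rbind, lapply(1:30, function(s)
      simulate_agent(c(alpha = 0.1, tau = 10, xi = 0, b = 0, pi = pi_val),
                     spec, sched, seed = 900 + s)))
    mean(sims$response[sims$reward_timing == "immediate"] == "go")
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})
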