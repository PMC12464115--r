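test_that("the design table uses sum-to-zero codes and centred block", {
  cfg <- cohort_config(n_participants = 3, n_per_condition = 10)
  coh <- generate_cohort(cfg, seed = 90)
  d <- build_design(coh$trials)
  expect_equal(sort(unique(d$action_code)), c(-1, 1))
  expect_equal(sort(unique(d$reward_code)), c(-1, 1))
  expect_equal(mean(d$block_c), 0)
  imm_go <- coh$trials$required_action == "go" &
    coh$trials$reward_timing == "immediate"
  expect_true(all(d$action_code[imm_go] == 1 & d$reward_code[imm_go] == 1))

  # supplying a covariate doubles the factorial fixed-effect expansion
  mh <- data.frame(participant_id = unique(d$participant_id),
                   score = c(1, 4, 9))
  d2 <- build_design(coh$trials, mh)
  expect_equal(mean(d2$mh), 0, tolerance = 1e-12)
  t1 <- fit_response_bias(d, re = "intercept")
  t2 <- fit_response_bias(d2, re = "intercept")
  expect_equal(nrow(t1), 8)
  expect_equal(nrow(t2), 16)
  expect_error(build_design(coh$trials[1:3, ]), "invalid input")
})

test_that("a planted reward effect is recovered with interval coverage", {
  trials <- simulate_bias_cohort(n_agents = 60, effect_reward = 0.5,
                                 sd_reward = 0.4, seed = 91)
  tab <- fit_response_bias(build_design(trials))
  row <- tab[tab$effect == "reward_code", ]
  expect_true(row$lower <= 0.5 && row$upper >= 0.5)
  expect_true(row$significant)
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
})

test_that("relabeling reward levels flips the reward coefficient's sign", {
  trials <- simulate_bias_cohort(n_agents = 25, effect_reward = 0.4,
                                 n_per_condition = 20, seed = 92)
  flipped <- trials
  flipped$reward_timing <- ifelse(trials$reward_timing == "immediate",
                                  "delayed", "immediate")
  t1 <- fit_response_bias(build_design(trials), re = "intercept")
  t2 <- fit_response_bias(build_design(flipped), re = "intercept")
  r1 <- t1$estimate[t1$effect == "reward_code"]
  r2 <- t2$estimate[t2$effect == "reward_code"]
  expect_equal(r1, -r2, tolerance = 1e-6)
  a1 <- t1$estimate[t1$effect == "action_code"]
  a2 <- t2$estimate[t2$effect == "action_code"]
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("the RT model recovers planted log-scale effects and absorbs shifts", {
  cfg <- cohort_config(n_participants = 25, n_per_condition = 25,
                       rt = list(shift = 150, meanlog = log(180), sdlog = 0.25,
                                 eff_reward = -0.06, eff_action = 0.02,
                                 eff_interaction = 0.04, eff_block = -0.01))
  coh <- generate_cohort(cfg, seed = 93)
  d <- build_design(coh$trials)
  tab <- fit_rt_bias(d, re = "intercept")
  expect_equal(attr(tab, "shift"), 150, tolerance = 40)
  rw <- tab[tab$effect == "reward_code", ]
  expect_lt(abs(rw$estimate - (-0.06)), 0.03)
  expect_true(rw$significant)
  ia <- tab[tab$effect == "action_code:reward_code", ]
  expect_lt(abs(ia$estimate - 0.04), 0.03)

  # a constant added to every RT moves the shift, not the slopes
  d2 <- d
  d2$rt_ms <- d$rt_ms + 100
  tab2 <- fit_rt_bias(d2, re = "intercept")
  expect_equal(attr(tab2, "shift") - attr(tab, "shift"), 100, tolerance = 40)
  expect_equal(tab2$estimate[tab2$effect == "reward_code"], rw$estimate,
               tolerance = 0.02)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  bh <- bh_adjust(c(0.01, 0.02, 0.04, 0.05), q = 0.05)
  expect_true(all(bh$rejected))   # largest p equals 0.05 * 4/4
  bh2 <- bh_adjust(0.06, q = 0.05)
  expect_false(bh2$rejected)
  bh3 <- bh_adjust(rep(0.001, 10), q = 0.05)
  expect_true(all(bh3$rejected))
  expect_equal(bh3$adjusted, rep(0.001, 10))
  # rejections are a subset of unadjusted ones and monotone in q
  set.seed(94)
  p <- runif(20)^2
  r1 <- bh_adjust(p, 0.05)$rejected
  expect_true(all(p[r1] <= 0.05))
  r2 <- bh_adjust(p, 0.1)$rejected
  expect_true(all(r1 <= r2))
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("a single covariate at q = 0.05 reduces to the unadjusted rule", {
  mh_tab <- data.frame(participant_id = sprintf("s%04d", 1:30),
                       cov1 = rnorm(30))
  trials <- simulate_bias_cohort(n_agents = 30, effect_reward = 0.3,
                                 n_per_condition = 15, seed = 95)
  scan <- moderation_scan(trials, mh_tab, which = "response", re = "intercept")
  expect_equal(nrow(scan$summary), 1)
  expect_equal(scan$summary$p_adj, scan$summary$tail_p)
  expect_equal(scan$summary$significant, scan$summary$tail_p <= 0.05)
})

test_that("a planted reward-by-symptom moderation is detected", {
  set.seed(96)
  mh <- rnorm(60)
  trials <- simulate_bias_cohort(n_agents = 60, effect_reward = 0.2,
                                 sd_reward = 0.3, mh = mh, beta_mh = 0.6,
                                 n_per_condition = 25, seed = 97)
  mh_tab <- data.frame(participant_id = sprintf("s%04d", 1:60), sym = mh)
  scan <- moderation_scan(trials, mh_tab, which = "response")
  expect_gt(scan$summary$estimate, 0)
  expect_true(scan$summary$significant)
})

test_that("correlations with covariates use Pearson r with BH control", {
  mh_tab <- data.frame(participant_id = sprintf("p%03d", 1:40),
                       a = 1:40 + rnorm(40, 0, 1e-8), b = rnorm(40))
  v <- setNames(1:40, sprintf("p%03d", 1:40))
  out <- correlate_with_mh(v, mh_tab)
  expect_equal(out$r[out$covariate == "a"], 1, tolerance = 1e-6)
  outn <- correlate_with_mh(setNames(-(1:40), names(v)),
                            mh_tab[c("participant_id", "a")])
  expect_equal(outn$r, -1, tolerance = 1e-6)

  # independent normals at the study's sample size rarely exceed |r| = 0.15
  set.seed(98)
  rs <- replicate(500, cor(rnorm(389), rnorm(389)))
  expect_gte(mean(abs(rs) < 0.15), 0.99)

  expect_error(correlate_with_mh(v[1:2], mh_tab[1:2, ]), "invalid input")
})
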