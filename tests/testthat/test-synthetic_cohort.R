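test_that("true parameter draws respect boxes and configured locations", {
  cfg <- cohort_config(n_participants = 400)
  params <- sample_params(cfg, seed = 80)
  spec <- model_spec("M3")
  for (j in seq_along(spec$par_names)) {
    pn <- spec$par_names[j]
    expect_true(all(params[[pn]] >= spec$lower[j] &
                    params[[pn]] <= spec$upper[j]))
  }
  # cohort means near the configured locations (truncation shifts alpha and
  # xi upward slightly, so allow a little beyond 2 SEM for those)
  for (pn in c("tau", "b", "pi")) {
    sem <- cfg$param_sd[[pn]] / sqrt(400)
    expect_lt(abs(mean(params[[pn]]) - cfg$param_mean[[pn]]), 3 * sem)
  }

  # degenerate scales reproduce the locations exactly
  cfg0 <- cohort_config(n_participants = 5,
                        param_sd = c(alpha = 0, tau = 0, xi = 0, b = 0, pi = 0))
  p0 <- sample_params(cfg0, seed = 81)
  expect_true(all(p0$alpha == 0.21 & p0$tau == 7.33 & p0$pi == 0.05))
})

test_that("mental-health covariates achieve the configured link to the true bias", {
  cfg <- cohort_config(n_participants = 1000,
                       mh = list(names = c("null_cov", "linked_cov"),
                                 cor_pi = c(0, 0.5),
                                 dist = c("normal", "normal"),
                                 mean = 0, sd = 1))
  pi_true <- rnorm(1000, 0.05, 0.3)
  mh <- sample_mh(cfg, pi_true, seed = 82)
  expect_lt(abs(cor(mh$null_cov, pi_true)), 0.1)
  expect_lt(abs(cor(mh$linked_cov, pi_true) - 0.5), 0.1)

  # skewed marginals approximately preserve the configured correlation
  cfg_skew <- cohort_config(n_participants = 1000,
                            mh = list(names = "symptoms", cor_pi = 0.5,
                                      dist = "skew", mean = 5, sd = 5))
  mhs <- sample_mh(cfg_skew, pi_true, seed = 83)
  expect_gt(min(mhs$symptoms), 0)
  expect_gt(cor(mhs$symptoms, pi_true), 0.35)

  expect_error(
    sample_mh(cohort_config(mh = list(names = "x", cor_pi = 0,
                                      dist = "normal", mean = 0, sd = 0)),
              pi_true, 84),
    "invalid configuration")
  expect_error(
    cohort_config(mh = list(names = "x", cor_pi = 1.2, dist = "normal",
                            mean = 0, sd = 1)),
    "invalid configuration")
})

test_that("response times are shifted-lognormal inside the response window", {
  rtc <- list(shift = 150, meanlog = log(180), sdlog = 0, eff_reward = 0,
              eff_action = 0, eff_interaction = 0, eff_block = 0)
  expect_equal(sample_rt(1, 1, 0, rtc), 150 + 180)

  rtc$sdlog <- 0.3
  set.seed(85)
  rts <- sample_rt(rep(1, 5000), rep(1, 5000), rep(0, 5000), rtc)
  expect_true(all(rts > 150 & rts <= 600))

  # a negative immediate effect speeds immediate-reward go responses
  rtc$eff_reward <- -0.1
  set.seed(86)
  imm <- sample_rt(rep(1, 4000), rep(1, 4000), rep(0, 4000), rtc)
  del <- sample_rt(rep(-1, 4000), rep(1, 4000), rep(0, 4000), rtc)
  expect_lt(median(imm), median(del))

  rtc$sdlog <- 0
  rtc$meanlog <- log(700)
  expect_error(sample_rt(1, 1, 0, rtc), "invalid configuration")
})

test_that("generated cohorts are complete, reproducible, and round-trip", {
  cfg <- cohort_config(n_participants = 6, n_per_condition = 10)
  coh <- generate_cohort(cfg, seed = 87)
  expect_s3_class(coh, "gng_cohort")
  expect_equal(nrow(coh$trials), 6 * 40)
  expect_equal(nrow(coh$params_true), 6)
  expect_equal(nrow(coh$titration), 6)
  expect_equal(nrow(coh$mh), 6)
  go <- coh$trials$response == "go"
  expect_true(all(is.finite(coh$trials$rt_ms[go])))
  expect_true(all(is.na(coh$trials$rt_ms[!go])))
  expect_true(all(coh$trials$rt_ms[go] <= 600))

  coh2 <- generate_cohort(cfg, seed = 87)
  expect_identical(coh$trials, coh2$trials)
  expect_identical(coh$mh, coh2$mh)

  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("trials.csv", "params_true.csv",
                                               "titration.csv",
                                               "mental_health.csv",
                                               "config.json")))))
  back <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(back, coh$trials, ignore_attr = TRUE)
})

test_that("a strong cue-response bias shows up in condition go rates end to end", {
  cfg <- cohort_config(n_participants = 12, n_per_condition = 25,
                       param_mean = c(alpha = 0.21, tau = 7.33, xi = 0.17,
                                      b = 0.09, pi = 0.5),
                       param_sd = c(alpha = 0.1, tau = 2, xi = 0.1,
                                    b = 0.2, pi = 0.1))
  coh <- generate_cohort(cfg, seed = 88)
  go <- coh$trials$response == "go"
  diff <- mean(go[coh$trials$reward_timing == "immediate"]) -
    mean(go[coh$trials$reward_timing == "delayed"])
  expect_gt(diff, 0.05)
})

test_that("titration results in generated cohorts are internally consistent", {
  cfg <- cohort_config(n_participants = 20, n_per_condition = 5,
                       titration_temperature = 0)
  coh <- generate_cohort(cfg, seed = 89)
  tt <- coh$titration
  conv <- tt[tt$converged, ]
  expect_gt(nrow(conv), 0)
  expect_true(all(conv$matched_amount >= 0 & conv$matched_amount <= 28))
  # noiseless agents land within one step of their true indifference point
  pv <- 28 / (1 + conv$k_true * 120)
  expect_true(all(abs(conv$matched_amount - pv) <= 2.5))
  expect_equal(conv$impatience[conv$matched_amount >= 1],
               29 - conv$matched_amount[conv$matched_amount >= 1])
})
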