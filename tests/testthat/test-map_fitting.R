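test_that("log posterior adds closed-form prior densities to the likelihood", {
  sched <- generate_schedule(5, 2, 0.8, seed = 30)
  ses <- simulate_agent(test_params("M3"), model_spec("M3"), sched, seed = 31)

  # M0: only tau carries a non-uniform prior
  p0 <- c(alpha = 0.3, tau = 10)
  lp <- log_posterior(p0, model_spec("M0"), ses)
  ll <- session_loglik(p0, model_spec("M0"), ses)
  tau_prior <- 3 * log(0.3) + 2 * log(10) - 0.3 * 10 - lgamma(3)
  expect_equal(lp - ll, tau_prior, tolerance = 1e-10)
  expect_equal(dgamma(10, 3, rate = 0.3, log = TRUE), tau_prior)

  # Gaussian(0,1) prior at b = 0 contributes -log(sqrt(2*pi))
  p2 <- c(alpha = 0.3, tau = 10, xi = 0.1, b = 0)
  lp2 <- log_posterior(p2, model_spec("M2"), ses)
  ll2 <- session_loglik(p2, model_spec("M2"), ses)
  expect_equal(lp2 - ll2 - tau_prior, log(1 / sqrt(2 * pi)), tolerance = 1e-10)

  expect_error(log_posterior(c(alpha = 1.4, tau = 5), model_spec("M0"), ses),
               "invalid parameter")
})

test_that("AIC follows its definition and the family's parameter counts", {
  expect_equal(aic(-100, 5), 210)
  expect_equal(aic(0, 0), 0)
  ks <- vapply(gng_models, function(m) model_spec(m)$n_free, 1L)
  expect_equal(unname(ks), c(2, 3, 4, 5, 5, 6))
  expect_error(aic(-10, -1))
})

test_that("MAP fits are deterministic, boxed, and self-consistent at large T", {
  sched <- generate_schedule(500, 2, 0.8, seed = 40)
  true <- c(alpha = 0.3, tau = 5)
  ses <- simulate_agent(true, model_spec("M0"), sched, seed = 41)
  f1 <- gng_fit(ses, "M0", seed = 42)
  f2 <- gng_fit(ses, "M0", seed = 42)
  expect_identical(f1$par, f2$par)
  expect_true(all(f1$par >= model_spec("M0")$lower &
                  f1$par <= model_spec("M0")$upper))
  expect_lt(abs(f1$par[["alpha"]] - 0.3), 0.1)
  expect_lt(abs(f1$par[["tau"]] - 5), 2)
  # the reported likelihood is the pure likelihood at the MAP point
  expect_equal(f1$loglik, session_loglik(f1$par, f1$spec, ses))
  expect_equal(f1$aic, 2 * 2 - 2 * f1$loglik)
})

test_that("fitted children attain at least their parent's likelihood", {
  sched <- generate_schedule(50, 2, 0.8, seed = 43)
  ses <- simulate_agent(test_params("M3"), model_spec("M3"), sched, seed = 44)
  lls <- vapply(c("M0", "M1", "M2", "M3"), function(m)
    gng_fit(ses, m, seed = 45)$loglik, numeric(1))
  tol <- 0.05  # optimizer tolerance
  expect_true(all(diff(lls) > -tol))
  m5 <- gng_fit(ses, "M5", seed = 45)$loglik
  expect_gt(m5, gng_fit(ses, "M4", seed = 45)$loglik - tol)
  expect_gt(m5, lls[["M3"]] - tol)
})

test_that("fit object methods expose coefficients, likelihood, and predictions", {
  sched <- generate_schedule(25, 2, 0.8, seed = 46)
  ses <- simulate_agent(test_params("M3"), model_spec("M3"), sched, seed = 47)
  fit <- gng_fit(ses, "M3", seed = 48, control = fast_control)
  expect_named(coef(fit), c("alpha", "tau", "xi", "b", "pi"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 5)
  expect_equal(AIC(fit), fit$aic)
  pg <- predict(fit)
  expect_length(pg, nrow(ses))
  expect_true(all(pg >= 0 & pg <= 1))
  r <- residuals(fit)
  expect_equal(r, as.integer(ses$response == "go") - pg)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(ses))
  expect_output(print(fit), "MAP fit of model M3")
  expect_output(print(summary(fit)), "go rate")
})

test_that("cohort fitting produces a complete reproducible grid", {
  cfg <- cohort_config(n_participants = 3)
  coh <- generate_cohort(cfg, seed = 50)
  fits <- fit_cohort(coh, models = c("M0", "M2"), control = fast_control,
                     seed = 51)
  expect_equal(nrow(fits), 6)
  expect_equal(sort(unique(fits$model)), c("M0", "M2"))
  expect_true(all(is.finite(fits$aic)))
  fits2 <- fit_cohort(coh, models = c("M0", "M2"), control = fast_control,
                      seed = 51)
  expect_identical(fits, fits2)
})

test_that("model frequency splits ties and sums to one", {
  tab <- data.frame(
    participant_id = rep(1:5, each = 2),
    model = rep(c("M0", "M3"), 5),
    aic = c(10, 9, 10, 9, 10, 9, 9, 10, 9, 10))
  f <- model_frequency(tab)
  expect_equal(unname(f[["M3"]]), 0.6)
  expect_equal(sum(f), 1)

  tie <- data.frame(participant_id = rep(1, 6), model = gng_models,
                    aic = rep(100, 6))
  ft <- model_frequency(tie)
  expect_equal(unname(ft), rep(1 / 6, 6))

  set.seed(9)
  for (i in 1:20) {
    rnd <- data.frame(participant_id = rep(1:4, each = 3),
                      model = rep(c("A", "B", "C"), 4),
                      aic = round(rnorm(12), 2))
    expect_equal(sum(model_frequency(rnd)), 1)
  }
  expect_error(model_frequency(tab[-1, ]), "invalid input")
})
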