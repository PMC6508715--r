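os_table3 <- hazard_params("constant", lambda0 = 1e-4, delta_stage = 1e-4,
                           delta_linitis = 2e-4, beta_met = 3.43)

test_that("hazard composition: additive baseline, multiplicative metastasis", {
  expect_equal(hazard_at(os_table3, 100), 1e-4)
  expect_equal(hazard_at(os_table3, 100, linitis = TRUE), 3e-4)
  expect_equal(hazard_at(os_table3, 100, stage3 = TRUE, linitis = TRUE), 4e-4)
  # after the metastasis switch the rate is multiplied by exp(3.43)
  expect_equal(hazard_at(os_table3, 1500, t_met = 1000), 1e-4 * exp(3.43))
  expect_equal(hazard_at(os_table3, 1500, t_met = 1000), 3.088e-3, tolerance = 1e-3)
  expect_equal(hazard_at(os_table3, 500, t_met = 1000), 1e-4) # before the switch
  expect_error(hazard_params("constant", lambda0 = 1e-4, delta_stage = -2e-4),
               "non-positive")
})

test_that("cumulative hazard has exact piecewise closed form", {
  expect_identical(cumulative_hazard(os_table3, 0), 0)
  expect_equal(cumulative_hazard(os_table3, 2920), 0.292)
  expect_equal(cumulative_hazard(os_table3, 2000, t_met = 1000),
               0.1 + 0.1 * exp(3.43), tolerance = 1e-12)
  expect_equal(cumulative_hazard(os_table3, 2000, t_met = 1000), 3.188,
               tolerance = 1e-3)
})

test_that("survival probabilities are coherent and monotone", {
  expect_identical(survival_prob(os_table3, 0), 1)
  expect_equal(survival_prob(os_table3, 2920), exp(-0.292))
  expect_equal(survival_prob(os_table3, 2920), 0.747, tolerance = 1e-3)
  set.seed(3)
  for (i in 1:20) {
    fam <- sample(c("constant", "weibull", "gompertz"), 1)
    p <- hazard_params(fam, lambda0 = 10^runif(1, -5, -3),
                       shape = if (fam == "constant") NULL else
                         if (fam == "weibull") runif(1, 0.5, 2) else runif(1, -1e-3, 1e-3),
                       delta_stage = runif(1, 0, 2e-4), beta_met = runif(1, 0, 3))
    tt <- sort(runif(6, 0, 4000))
    S <- survival_prob(p, tt, stage3 = TRUE, t_met = 1200)
    H <- cumulative_hazard(p, tt, stage3 = TRUE, t_met = 1200)
    expect_true(all(diff(S) <= 1e-15))
    expect_true(all(diff(H) >= -1e-15))
    expect_true(all(H >= 0))
  }
})

test_that("closed-form cumulative hazards match numeric integration", {
  for (fam in c("constant", "weibull", "gompertz")) {
    p <- hazard_params(fam, lambda0 = 2e-4,
                       shape = switch(fam, constant = NULL, weibull = 1.4,
                                      gompertz = 4e-4),
                       delta_linitis = 1e-4, beta_met = 2)
    for (tt in c(500, 1500, 2500)) {
      num <- stats::integrate(function(s) hazard_at(p, s, linitis = TRUE,
                                                    t_met = 1000),
                              0, tt, rel.tol = 1e-11, subdivisions = 500L)$value
      expect_equal(cumulative_hazard(p, tt, linitis = TRUE, t_met = 1000), num,
                   tolerance = 1e-8)
    }
  }
})

test_that("event log-likelihood matches closed forms", {
  # one observed subject under a constant hazard: log(lambda) - lambda * t
  d1 <- mk_event_data(time = 730, observed = TRUE)
  lam <- 3e-4
  p <- hazard_params("constant", lam)
  expect_equal(event_loglik(p, d1), log(lam) - lam * 730)
  # the analytic maximum sits at lambda = 1/t
  lams <- c(1 / 730 * 0.5, 1 / 730, 1 / 730 * 2)
  lls <- vapply(lams, function(l) event_loglik(hazard_params("constant", l), d1),
                numeric(1))
  expect_identical(which.max(lls), 2L)
  # all-censored data: -sum(HZ), strictly decreasing in lambda
  dc <- mk_event_data(time = c(400, 900, 1300), observed = FALSE)
  expect_equal(event_loglik(p, dc), -lam * sum(dc$time))
  expect_gt(event_loglik(hazard_params("constant", 1e-4), dc),
            event_loglik(hazard_params("constant", 2e-4), dc))
  expect_error(event_loglik(p, mk_event_data(time = 0, observed = TRUE)),
               "positive")
})

test_that("constant-hazard MLE equals deaths over person-time", {
  set.seed(11)
  n <- 500
  tt <- rexp(n, 2.5e-4)
  cens <- runif(n, 500, 4000)
  d <- mk_event_data(time = pmin(tt, cens), observed = tt <= cens)
  fit <- fit_survival_model(d, covariates = character(0), metastasis = FALSE)
  closed <- sum(d$observed) / sum(d$time)
  expect_equal(unname(fit$estimates["lambda0"]), closed, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("no observed event aborts the fit with a clear message", {
  d <- mk_event_data(time = c(100, 200), observed = c(FALSE, FALSE))
  expect_error(fit_survival_model(d, covariates = character(0),
                                  metastasis = FALSE), "no observed events")
})

test_that("hazard ratios follow their closed forms", {
  expect_equal(hazard_ratio(os_table3, "metastasis"), exp(3.43))
  expect_equal(hazard_ratio(os_table3, "metastasis"), 30.9, tolerance = 1e-2)
  expect_equal(hazard_ratio(os_table3, "linitis"), 3.0)
  expect_equal(hazard_ratio(os_table3, "stage3"), 2.0)
  null <- hazard_params("constant", 1e-4)
  expect_equal(hazard_ratio(null, "stage3"), 1)
  expect_equal(hazard_ratio(null, "metastasis"), 1)
})

test_that("inverse-CDF event simulation reproduces the exponential law", {
  p <- hazard_params("constant", 2e-4, beta_met = 3.43)
  set.seed(19)
  tt <- vapply(seq_len(1e4), function(i) {
    simulate_event_time(p, max_follow_days = Inf)$time
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(tt, stats::pexp, 2e-4))
  expect_gt(ks$p.value, 0.01)
  # degenerate horizon: always censored at the boundary
  z <- simulate_event_time(p, max_follow_days = 0)
  expect_false(z$observed)
  expect_identical(z$time, 0)
  # deterministic given the uniform draw; the switch accelerates the event
  a <- simulate_event_time(p, t_met = 500, max_follow_days = Inf, u = 0.31)
  b <- simulate_event_time(p, t_met = 500, max_follow_days = Inf, u = 0.31)
  expect_identical(a, b)
  no_sw <- simulate_event_time(p, max_follow_days = Inf, u = 0.31)
  expect_lte(a$time, no_sw$time)
  # non-constant families invert by root finding to the same target
  w <- hazard_params("weibull", 1e-7, shape = 1.6)
  ev <- simulate_event_time(w, max_follow_days = Inf, u = 0.2)
  expect_equal(cumulative_hazard(w, ev$time), -log(0.2), tolerance = 1e-6)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplan_meier(time = c(1, 2, 3, 3, 4),
                     observed = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(km_at(km, 0), 1)
  expect_equal(km_at(km, 2), 0.75)
  expect_equal(km_at(km, 3), 0.25)
  expect_equal(km_at(km, 10), 0.25)
  # without censoring the estimate is the empirical survival function
  km2 <- kaplan_meier(c(5, 1, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km_at(km2, c(0.5, 1, 3, 5)), c(1, 2 / 3, 1 / 3, 0))
  expect_error(kaplan_meier(numeric(0), logical(0)), "empty")
})

test_that("Kaplan-Meier converges to the true exponential survival curve", {
  set.seed(29)
  n <- 5000
  lam <- 3e-4
  tt <- rexp(n, lam)
  cens <- runif(n, 1000, 6000)
  km <- kaplan_meier(pmin(tt, cens), tt <= cens)
  grid <- seq(0, 3000, by = 50)
  expect_lt(max(abs(km_at(km, grid) - exp(-lam * grid))), 0.03)
})

test_that("Weibull refit of constant-hazard data rarely flags a shape effect", {
  set.seed(47)
  hits <- 0L
  for (r in 1:20) {
    n <- 300
    tt <- rexp(n, 2e-4)
    cens <- runif(n, 1000, 5000)
    d <- mk_event_data(time = pmin(tt, cens), observed = tt <= cens)
    fc <- fit_survival_model(d, "constant", covariates = character(0),
                             metastasis = FALSE, compute_covariance = FALSE)
    fw <- fit_survival_model(d, "weibull", covariates = character(0),
                             metastasis = FALSE, compute_covariance = FALSE)
    if (fc$ofv - fw$ofv < 3.86) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
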