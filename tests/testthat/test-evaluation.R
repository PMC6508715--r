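test_that("categorical VPC envelopes are ordered, complete and reproducible", {
  p <- response_params()
  design <- data.frame(n_visits = rep(3L, 60), covterm = 0)
  v1 <- vpc_categorical(p, design, n_sim = 80, seed = 5)
  expect_identical(attr(v1, "n_sim"), 80L)
  expect_identical(nrow(v1), 9L) # 3 visits x 3 categories
  expect_true(all(v1$`p2.5` <= v1$p50 & v1$p50 <= v1$`p97.5`))
  v2 <- vpc_categorical(p, design, n_sim = 80, seed = 5)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_error(vpc_categorical(p, design, n_sim = 1), "n_sim")
})

test_that("degenerate response parameters collapse the VPC envelope", {
  # enormous baseline logits and null Markov effects: everyone stays in
  # disease progression at every visit
  stuck <- response_params(beta = c(500, -1), theta_markov = c(pr = 0, sd = 0, dp = 0),
                           omega2 = 0)
  v <- vpc_categorical(stuck, data.frame(n_visits = rep(3L, 20)), n_sim = 50,
                       seed = 1)
  expect_true(all(v$`p2.5` == v$`p97.5`))
  expect_true(all(v$p50[v$category == 2] == 1))
  expect_true(all(v$p50[v$category != 2] == 0))
})

test_that("survival VPC starts at (1,1,1), stratifies, and is reproducible", {
  os <- hazard_params("constant", 1e-4, delta_stage = 1e-4,
                      delta_linitis = 2e-4, beta_met = 3.43)
  design <- data.frame(stage3 = rep(c(TRUE, FALSE), 30),
                       linitis = rep(c(TRUE, FALSE), each = 30),
                       censor_time = runif(60, 2000, 3600))
  grid <- c(0, 365, 1095, 2920)
  v <- vpc_survival(os, design, met_rate = 2e-4, time_grid = grid,
                    n_sim = 60, seed = 9)
  z <- v[v$time == 0, ]
  expect_equal(unname(unlist(z[c("p2.5", "p50", "p97.5")])), c(1, 1, 1))
  expect_true(all(v$`p2.5` <= v$p50 & v$p50 <= v$`p97.5`))
  vs <- vpc_survival(os, design, met_rate = 2e-4, time_grid = grid,
                     n_sim = 60, stratify = "linitis", seed = 9)
  expect_setequal(unique(vs$stratum), c("linitis", "no_linitis"))
  va <- vpc_survival(os, design, met_rate = 2e-4, time_grid = grid,
                     n_sim = 60, seed = 9)
  expect_identical(as.data.frame(v), as.data.frame(va))
})

test_that("bootstrap over identical subjects has zero-width intervals", {
  co <- mk_cohort(rep(list(c(2L, 1L, 0L)), 6), event_times = rep(900, 6))
  out <- bootstrap_fits(co, function(b) {
    d <- os_event_data(b)
    c(mean_time = mean(d$time))
  }, n_boot = 25, seed = 3)
  expect_identical(out$n_converged, 25L)
  expect_false(out$unreliable)
  expect_equal(out$summary$`p2.5`, out$summary$`p97.5`)
})

test_that("bootstrap resamples subjects as units and flags unreliability", {
  co <- simulate_cohort(simulation_config(n_patients = 40, seed = 21))
  fit_rate <- function(b) {
    d <- metastasis_event_data(b)
    c(lambda = sum(d$observed) / sum(d$time))
  }
  out <- bootstrap_fits(co, fit_rate, n_boot = 40, seed = 2)
  expect_identical(dim(out$estimates), c(40L, 1L))
  expect_true(out$summary$`p2.5` < out$summary$`p97.5`)
  out_b <- bootstrap_fits(co, fit_rate, n_boot = 40, seed = 2)
  expect_identical(out$estimates, out_b$estimates) # bit-for-bit under the seed
  # >50% failures flips the reliability flag
  flaky <- local({
    k <- 0
    function(b) {
      k <<- k + 1
      if (k %% 3 != 0) stop("no convergence")
      fit_rate(b)
    }
  })
  out2 <- bootstrap_fits(co, flaky, n_boot = 30, seed = 4)
  expect_true(out2$unreliable)
})
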