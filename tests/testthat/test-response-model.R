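table3 <- response_params() # published estimates, omega2 = 1 convention

test_that("cumulative logits follow the partial-sum and sign conventions", {
  expect_equal(cumulative_logit(table3, 1), 19.7)
  expect_equal(cumulative_logit(table3, 2), 19.7 - 4.62)
  # previous stable disease subtracts its Markov effect
  expect_equal(cumulative_logit(table3, 1, prev_state = 1), 19.7 - 19.4)
  # covariates and eta add on the logit scale
  p <- response_params(theta_cov = c(LINITIS = 2.5))
  expect_equal(cumulative_logit(p, 1, covariates = c(LINITIS = 1), eta = 0.7),
               19.7 + 2.5 + 0.7)
  expect_error(cumulative_logit(p, 1, covariates = c(BOGUS = 1)), "unknown covariate")
})

test_that("logistic transform is exact and overflow-safe", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(19.7), 1 - 2.8e-9, tolerance = 1e-2)
  expect_equal(logistic(-4.62), 1 / (1 + exp(4.62)))
  expect_equal(logistic(-4.62), 0.0097, tolerance = 1e-2)
  expect_identical(logistic(750), 1)
  expect_gte(logistic(-750), 0)
})

test_that("category probabilities difference the cumulative curve and normalise", {
  # all probability mass on disease progression at diagnosis
  p_dx <- category_probabilities(table3)
  expect_equal(unname(p_dx[["2"]]), 1, tolerance = 1e-6)
  expect_equal(sum(p_dx), 1)
  # zero logits: both cumulative probabilities are 0.5, so the middle
  # category (their difference) carries no mass under the difference form
  p0 <- response_params(beta = c(0, 0), theta_markov = c(pr = 0, sd = 0, dp = 0))
  expect_equal(unname(category_probabilities(p0)), c(0.5, 0, 0.5))
  # random parameter battery: in [0,1], sum 1, cumulative non-increasing
  set.seed(17)
  for (i in 1:100) {
    pr <- response_params(beta = c(rnorm(1, 0, 10), -abs(rnorm(1, 0, 5))),
                          theta_markov = rnorm(3, 0, 10), omega2 = runif(1, 0, 4))
    v <- category_probabilities(pr, prev_state = sample(0:2, 1), eta = rnorm(1, 0, 2))
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v), 1)
  }
})

test_that("transition matrix rows are conditional distributions", {
  tm <- transition_matrix(table3)
  expect_equal(rowSums(tm), c(PR = 1, SD = 1, DP = 1))
  # from stable disease: L1 = 0.3, so P(PR) = 1 - logistic(0.3)
  expect_equal(unname(tm["SD", "PR"]), 1 - plogis(0.3), tolerance = 1e-12)
  expect_equal(unname(tm["SD", "PR"]), 0.426, tolerance = 2e-3)
  # identical Markov effects remove the state dependence
  flat <- response_params(theta_markov = c(pr = 5, sd = 5, dp = 5))
  tmf <- transition_matrix(flat)
  expect_equal(tmf["PR", ], tmf["SD", ])
  expect_equal(tmf["SD", ], tmf["DP", ])
})

test_that("raising the stable-disease Markov effect lowers P(Y>=1 | prev SD)", {
  th <- seq(10, 25, by = 2.5)
  p1 <- vapply(th, function(t) {
    pr <- response_params(theta_markov = c(pr = 18.1, sd = t, dp = 18.8))
    logistic(cumulative_logit(pr, 1, prev_state = 1))
  }, numeric(1))
  expect_true(all(diff(p1) < 0))
})

test_that("trajectory likelihoods are coherent distributions over outcomes", {
  # a single diagnosis visit is deterministic under the published parameters
  expect_equal(trajectory_loglik(table3, 2L), 0, tolerance = 1e-6)
  # exhaustive enumeration: probabilities of all continuations sum to 1
  set.seed(23)
  for (i in 1:10) {
    pr <- response_params(beta = c(rnorm(1, 2, 3), -abs(rnorm(1, 2, 2))),
                          theta_markov = rnorm(3, 0, 5))
    for (len in 2:4) {
      eta <- rnorm(1, 0, 1.5)
      tot <- sum(vapply(all_trajectories(len), function(dv) {
        exp(trajectory_loglik(pr, dv, eta = eta))
      }, numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
  # an impossible observation under degenerate parameters yields -Inf
  degen <- response_params(beta = c(19.7, -2000))
  ll <- trajectory_loglik(degen, c(2L, 2L))
  expect_identical(ll[[1]], -Inf)
})

test_that("marginal likelihood methods agree where they must", {
  set.seed(31)
  co <- simulate_cohort(simulation_config(
    n_patients = 5, seed = 31,
    true_response_params = response_params(omega2 = 0.1)))
  p <- response_params(omega2 = 0.1)
  ll_la <- marginal_loglik(p, co, "laplace")
  ll_gq <- marginal_loglik(p, co, "quadrature", nodes = 64)
  ll_mc <- marginal_loglik(p, co, "montecarlo", draws = 2e5, seed = 99)
  expect_equal(ll_la, ll_gq, tolerance = 1e-3)
  expect_lt(abs(ll_mc - ll_gq), 3 * attr(ll_mc, "mc_se"))
  # degenerate variance: every method collapses to the conditional at eta = 0
  p0 <- response_params(omega2 = 0)
  cond <- sum(vapply(unique(co$visits$patient_id), function(id) {
    dv <- co$visits$response_dv[co$visits$patient_id == id &
                                  co$visits$visit_index <= 3]
    trajectory_loglik(p0, dv, eta = 0)
  }, numeric(1)))
  expect_equal(marginal_loglik(p0, co, "laplace"), cond)
  expect_equal(marginal_loglik(p0, co, "quadrature"), cond)
  # omega2 -> 0 limit of the Laplace route
  p_eps <- response_params(omega2 = 1e-10)
  expect_equal(marginal_loglik(p_eps, co, "laplace"), cond, tolerance = 1e-6)
  expect_error(marginal_loglik(p, co, "montecarlo"), "seed")
})

test_that("fitting respects parameter masks and optimality", {
  set.seed(37)
  co <- simulate_cohort(simulation_config(n_patients = 150, seed = 37))
  # all-fixed mask: no search, OFV evaluated at init
  f0 <- fit_response_model(co, init = table3, free = character(0))
  expect_equal(f0$ofv, -2 * marginal_loglik(table3, co, "laplace"))
  expect_identical(f0$estimates["beta1"], c(beta1 = 19.7))
  # refitting from the truth cannot end worse than the truth
  fit <- fit_response_model(co, init = table3, compute_covariance = FALSE)
  expect_lte(fit$ofv, f0$ofv + 1e-6)
  expect_true(fit$converged)
})

test_that("trajectory simulation matches the model law and is reproducible", {
  expect_identical(simulate_trajectory(table3, n_visits = 1), 2L)
  # empirical second-visit frequencies at eta = 0 vs model probabilities
  set.seed(43)
  n <- 2e4
  sims <- vapply(seq_len(n), function(i) {
    simulate_trajectory(table3, n_visits = 2, eta = 0)[2]
  }, integer(1))
  probs <- category_probabilities(table3, prev_state = 2, eta = 0)
  for (m in 0:2) {
    se <- sqrt(probs[[as.character(m)]] * (1 - probs[[as.character(m)]]) / n)
    expect_lt(abs(mean(sims == m) - probs[[as.character(m)]]), 3 * se + 1e-12)
  }
  set.seed(7); a <- simulate_trajectory(table3, n_visits = 4)
  set.seed(7); b <- simulate_trajectory(table3, n_visits = 4)
  expect_identical(a, b)
})

test_that("parameter files round-trip exactly", {
  p <- response_params(beta = c(19.7, -4.62),
                       theta_markov = c(pr = 18.1, sd = 19.4, dp = 18.8),
                       theta_cov = c(LINITIS = -0.123456789012345),
                       omega2 = 0.987654321)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_response_params(p, path)
  q <- read_response_params(path)
  expect_equal(q$beta, p$beta)
  expect_equal(q$theta_markov, p$theta_markov)
  expect_equal(q$theta_cov, p$theta_cov)
  expect_equal(q$omega2, p$omega2)
  h <- hazard_params("weibull", lambda0 = 2.5e-4, shape = 1.2,
                     delta_stage = 1e-4, delta_linitis = 2e-4, beta_met = 3.43)
  hpath <- withr::local_tempfile(fileext = ".yaml")
  write_hazard_params(h, hpath)
  h2 <- read_hazard_params(hpath)
  expect_equal(h2[c("family", "lambda0", "shape", "delta_stage",
                    "delta_linitis", "beta_met")],
               h[c("family", "lambda0", "shape", "delta_stage",
                   "delta_linitis", "beta_met")])
})
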