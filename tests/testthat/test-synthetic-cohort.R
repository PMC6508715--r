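test_that("generated cohorts satisfy every container invariant", {
  for (s in c(1, 2)) {
    co <- simulate_cohort(simulation_config(n_patients = 80, seed = s))
    expect_identical(validate_cohort(co), character(0))
    dx <- co$visits[co$visits$visit_index == 1L, ]
    expect_true(all(dx$response_dv == 2L))
    # metastasis-before-death ordering by construction
    e <- co$events
    met <- e[e$event_type == "metastasis" & e$observed, ]
    dth <- e[e$event_type == "death", ]
    m <- merge(met, dth, by = "patient_id")
    expect_true(all(m$time_days.x <= m$time_days.y))
  }
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(simulation_config(n_patients = 60, seed = 123))
  b <- simulate_cohort(simulation_config(n_patients = 60, seed = 123))
  for (part in c("patients", "visits", "events")) {
    expect_identical(as.data.frame(a[[part]]), as.data.frame(b[[part]]))
  }
})

test_that("sampled covariates match the configured frequencies", {
  cfg <- simulation_config(n_patients = 5e4, seed = 55)
  co <- simulate_cohort(cfg)
  n <- nrow(co$patients)
  check_freq <- function(obs_p, target) {
    se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(obs_p - target), 3 * se + 1e-4)
  }
  dx <- co$visits[co$visits$visit_index == 1L, ]
  ct <- dx$clinical_t[match(co$patients$patient_id, dx$patient_id)]
  check_freq(mean(ct == 3L), 0.652 / sum(c(0.087, 0.652, 0.217, 0.043)))
  check_freq(mean(co$patients$sex == "male"), 0.704)
  check_freq(mean(co$patients$linitis), 0.243)
  check_freq(mean(co$patients$ctnm_stage == 3L), 0.696)
  # pathologic marginals from the copula discretisation
  ypt_t <- c(0.148, 0.096, 0.226, 0.435, 0.070, 0.026)
  ypt_t <- ypt_t / sum(ypt_t)
  check_freq(mean(co$patients$ypt == 0L), ypt_t[1])
  check_freq(mean(co$patients$ypt == 3L), ypt_t[4])
  ypn_t <- c(0.609, 0.226, 0.070, 0.087, 0.009) / 1.001
  check_freq(mean(co$patients$ypn == 0L), ypn_t[1])
  # age stays on the published range with the published centre
  expect_true(all(co$patients$age_years >= 31 & co$patients$age_years <= 83))
  expect_lt(abs(stats::median(co$patients$age_years) - 62), 3)
})

test_that("point-mass frequencies give a homogeneous cohort", {
  cfg <- simulation_config(
    n_patients = 25, seed = 2,
    covariate_frequencies = list(male = 1, linitis = 0, crt = 1,
                                 grade = c(well = 0, moderate = 0, poor = 1)))
  co <- simulate_cohort(cfg)
  expect_true(all(co$patients$sex == "male"))
  expect_true(all(!co$patients$linitis))
  expect_true(all(co$patients$treatment == "CRT"))
  expect_true(all(co$patients$grade == "poor"))
})

test_that("copula limits behave: comonotone at rho 1, independent at rho 0", {
  # matched marginals (ypT carrying the clinical T distribution) + rho = 1:
  # the pathologic rank must reproduce the clinical rank exactly
  cfg1 <- simulation_config(
    n_patients = 500, seed = 3, rho_t = 1, rho_n = 0, response_link = 0,
    covariate_frequencies = list(
      ypt = c(`0` = 0, `1` = 0, `2` = 0.087, `3` = 0.652, `4a` = 0.217,
              `4b` = 0.043)))
  set.seed(3)
  pats <- sample_covariates(cfg1, 500)
  lat <- attr(pats, "latents")
  yp <- generate_pathologic_stage(lat$ct_rank, pats$ct_n_positive,
                                  final_dv = NULL, config = cfg1,
                                  z_ct = lat$z_ct, z_cn = lat$z_cn)
  expect_identical(yp$ypt, lat$ct_rank)
  # rho = 0: empirical Spearman correlation near zero
  cfg0 <- simulation_config(n_patients = 1e4, seed = 4, rho_t = 0, rho_n = 0,
                            response_link = 0)
  co0 <- simulate_cohort(cfg0)
  cc0 <- staging_concordance(co0)
  expect_lt(abs(cc0$rho_t), 0.03)
  expect_lt(abs(cc0$rho_n), 0.03)
})

test_that("calibrated copula targets are recovered in large samples", {
  co <- simulate_cohort(simulation_config(n_patients = 1e4, seed = 6))
  cc <- staging_concordance(co)
  expect_lt(abs(cc$rho_t - 0.32), 0.03)
  expect_lt(abs(cc$rho_n - 0.19), 0.03)
})

test_that("calibration rejects unattainable targets and extreme inputs", {
  px <- c(0.9, 0.1); py <- c(0.5, 0.5)
  expect_equal(calibrate_copula_rho(0, px, py), 0)
  expect_equal(calibrate_copula_rho(1, px, py), 1)
  # mismatched binary marginals cap the attainable rank correlation well
  # below 0.9
  expect_error(calibrate_copula_rho(0.9, px, py), "unattainable")
  # round trip: calibrated latent value reproduces the target analytically
  ct <- c(0.087, 0.652, 0.217, 0.043) / 0.999
  ypt <- c(0.148, 0.096, 0.226, 0.435, 0.070, 0.026) / 1.001
  r <- calibrate_copula_rho(0.32, ct, ypt)
  expect_equal(neogastric:::.discrete_spearman(r, ct, ypt), 0.32,
               tolerance = 1e-4)
})
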