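# Synthetic-cohort generator emulating the 115-patient neoadjuvant study
# design: covariate frequencies from the published characteristics table, a
# 3-visit clinical assessment schedule (all patients in the progression
# category at diagnosis) plus a surgery/pathology visit, Markov-dependent
# response trajectories, metastasis and death times from the survival model
# with accrual-driven administrative censoring, and pathologic ypT/ypN stages
# linked to the clinical stage through a Gaussian copula whose latent
# correlation is calibrated so the observed (discretised) Spearman
# correlation hits the configured target.

#' Simulation configuration
#'
#' Bundles everything needed to generate a synthetic cohort reproducibly.
#' Defaults reproduce the published study conditions: covariate frequencies
#' from the patients' characteristics table, response-model and
#' overall-survival parameters at the published estimates (random-effect
#' variance 1, which the source does not report), clinical assessments at
#' days 0/42/84 with surgery at day 120, uniform accrual over 5 years with
#' administrative censoring at 10 years, and clinical-pathologic Spearman
#' targets 0.32 (T), 0.19 (N). The metastasis hazard (2e-4/day), HER2
#' prevalence (0.15) and dose-intensity distribution are generator
#' conventions, not published values.
#'
#' @param n_patients cohort size (default 115).
#' @param seed integer RNG seed or `NULL`.
#' @param true_response_params,true_os_params generating parameters.
#' @param met_rate constant metastasis hazard per day.
#' @param visit_schedule_days times of visits 1-4.
#' @param rho_t,rho_n target observed Spearman correlations for (cT, ypT)
#'   and (cN+, ypN).
#' @param response_link latent weight coupling the final clinical response
#'   to the pathologic stage draw (negative clinical-pathologic response
#'   correlation for positive values; see the methods vignette).
#' @param accrual_years,admin_censor_years censoring scheme.
#' @param surgery_prob probability a patient reaches surgery (has ypT/ypN).
#' @param covariate_frequencies optional named list overriding any of the
#'   default frequency entries (see `default_covariate_frequencies()`).
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 115L, seed = NULL,
                              true_response_params = response_params(),
                              true_os_params = hazard_params(
                                "constant", lambda0 = 1e-4,
                                delta_stage = 1e-4, delta_linitis = 2e-4,
                                beta_met = 3.43),
                              met_rate = 2e-4,
                              visit_schedule_days = c(0, 42, 84, 120),
                              rho_t = 0.32, rho_n = 0.19,
                              response_link = 0.38,
                              accrual_years = 5, admin_censor_years = 10,
                              surgery_prob = 1,
                              covariate_frequencies = NULL) {
  freq <- default_covariate_frequencies()
  if (!is.null(covariate_frequencies)) {
    stopifnot(all(names(covariate_frequencies) %in% names(freq)))
    freq[names(covariate_frequencies)] <- covariate_frequencies
  }
  for (nm in c("location", "ct", "stage", "grade", "ypt", "ypn")) {
    s <- sum(freq[[nm]])
    stopifnot(all(freq[[nm]] >= 0), s > 0)
    freq[[nm]] <- freq[[nm]] / s
  }
  for (nm in c("male", "ecog0", "gastric", "cn_positive", "linitis",
               "diffuse", "crt", "her2")) {
    stopifnot(freq[[nm]] >= 0, freq[[nm]] <= 1)
  }
  stopifnot(n_patients >= 1, length(visit_schedule_days) == 4,
            !is.unsorted(visit_schedule_days, strictly = TRUE),
            abs(rho_t) < 1 || rho_t %in% c(-1, 1),
            abs(rho_n) < 1 || rho_n %in% c(-1, 1),
            surgery_prob >= 0, surgery_prob <= 1)
  if (rho_t^2 + response_link^2 > 1 || rho_n^2 + response_link^2 > 1) {
    stop("rho targets and response_link jointly too large (latent variance exceeded)",
         call. = FALSE)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = seed,
    true_response_params = true_response_params,
    true_os_params = true_os_params, met_rate = met_rate,
    visit_schedule_days = visit_schedule_days,
    rho_t = rho_t, rho_n = rho_n, response_link = response_link,
    accrual_years = accrual_years, admin_censor_years = admin_censor_years,
    surgery_prob = surgery_prob, freq = freq
  ), class = "sim_config")
  # latent copula correlations calibrated so the discretised Spearman hits
  # the configured targets
  cfg$rho_t_latent <- calibrate_copula_rho(rho_t, freq$ct, cfg$freq$ypt)
  cfg$rho_n_latent <- calibrate_copula_rho(
    rho_n, c(1 - freq$cn_positive, freq$cn_positive), cfg$freq$ypn)
  cfg
}

#' @rdname simulation_config
#' @export
default_covariate_frequencies <- function() {
  list(
    male = 0.704, ecog0 = 0.052, gastric = 0.696,
    location = c(cardias = 0.304, antrum = 0.357, body = 0.313, pylorus = 0.017),
    ct = c(`2` = 0.087, `3` = 0.652, `4a` = 0.217, `4b` = 0.043),
    cn_positive = 0.722,
    stage = c(`1` = 0, `2` = 0.304, `3` = 0.696),
    grade = c(well = 0.035, moderate = 0.409, poor = 0.556),
    linitis = 0.243, diffuse = 0.539, crt = 0.565, her2 = 0.15,
    age = c(min = 31, median = 62, max = 83),
    ypt = c(`0` = 0.148, `1` = 0.096, `2` = 0.226, `3` = 0.435,
            `4a` = 0.070, `4b` = 0.026),
    ypn = c(`0` = 0.609, `1` = 0.226, `2` = 0.070, `3a` = 0.087, `3b` = 0.009)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n = %d, seed = %s\n", x$n_patients,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  cat(sprintf("  copula targets: rho_t = %.3g (latent %.3g), rho_n = %.3g (latent %.3g)\n",
              x$rho_t, x$rho_t_latent, x$rho_n, x$rho_n_latent))
  invisible(x)
}

# ---- Copula calibration -----------------------------------------------------

# Population Spearman correlation of two ordinal variables obtained by
# discretising a bivariate standard normal with latent correlation rho at the
# quantile cuts of the marginal probability vectors px, py: the correlation
# of the midrank scores under the implied cell probabilities.
.discrete_spearman <- function(rho, px, py) {
  px <- px / sum(px); py <- py / sum(py)
  nx <- length(px); ny <- length(py)
  cuts_x <- c(-Inf, stats::qnorm(cumsum(px)[-nx]), Inf)
  cuts_y <- c(-Inf, stats::qnorm(cumsum(py)[-ny]), Inf)
  corr <- matrix(c(1, rho, rho, 1), 2)
  Phi2 <- matrix(0, nx + 1L, ny + 1L)
  for (i in seq_len(nx + 1L)) {
    for (j in seq_len(ny + 1L)) {
      Phi2[i, j] <- if (is.infinite(cuts_x[i]) && cuts_x[i] < 0) 0
        else if (is.infinite(cuts_y[j]) && cuts_y[j] < 0) 0
        else mvtnorm::pmvnorm(upper = c(cuts_x[i], cuts_y[j]), corr = corr)[1]
    }
  }
  p <- Phi2[-1, -1] - Phi2[-(nx + 1L), -1] - Phi2[-1, -(ny + 1L)] +
    Phi2[-(nx + 1L), -(ny + 1L)]
  p <- pmax(p, 0)
  # midrank scores on the 0..1 scale
  ax <- cumsum(px) - px / 2
  ay <- cumsum(py) - py / 2
  Ex <- sum(px * ax); Ey <- sum(py * ay)
  Vx <- sum(px * ax^2) - Ex^2; Vy <- sum(py * ay^2) - Ey^2
  Exy <- sum(outer(ax, ay) * p)
  (Exy - Ex * Ey) / sqrt(Vx * Vy)
}

#' Calibrate a latent copula correlation to an observed Spearman target
#'
#' Discretising a Gaussian copula attenuates rank correlation; this inverts
#' the attenuation numerically so that the generated ordinal pair attains the
#' target Spearman correlation in expectation.
#'
#' @param target desired observed Spearman correlation (in (-1, 1); the
#'   exact values -1/0/1 are passed through).
#' @param px,py marginal probability vectors of the two ordinal variables.
#' @return latent bivariate-normal correlation.
#' @export
calibrate_copula_rho <- function(target, px, py) {
  if (target == 0) return(0)
  if (abs(target) >= 1) return(sign(target))
  lim <- .discrete_spearman(0.9995, px, py)
  if (abs(target) >= lim) {
    stop(sprintf("target %.3g unattainable after discretisation (max %.3g)",
                 target, lim), call. = FALSE)
  }
  stats::uniroot(function(r) .discrete_spearman(r, px, py) - target,
                 interval = c(-0.9995, 0.9995), tol = 1e-6)$root
}

# ---- Covariate sampling -----------------------------------------------------

.rtriangular <- function(n, a, c, b) {
  u <- stats::runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

# Mode of the triangular distribution on [a, b] whose median equals `med`
# (the published table reports median and range, not the mode).
.triangular_mode <- function(a, med, b) {
  if (med >= (a + b) / 2) a + 2 * (med - a)^2 / (b - a)
  else b - 2 * (b - med)^2 / (b - a)
}

#' Sample baseline patient covariates
#'
#' Independent categorical draws at the configured frequencies; age from a
#' triangular distribution on the published median and range. The clinical
#' T stage and nodal status are drawn through latent-normal uniforms that
#' are retained (as attribute `latents`) for the pathologic-stage copula.
#'
#' @param config a [simulation_config()].
#' @param n number of patients (default `config$n_patients`).
#' @return tibble of patient records with attribute `latents` (list with
#'   `z_ct`, `z_cn`, and the drawn `ct_rank`).
#' @export
sample_covariates <- function(config, n = config$n_patients) {
  f <- config$freq
  u_ct <- stats::runif(n)
  ct_rank <- c(2L, 3L, 4L, 5L)[findInterval(u_ct, cumsum(f$ct)) + 1L]
  u_cn <- stats::runif(n)
  cn_pos <- u_cn > (1 - f$cn_positive)
  stage <- c(1L, 2L, 3L)[findInterval(stats::runif(n), cumsum(f$stage)) + 1L]
  p <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    age_years = round(.rtriangular(
      n, f$age[["min"]],
      .triangular_mode(f$age[["min"]], f$age[["median"]], f$age[["max"]]),
      f$age[["max"]])),
    sex = ifelse(stats::runif(n) < f$male, "male", "female"),
    ecog = ifelse(stats::runif(n) < f$ecog0, 0L, 1L),
    tumor_site = ifelse(stats::runif(n) < f$gastric, "gastric", "gej"),
    location = names(f$location)[findInterval(stats::runif(n),
                                              cumsum(f$location)) + 1L],
    linitis = stats::runif(n) < f$linitis,
    lauren = ifelse(stats::runif(n) < f$diffuse, "diffuse", "intestinal"),
    grade = names(f$grade)[findInterval(stats::runif(n), cumsum(f$grade)) + 1L],
    her2 = stats::runif(n) < f$her2,
    ctnm_stage = stage,
    treatment = ifelse(stats::runif(n) < f$crt, "CRT", "ChT"),
    dose_intensity = stats::rbeta(n, 8, 2),
    ct_n_positive = cn_pos,
    ypt = NA_integer_, ypn = NA_integer_
  )
  attr(p, "latents") <- list(z_ct = stats::qnorm(u_ct), z_cn = stats::qnorm(u_cn),
                             ct_rank = ct_rank)
  p
}

# ---- Pathologic stage generation --------------------------------------------

#' Generate pathologic ypT/ypN stages via a Gaussian copula
#'
#' Latent pathologic scores are built from the clinical latent scores (with
#' the calibrated latent correlations), minus `response_link` times a latent
#' consistent with the final clinical response category, plus independent
#' noise; they are then discretised to the configured ypT/ypN marginal
#' distributions. With `rho = 1` and matched marginals the mapping is
#' comonotone (rank-preserving); with `rho = 0` the pathologic stage is
#' independent of the clinical one.
#'
#' @param ct_rank baseline clinical T ranks (vector).
#' @param cn_positive baseline nodal positivity (logical vector).
#' @param final_dv final clinical response categories (0/1/2), or `NULL` to
#'   omit the response link.
#' @param config a [simulation_config()] providing targets and marginals.
#' @param z_ct,z_cn optional clinical latent normal scores (as produced by
#'   [sample_covariates()]); reconstructed from the ranks (uniform within the
#'   rank band) when absent.
#' @return list with integer vectors `ypt` (0..5) and `ypn` (0..4).
#' @export
generate_pathologic_stage <- function(ct_rank, cn_positive, final_dv = NULL,
                                      config = simulation_config(),
                                      z_ct = NULL, z_cn = NULL) {
  n <- length(ct_rank)
  f <- config$freq
  if (is.null(z_ct)) {
    z_ct <- .latent_from_rank(match(ct_rank, c(2L, 3L, 4L, 5L)), f$ct)
  }
  if (is.null(z_cn)) {
    z_cn <- .latent_from_rank(as.integer(cn_positive) + 1L,
                              c(1 - f$cn_positive, f$cn_positive))
  }
  gamma <- if (is.null(final_dv)) 0 else config$response_link
  z_resp <- if (is.null(final_dv)) numeric(n) else {
    pr <- as.numeric(table(factor(final_dv, levels = 0:2))) / length(final_dv)
    .latent_from_rank(final_dv + 1L, pr)
  }
  draw <- function(z_clin, rho_lat, probs) {
    s2 <- 1 - rho_lat^2 - gamma^2
    if (s2 < 0) stop("latent variance exceeded; lower response_link", call. = FALSE)
    z <- rho_lat * z_clin - gamma * z_resp + sqrt(s2) * stats::rnorm(n)
    findInterval(stats::pnorm(z), cumsum(probs) / sum(probs),
                 rightmost.closed = TRUE)
  }
  list(ypt = as.integer(draw(z_ct, config$rho_t_latent, f$ypt)),
       ypn = as.integer(draw(z_cn, config$rho_n_latent, f$ypn)))
}

# Reconstruct a standard-normal latent consistent with an ordinal draw:
# uniform within the category's probability band. `idx` is 1-based category
# index into `probs`.
.latent_from_rank <- function(idx, probs) {
  probs <- probs / sum(probs)
  lo <- c(0, cumsum(probs))[idx]
  stats::qnorm(lo + stats::runif(length(idx)) * probs[idx])
}

# ---- Full cohort simulation -------------------------------------------------

#' Simulate a synthetic cohort
#'
#' Full generative pipeline: baseline covariates; Markov response
#' trajectories over the three clinical visits (diagnosis forced to disease
#' progression); a surgery/pathology visit whose response category applies
#' the downstage / no-change / upstage rule to the clinical-to-pathologic
#' stage change; metastasis times from a constant hazard; death times from
#' the overall-survival model with the time-dependent metastasis switch;
#' right censoring from uniform accrual plus an administrative cutoff; and
#' copula-linked pathologic stages. The returned cohort satisfies every
#' container invariant by construction.
#'
#' @param config a [simulation_config()].
#' @return a validated `cohort_table`, with attributes `n_pcr` (number of
#'   generated complete pathologic responses) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  sched <- config$visit_schedule_days

  patients <- sample_covariates(config, n)
  lat <- attr(patients, "latents")
  ct_rank <- lat$ct_rank

  rp <- config$true_response_params
  dv <- .simulate_dv_matrix(rp, n, 3L)
  final_dv <- dv[, 3]

  operated <- stats::runif(n) < config$surgery_prob
  yp <- generate_pathologic_stage(ct_rank, patients$ct_n_positive, final_dv,
                                  config, z_ct = lat$z_ct, z_cn = lat$z_cn)
  patients$ypt[operated] <- yp$ypt[operated]
  patients$ypn[operated] <- yp$ypn[operated]

  # pathologic response category: stage change from (cT, cN+) to (ypT, ypN>0),
  # same up/down/no-change rule as derive_response, vectorised
  dn_t <- yp$ypt - ct_rank
  dn_n <- as.integer(yp$ypn > 0) - as.integer(patients$ct_n_positive)
  path_dv <- ifelse(dn_t > 0 | dn_n > 0, 2L,
                    ifelse(dn_t < 0 | dn_n < 0, 0L, 1L))

  visits <- rbind(
    tibble::tibble(patient_id = patients$patient_id, visit_index = 1L,
                   time_days = sched[1], clinical_t = ct_rank,
                   clinical_n = patients$ct_n_positive,
                   response_dv = dv[, 1]),
    tibble::tibble(patient_id = patients$patient_id, visit_index = 2L,
                   time_days = sched[2], clinical_t = NA_integer_,
                   clinical_n = NA, response_dv = dv[, 2]),
    tibble::tibble(patient_id = patients$patient_id, visit_index = 3L,
                   time_days = sched[3], clinical_t = NA_integer_,
                   clinical_n = NA, response_dv = dv[, 3]),
    tibble::tibble(patient_id = patients$patient_id[operated], visit_index = 4L,
                   time_days = sched[4], clinical_t = NA_integer_,
                   clinical_n = NA, response_dv = as.integer(path_dv[operated]))
  )

  stage3 <- patients$ctnm_stage >= 3L
  t_met_raw <- stats::rexp(n, config$met_rate)
  follow <- config$admin_censor_years * 365 -
    stats::runif(n, 0, config$accrual_years * 365)
  death_raw <- .simulate_os_times(config$true_os_params, stage3,
                                  patients$linitis, t_met_raw)
  death_time <- pmin(death_raw, follow)
  death_obs <- death_raw <= follow
  met_obs <- t_met_raw <= death_time
  events <- rbind(
    tibble::tibble(patient_id = patients$patient_id, event_type = "death",
                   time_days = death_time, observed = death_obs),
    tibble::tibble(patient_id = patients$patient_id, event_type = "metastasis",
                   time_days = ifelse(met_obs, t_met_raw, death_time),
                   observed = met_obs)
  )

  cohort <- cohort_table(patients, visits, events, validate = TRUE)
  attr(cohort, "n_pcr") <- sum(patients$ypt == 0L & patients$ypn == 0L, na.rm = TRUE)
  attr(cohort, "config") <- config
  cohort
}
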