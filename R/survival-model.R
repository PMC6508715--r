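# Parametric time-to-event models for metastasis appearance and overall
# survival. The hazard is
#
#   h(t) = [lambda0 + delta_stage*1(stage>=III) + delta_linitis*1(linitis)]
#          * b(t) * exp(beta_met * 1(t >= t_met))
#
# with b(t) = 1 (constant), shape * t^(shape-1) (Weibull) or exp(shape * t)
# (Gompertz). Stage and linitis act additively on the baseline rate;
# metastasis appearance acts multiplicatively from its (observed or
# simulated) time onward, as a right-continuous step switch. S(t) = exp(-HZ)
# with HZ the cumulative hazard. Time is in days unless `time_unit_days`
# rescales it.

HAZARD_FAMILIES <- c("constant", "weibull", "gompertz")

#' Hazard model parameters
#'
#' @param family `"constant"` (exponential survival), `"weibull"` or
#'   `"gompertz"`.
#' @param lambda0 baseline hazard rate (> 0), per `time_unit_days` days.
#' @param shape Weibull exponent (> 0) or Gompertz log-slope; must be absent
#'   for the constant family.
#' @param delta_stage additive baseline increment for cTNM stage >= III.
#' @param delta_linitis additive baseline increment for linitis plastica.
#' @param beta_met log hazard-ratio applied multiplicatively from the
#'   metastasis time onward.
#' @param delta_extra optional named numeric vector of additional additive
#'   baseline increments (used by covariate screening).
#' @param time_unit_days scale of the time axis (default 1 = per day).
#' @return object of class `hazard_params`.
#' @export
hazard_params <- function(family = "constant", lambda0 = 1e-4, shape = NULL,
                          delta_stage = 0, delta_linitis = 0, beta_met = 0,
                          delta_extra = NULL, time_unit_days = 1) {
  family <- match.arg(family, HAZARD_FAMILIES)
  stopifnot(is.numeric(lambda0), length(lambda0) == 1, lambda0 > 0)
  if (family == "constant") {
    if (!is.null(shape)) stop("constant family has no shape parameter", call. = FALSE)
  } else {
    stopifnot(is.numeric(shape), length(shape) == 1, is.finite(shape))
    if (family == "weibull" && shape <= 0) stop("Weibull shape must be > 0", call. = FALSE)
  }
  if (!is.null(delta_extra)) stopifnot(is.numeric(delta_extra), !is.null(names(delta_extra)))
  p <- structure(list(family = family, lambda0 = lambda0, shape = shape,
                      delta_stage = delta_stage, delta_linitis = delta_linitis,
                      beta_met = beta_met, delta_extra = delta_extra,
                      time_unit_days = time_unit_days),
                 class = "hazard_params")
  # positivity of the composite baseline for every covariate combination
  combos <- expand.grid(s = c(0, 1), l = c(0, 1))
  lo <- min(lambda0 + combos$s * delta_stage + combos$l * delta_linitis)
  if (!is.null(delta_extra)) lo <- lo + sum(pmin(delta_extra, 0))
  if (lo <= 0) stop("composite baseline hazard non-positive for some covariate combination",
                    call. = FALSE)
  p
}

#' @export
print.hazard_params <- function(x, ...) {
  cat(sprintf("<hazard_params> family = %s, lambda0 = %.4g/day%s\n",
              x$family, x$lambda0,
              if (is.null(x$shape)) "" else sprintf(", shape = %.4g", x$shape)))
  cat(sprintf("  delta_stage = %.4g, delta_linitis = %.4g, beta_met = %.4g (HR %.3g)\n",
              x$delta_stage, x$delta_linitis, x$beta_met, exp(x$beta_met)))
  invisible(x)
}

.base_rate <- function(params, stage3, linitis, extra = NULL) {
  r <- params$lambda0 + params$delta_stage * as.numeric(stage3) +
    params$delta_linitis * as.numeric(linitis)
  if (!is.null(params$delta_extra)) {
    if (is.null(extra)) {
      # reference level 0 for unspecified extra covariates
    } else {
      keys <- intersect(names(params$delta_extra), colnames(extra))
      if (length(keys)) {
        r <- r + drop(extra[, keys, drop = FALSE] %*% params$delta_extra[keys])
      }
    }
  }
  if (any(r <= 0)) stop("non-positive composite baseline hazard", call. = FALSE)
  r
}

.time_part <- function(params, t) {
  switch(params$family,
    constant = rep_len(1, length(t)),
    weibull = params$shape * t^(params$shape - 1),
    gompertz = exp(params$shape * t)
  )
}

# Integral of the time part from 0 to t (closed form for all families).
.time_integral <- function(params, t) {
  switch(params$family,
    constant = t,
    weibull = t^params$shape,
    gompertz = if (abs(params$shape) < 1e-12) t else expm1(params$shape * t) / params$shape
  )
}

#' Hazard rate at time t
#'
#' @param params a [hazard_params()].
#' @param t time in days (vectorised, >= 0).
#' @param stage3 logical: cTNM stage >= III.
#' @param linitis logical: linitis plastica present.
#' @param t_met metastasis time in days, or `NULL`/`NA` if none; the
#'   multiplicative `exp(beta_met)` applies for `t >= t_met`.
#' @param extra optional 1-row matrix of extra covariate indicators.
#' @return hazard rate(s) per day.
#' @export
hazard_at <- function(params, t, stage3 = FALSE, linitis = FALSE, t_met = NULL,
                      extra = NULL) {
  stopifnot(all(t >= 0))
  u <- t / params$time_unit_days
  rate <- .base_rate(params, stage3, linitis, extra) * .time_part(params, u)
  if (!is.null(t_met) && !is.na(t_met)) {
    rate <- rate * exp(params$beta_met * (t >= t_met))
  }
  rate / params$time_unit_days
}

#' Cumulative hazard HZ(t)
#'
#' Piecewise closed form around the metastasis switch:
#' `HZ(t) = lambda_c * [T(min(t, t_met)) + exp(beta_met) * (T(t) - T(t_met))+]`
#' where `T` is the integrated time part of the family. `HZ(0) = 0` and HZ is
#' non-decreasing in `t`.
#'
#' @inheritParams hazard_at
#' @return cumulative hazard(s), >= 0.
#' @export
cumulative_hazard <- function(params, t, stage3 = FALSE, linitis = FALSE,
                              t_met = NULL, extra = NULL) {
  stopifnot(all(t >= 0))
  u <- t / params$time_unit_days
  lam <- .base_rate(params, stage3, linitis, extra)
  if (is.null(t_met) || is.na(t_met)) {
    return(lam * .time_integral(params, u))
  }
  um <- t_met / params$time_unit_days
  pre <- .time_integral(params, pmin(u, um))
  post <- pmax(.time_integral(params, u) - .time_integral(params, um), 0)
  lam * (pre + exp(params$beta_met) * post)
}

#' Survival probability S(t) = exp(-HZ(t))
#'
#' @inheritParams hazard_at
#' @return probability in (0, 1]; `S(0) = 1`, non-increasing in `t`.
#' @export
survival_prob <- function(params, t, stage3 = FALSE, linitis = FALSE,
                          t_met = NULL, extra = NULL) {
  exp(-cumulative_hazard(params, t, stage3, linitis, t_met, extra))
}

# ---- Event data and likelihood ---------------------------------------------

#' Extract overall-survival event data from a cohort
#'
#' One row per patient with the death/censoring time, event indicator,
#' baseline covariates and the observed metastasis time (NA when metastasis
#' was not observed; censored metastasis records carry no switch).
#'
#' @param cohort a `cohort_table`; every patient must have a death record
#'   (observed or censored).
#' @return data frame with columns `patient_id`, `time`, `observed`,
#'   `stage3`, `linitis`, `t_met`.
#' @export
os_event_data <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  e <- cohort$events
  dth <- e[e$event_type == "death", ]
  missing_ids <- setdiff(cohort$patients$patient_id, dth$patient_id)
  if (length(missing_ids)) {
    stop(sprintf("patients without a death/censoring record: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  met <- e[e$event_type == "metastasis" & e$observed %in% TRUE, ]
  p <- cohort$patients
  i <- match(p$patient_id, dth$patient_id)
  data.frame(
    patient_id = p$patient_id,
    time = dth$time_days[i],
    observed = dth$observed[i],
    stage3 = p$ctnm_stage >= 3L,
    linitis = p$linitis %in% TRUE,
    t_met = met$time_days[match(p$patient_id, met$patient_id)],
    stringsAsFactors = FALSE
  )
}

#' Extract metastasis (PFS-type) event data from a cohort
#'
#' @param cohort a `cohort_table`.
#' @return data frame with `patient_id`, `time`, `observed`, `stage3`,
#'   `linitis` (and `t_met = NA`, so the same likelihood code applies).
#' @export
metastasis_event_data <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  e <- cohort$events
  met <- e[e$event_type == "metastasis", ]
  p <- cohort$patients
  i <- match(p$patient_id, met$patient_id)
  keep <- !is.na(i)
  data.frame(
    patient_id = p$patient_id[keep],
    time = met$time_days[i[keep]],
    observed = met$observed[i[keep]],
    stage3 = p$ctnm_stage[keep] >= 3L,
    linitis = p$linitis[keep] %in% TRUE,
    t_met = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Log-likelihood of right-censored event data
#'
#' Standard parametric survival likelihood: observed events contribute
#' `log h(t_i) - HZ(t_i)`, censored records `-HZ(t_i)`. Metastasis times in
#' the `t_met` column enter as the time-dependent hazard switch.
#'
#' @param params a [hazard_params()].
#' @param data data frame with columns `time` (> 0), `observed` (logical) and
#'   optionally `stage3`, `linitis`, `t_met`, plus extra indicator columns
#'   named in `params$delta_extra`.
#' @return scalar log-likelihood.
#' @export
event_loglik <- function(params, data) {
  stopifnot(all(c("time", "observed") %in% names(data)))
  if (any(!is.finite(data$time)) || any(data$time <= 0)) {
    stop("event times must be positive and finite", call. = FALSE)
  }
  s3 <- if ("stage3" %in% names(data)) data$stage3 else FALSE
  li <- if ("linitis" %in% names(data)) data$linitis else FALSE
  tm <- if ("t_met" %in% names(data)) data$t_met else rep(NA_real_, nrow(data))
  extra <- NULL
  if (!is.null(params$delta_extra)) {
    keys <- names(params$delta_extra)
    if (!all(keys %in% names(data))) {
      stop(sprintf("data lacks extra covariate column(s): %s",
                   paste(setdiff(keys, names(data)), collapse = ", ")), call. = FALSE)
    }
    extra <- as.matrix(data[keys])
  }
  u <- data$time / params$time_unit_days
  lam <- .base_rate(params, s3, li, extra)
  lam <- rep_len(lam, nrow(data))
  tmi <- ifelse(is.na(tm), Inf, tm)
  um <- tmi / params$time_unit_days
  Hz <- lam * (.time_integral(params, pmin(u, um)) +
                 exp(params$beta_met) *
                   pmax(.time_integral(params, u) - .time_integral(params, um), 0))
  lh <- log(lam) + log(.time_part(params, u)) +
    params$beta_met * (data$time >= tmi) - log(params$time_unit_days)
  sum(ifelse(data$observed, lh, 0)) - sum(Hz)
}

# ---- Fitting ----------------------------------------------------------------

.haz_par_vector <- function(params, covariates) {
  v <- c(lambda0 = params$lambda0)
  if (params$family != "constant") v <- c(v, shape = params$shape)
  if ("stage3" %in% covariates) v <- c(v, delta_stage = params$delta_stage)
  if ("linitis" %in% covariates) v <- c(v, delta_linitis = params$delta_linitis)
  ex <- setdiff(covariates, c("stage3", "linitis"))
  for (k in ex) {
    v[[paste0("delta_", k)]] <- if (!is.null(params$delta_extra) && k %in% names(params$delta_extra))
      params$delta_extra[[k]] else 0
  }
  v
}

.haz_par_update <- function(params, v, covariates) {
  params$lambda0 <- v[["lambda0"]]
  if (params$family != "constant") params$shape <- v[["shape"]]
  if ("stage3" %in% covariates) params$delta_stage <- v[["delta_stage"]]
  if ("linitis" %in% covariates) params$delta_linitis <- v[["delta_linitis"]]
  ex <- setdiff(covariates, c("stage3", "linitis"))
  if (length(ex)) {
    params$delta_extra <- stats::setNames(
      vapply(ex, function(k) v[[paste0("delta_", k)]], numeric(1)), ex)
  }
  params
}

#' Fit a parametric survival model
#'
#' Maximum likelihood for the selected hazard family with additive baseline
#' covariates and (for overall survival) the time-dependent metastasis
#' effect. Reports OFV = -2 log-likelihood, the covariance of the estimates
#' from the inverse observed information and RSE%.
#'
#' @param data event data frame as produced by [os_event_data()] /
#'   [metastasis_event_data()] (or a `cohort_table`, in which case
#'   [os_event_data()] is applied).
#' @param family hazard family.
#' @param covariates character vector of additive baseline covariates:
#'   `"stage3"`, `"linitis"`, or names of extra indicator columns in `data`.
#' @param metastasis include the time-dependent metastasis effect
#'   (`beta_met`) as a free parameter.
#' @param init optional [hazard_params()] of starting values; defaults to
#'   the events/person-time rate with null effects.
#' @param control passed to [stats::nlminb()].
#' @param compute_covariance set `FALSE` to skip the Hessian.
#' @return object of class `survival_fit` with `params`, `estimates`, `ofv`,
#'   `covariance`, `se`, `rse_percent`, `converged`, `n_subjects`, `n_events`.
#' @export
fit_survival_model <- function(data, family = "constant",
                               covariates = c("stage3", "linitis"),
                               metastasis = TRUE, init = NULL,
                               control = list(), compute_covariance = TRUE) {
  if (inherits(data, "cohort_table")) data <- os_event_data(data)
  family <- match.arg(family, HAZARD_FAMILIES)
  if (sum(data$observed) < 1) stop("no observed events: likelihood is flat in lambda0",
                                   call. = FALSE)
  has_met <- metastasis && "t_met" %in% names(data) && any(!is.na(data$t_met))
  if (is.null(init)) {
    rate0 <- max(sum(data$observed) / sum(data$time), 1e-10)
    init <- hazard_params(family, lambda0 = rate0,
                          shape = if (family == "constant") NULL else 1,
                          beta_met = if (has_met) 1 else 0)
  }
  full <- .haz_par_vector(init, covariates)
  if (has_met) full <- c(full, beta_met = init$beta_met)

  mk_params <- function(v) {
    p <- .haz_par_update(init, v, covariates)
    if (has_met) p$beta_met <- v[["beta_met"]] else p$beta_met <- init$beta_met
    p
  }
  obj <- function(x) {
    v <- stats::setNames(x, names(full))
    v[["lambda0"]] <- exp(v[["lambda0"]])
    if (family == "weibull") v[["shape"]] <- exp(v[["shape"]])
    ll <- tryCatch(event_loglik(mk_params(v), data), error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -2 * ll
  }
  start <- full
  start[["lambda0"]] <- log(start[["lambda0"]])
  if (family == "weibull") start[["shape"]] <- log(start[["shape"]])
  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 500L, eval.max = 2000L),
                            control)
  # additive rate increments live on the lambda0 scale; tell the optimizer
  # their typical magnitude or it false-converges at the start
  scale <- rep(1, length(full))
  scale[grepl("^delta_", names(full))] <- 1 / max(init$lambda0, 1e-12)
  opt <- stats::nlminb(start, obj, scale = scale, control = ctrl)
  est <- stats::setNames(opt$par, names(full))
  est[["lambda0"]] <- exp(est[["lambda0"]])
  if (family == "weibull") est[["shape"]] <- exp(est[["shape"]])
  params_hat <- mk_params(est)

  covariance <- se <- rse <- NULL
  cov_ok <- FALSE
  if (compute_covariance) {
    nat_obj <- function(x) {
      v <- stats::setNames(x, names(full))
      if (v[["lambda0"]] <= 0) return(NA_real_)
      if (family == "weibull" && v[["shape"]] <= 0) return(NA_real_)
      ll <- tryCatch(event_loglik(mk_params(v), data), error = function(e) NA_real_)
      if (!is.finite(ll)) return(NA_real_)
      -2 * ll
    }
    h <- pmax(abs(est) * 1e-3, 1e-8)
    H <- tryCatch(.fd_hessian(nat_obj, est, h), error = function(e) NULL)
    covariance <- .cov_from_hessian(H, names(full))
    if (!is.null(covariance)) {
      dg <- diag(covariance)
      if (all(is.finite(dg)) && all(dg > 0)) {
        se <- sqrt(dg)
        rse <- 100 * se / abs(est)
        cov_ok <- TRUE
      }
    }
  }
  structure(list(
    params = params_hat, estimates = est, ofv = opt$objective,
    covariance = covariance, se = se, rse_percent = rse,
    covariance_ok = cov_ok, converged = opt$convergence == 0,
    message = opt$message, n_subjects = nrow(data),
    n_events = sum(data$observed)
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> %s family, OFV = %.4f (%d subjects, %d events)%s\n",
              x$params$family, x$ofv, x$n_subjects, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$estimates
  se <- if (!is.null(x$se)) x$se[names(est)] else rep(NA_real_, length(est))
  print(tibble::tibble(parameter = names(est), estimate = unname(est),
                       se = unname(se),
                       rse_percent = 100 * unname(se) / abs(unname(est))))
  invisible(x)
}

#' Hazard ratios implied by the model
#'
#' Metastasis: `exp(beta_met)`. Stage III and linitis: ratio of the composite
#' baseline rate with the covariate present to the reference rate
#' (`(lambda0 + delta) / lambda0`), evaluated with all other covariates at
#' reference.
#'
#' @param params a [hazard_params()].
#' @param effect `"metastasis"`, `"stage3"` or `"linitis"`.
#' @return scalar hazard ratio.
#' @export
hazard_ratio <- function(params, effect = c("metastasis", "stage3", "linitis")) {
  effect <- match.arg(effect)
  switch(effect,
    metastasis = exp(params$beta_met),
    stage3 = (params$lambda0 + params$delta_stage) / params$lambda0,
    linitis = (params$lambda0 + params$delta_linitis) / params$lambda0
  )
}

# ---- Event-time simulation --------------------------------------------------

#' Simulate one event time by inverse-CDF sampling
#'
#' Solves `HZ(T) = -log(U)` with `U ~ Uniform(0, 1)`: closed-form piecewise
#' inversion for the constant family, bracketed root-finding otherwise.
#' Times beyond `max_follow_days` are right-censored at the boundary.
#'
#' @inheritParams hazard_at
#' @param max_follow_days administrative censoring horizon (>= 0).
#' @param u optional uniform draw (for external RNG control).
#' @return list with `time` and `observed`.
#' @export
simulate_event_time <- function(params, stage3 = FALSE, linitis = FALSE,
                                t_met = NULL, max_follow_days = 3650, u = NULL) {
  stopifnot(max_follow_days >= 0)
  if (is.null(u)) u <- stats::runif(1)
  target <- -log(u)
  tt <- .invert_cumhaz(params, target, stage3, linitis, t_met)
  if (tt > max_follow_days) {
    list(time = max_follow_days, observed = FALSE)
  } else {
    list(time = tt, observed = TRUE)
  }
}

.invert_cumhaz <- function(params, target, stage3, linitis, t_met) {
  lam <- .base_rate(params, stage3, linitis)
  tm <- if (is.null(t_met) || is.na(t_met)) Inf else t_met
  if (params$family == "constant") {
    um <- tm / params$time_unit_days
    Hm <- lam * um
    u <- if (target <= Hm) target / lam
         else um + (target - Hm) / (lam * exp(params$beta_met))
    return(u * params$time_unit_days)
  }
  f <- function(t) cumulative_hazard(params, t, stage3, linitis,
                                     if (is.finite(tm)) tm else NULL) - target
  hi <- params$time_unit_days
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 2
  if (f(hi) < 0) return(Inf)
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}

# Vectorised constant-family simulation with per-subject covariates and
# metastasis switch; returns event times (Inf possible only if beta_met is
# pathologically negative).
.simulate_os_times <- function(params, stage3, linitis, t_met) {
  stopifnot(params$family == "constant")
  n <- length(stage3)
  lam <- .base_rate(params, stage3, linitis)
  lam <- rep_len(lam, n)
  target <- -log(stats::runif(n))
  tm <- ifelse(is.na(t_met), Inf, t_met)
  um <- tm / params$time_unit_days
  Hm <- lam * um
  u <- ifelse(target <= Hm, target / lam,
              um + (target - Hm) / (lam * exp(params$beta_met)))
  u * params$time_unit_days
}

# ---- Kaplan-Meier -----------------------------------------------------------

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] (right censoring; at tied times, events
#' precede censorings -- the standard convention) and returns a compact step
#' representation starting at `S(0) = 1`.
#'
#' @param time event/censoring times (> 0).
#' @param observed logical event indicators.
#' @return object of class `km_curve`: list with `time`, `survival`,
#'   `at_risk`, `events` (step points, `time[1] = 0`).
#' @export
kaplan_meier <- function(time, observed) {
  stopifnot(length(time) == length(observed))
  if (length(time) == 0) stop("empty stratum", call. = FALSE)
  if (any(time <= 0)) stop("event times must be positive", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, observed) ~ 1, conf.type = "none")
  structure(list(time = c(0, sf$time), survival = c(1, sf$surv),
                 at_risk = c(length(time), sf$n.risk),
                 events = c(0, sf$n.event)), class = "km_curve")
}

#' @rdname kaplan_meier
#' @param curve a `km_curve`.
#' @param t times at which to read the step function.
#' @export
km_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  idx <- findInterval(t, curve$time)
  curve$survival[pmax(idx, 1L)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d step points, S ranges %.3f..1\n",
              length(x$time) - 1L, min(x$survival)))
  invisible(x)
}
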