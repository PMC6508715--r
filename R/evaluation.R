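# Model-evaluation machinery: categorical and Kaplan-Meier visual predictive
# checks (fixed-parameter simulation, percentile envelopes across replicate
# datasets) and the subject-resampling nonparametric bootstrap. Percentiles
# use the linear-interpolation empirical quantile convention
# (stats::quantile type 7).

VPC_PROBS <- c(0.025, 0.5, 0.975)

.vpc_quantiles <- function(x) stats::quantile(x, VPC_PROBS, names = FALSE, type = 7)

#' Categorical visual predictive check
#'
#' Simulates `n_sim` replicate cohorts of response trajectories under the
#' fixed parameters and the observed study design, computes per visit the
#' proportion of subjects in each category, and reports the 2.5th / 50th /
#' 97.5th percentile envelope of those proportions, with the observed
#' proportions alongside when a cohort is supplied.
#'
#' @param params a [response_params()].
#' @param design data frame with one row per subject: column `n_visits`
#'   (1..4) and optionally `covterm` (per-subject covariate contribution to
#'   the logit, default 0). Usually from [vpc_design_from_cohort()].
#' @param n_sim number of replicate datasets (>= 2; the analysis default is
#'   500).
#' @param observed optional `cohort_table` supplying observed proportions.
#' @param seed optional RNG seed.
#' @return object of class `vpc_result`: tibble with columns `visit_index`,
#'   `category`, `observed`, `p2.5`, `p50`, `p97.5`; attribute `n_sim`.
#' @export
vpc_categorical <- function(params, design, n_sim = 500L, observed = NULL,
                            seed = NULL) {
  if (n_sim < 2) stop("n_sim must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot("n_visits" %in% names(design))
  n <- nrow(design)
  covterm <- if ("covterm" %in% names(design)) design$covterm else rep(0, n)
  max_v <- max(design$n_visits)
  # simulate all replicates at once: (n_sim * n) subjects
  N <- n_sim * n
  dv <- .simulate_dv_matrix(params, N, max_v, covterm = rep(covterm, times = n_sim))
  rep_id <- rep(seq_len(n_sim), each = n)
  nv <- rep(design$n_visits, times = n_sim)
  rows <- list()
  for (v in seq_len(max_v)) {
    inv <- nv >= v
    cats <- dv[inv, v]
    rid <- rep_id[inv]
    denom <- tabulate(rid, n_sim)
    for (m in 0:2) {
      num <- tabulate(rid[cats == m], n_sim)
      props <- num / denom
      q <- .vpc_quantiles(props)
      obs <- NA_real_
      if (!is.null(observed)) {
        ov <- observed$visits
        ov <- ov[ov$visit_index == v & !is.na(ov$response_dv), ]
        if (nrow(ov)) obs <- mean(ov$response_dv == m)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        visit_index = v, category = m, observed = obs,
        `p2.5` = q[1], p50 = q[2], `p97.5` = q[3]
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_sim") <- as.integer(n_sim)
  class(out) <- c("vpc_result", class(out))
  out
}

#' Design extraction for VPCs
#'
#' @param cohort a `cohort_table`.
#' @param params optional [response_params()] whose `theta_cov` keys define
#'   the per-subject covariate term.
#' @param visit_set visits counted towards `n_visits`.
#' @return data frame with `patient_id`, `n_visits`, `covterm`, and the
#'   survival-design columns `stage3`, `linitis`, `censor_time`.
#' @export
vpc_design_from_cohort <- function(cohort, params = NULL, visit_set = 1:3) {
  p <- cohort$patients
  v <- cohort$visits[cohort$visits$visit_index %in% visit_set &
                       !is.na(cohort$visits$response_dv), ]
  nv <- table(factor(v$patient_id, levels = p$patient_id))
  covterm <- rep(0, nrow(p))
  if (!is.null(params) && !is.null(params$theta_cov)) {
    X <- .response_covariate_matrix(p, names(params$theta_cov))
    covterm <- drop(X %*% unlist(params$theta_cov))
  }
  e <- cohort$events
  dth <- e[e$event_type == "death", ]
  i <- match(p$patient_id, dth$patient_id)
  data.frame(patient_id = p$patient_id, n_visits = as.integer(nv),
             covterm = covterm, stage3 = p$ctnm_stage >= 3L,
             linitis = p$linitis %in% TRUE,
             censor_time = dth$time_days[i], stringsAsFactors = FALSE)
}

#' Kaplan-Meier visual predictive check for overall survival
#'
#' Per replicate, simulates a metastasis time (constant hazard `met_rate`)
#' and a death time under `params` with the time-dependent metastasis switch
#' for every design subject, right-censors at the subject's `censor_time`,
#' computes the Kaplan-Meier estimate on `time_grid` (optionally per
#' stratum), and reports the percentile envelope; at `t = 0` the envelope is
#' exactly (1, 1, 1).
#'
#' @param params a [hazard_params()] (constant family).
#' @param design data frame with `stage3`, `linitis`, `censor_time` per
#'   subject (see [vpc_design_from_cohort()]).
#' @param met_rate constant metastasis hazard (per day) used to re-simulate
#'   the time-dependent covariate in each replicate.
#' @param time_grid evaluation times in days (0 is prepended if absent).
#' @param n_sim number of replicates (>= 2).
#' @param stratify `"none"`, `"metastasis"`, `"stage3"` or `"linitis"`.
#'   Metastasis strata are defined per replicate by the simulated metastasis
#'   status (observed strata use observed status).
#' @param observed optional `cohort_table` for the observed KM overlay.
#' @param seed optional RNG seed.
#' @return `vpc_result` tibble with `stratum`, `time`, `observed`, `p2.5`,
#'   `p50`, `p97.5`; attribute `n_sim`. Strata empty in every replicate are
#'   omitted with a warning.
#' @export
vpc_survival <- function(params, design, met_rate, time_grid, n_sim = 500L,
                         stratify = c("none", "metastasis", "stage3", "linitis"),
                         observed = NULL, seed = NULL) {
  if (n_sim < 2) stop("n_sim must be at least 2", call. = FALSE)
  stratify <- match.arg(stratify)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("stage3", "linitis", "censor_time") %in% names(design)))
  time_grid <- sort(unique(c(0, time_grid)))
  n <- nrow(design)

  strata_of <- function(met_status) {
    switch(stratify,
      none = rep("all", n),
      metastasis = ifelse(met_status, "metastasis", "no_metastasis"),
      stage3 = ifelse(design$stage3, "stage_III", "stage_lt_III"),
      linitis = ifelse(design$linitis, "linitis", "no_linitis")
    )
  }
  km_on_grid <- function(time, obs) {
    if (!length(time)) return(rep(NA_real_, length(time_grid)))
    km_at(kaplan_meier(time, obs), time_grid)
  }

  sim_levels <- switch(stratify,
    none = "all", metastasis = c("metastasis", "no_metastasis"),
    stage3 = c("stage_III", "stage_lt_III"), linitis = c("linitis", "no_linitis"))
  acc <- array(NA_real_, dim = c(n_sim, length(sim_levels), length(time_grid)),
               dimnames = list(NULL, sim_levels, NULL))
  for (r in seq_len(n_sim)) {
    t_met_raw <- stats::rexp(n, met_rate)
    death_raw <- .simulate_os_times(params, design$stage3, design$linitis, t_met_raw)
    time <- pmin(death_raw, design$censor_time)
    obs <- death_raw <= design$censor_time
    time <- pmax(time, 1e-9)
    met_status <- t_met_raw <= time
    st <- strata_of(met_status)
    for (lv in sim_levels) {
      sel <- st == lv
      if (any(sel)) acc[r, lv, ] <- km_on_grid(time[sel], obs[sel])
    }
  }

  obs_curves <- NULL
  if (!is.null(observed)) {
    od <- os_event_data(observed)
    met_obs <- !is.na(od$t_met)
    st <- switch(stratify,
      none = rep("all", nrow(od)),
      metastasis = ifelse(met_obs, "metastasis", "no_metastasis"),
      stage3 = ifelse(od$stage3, "stage_III", "stage_lt_III"),
      linitis = ifelse(od$linitis, "linitis", "no_linitis"))
    obs_curves <- lapply(stats::setNames(sim_levels, sim_levels), function(lv) {
      sel <- st == lv
      if (!any(sel)) return(rep(NA_real_, length(time_grid)))
      km_on_grid(od$time[sel], od$observed[sel])
    })
  }

  rows <- list()
  for (lv in sim_levels) {
    mat <- acc[, lv, , drop = FALSE]
    if (all(is.na(mat))) {
      warning(sprintf("stratum '%s' empty in every replicate; omitted", lv))
      next
    }
    for (g in seq_along(time_grid)) {
      vals <- mat[, 1, g]
      vals <- vals[!is.na(vals)]
      q <- if (time_grid[g] == 0) c(1, 1, 1) else .vpc_quantiles(vals)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stratum = lv, time = time_grid[g],
        observed = if (is.null(obs_curves)) NA_real_ else
          if (time_grid[g] == 0) 1 else obs_curves[[lv]][g],
        `p2.5` = q[1], p50 = q[2], `p97.5` = q[3]
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_sim") <- as.integer(n_sim)
  class(out) <- c("vpc_result", class(out))
  out
}

#' Nonparametric bootstrap of a model fit
#'
#' Resamples subjects with replacement (the subject is the resampling unit:
#' all visits and event records travel together), refits with `fit_fun`, and
#' summarises each parameter's replicate distribution by its 2.5th / 50th /
#' 97.5th percentiles. Replicates that error or fail to converge are dropped;
#' if more than half do, the result is flagged unreliable.
#'
#' @param cohort a `cohort_table` with >= 2 subjects.
#' @param fit_fun closure taking a `cohort_table` and returning either a
#'   named numeric vector of estimates or a list with `estimates` (named
#'   numeric) and optionally `converged`.
#' @param n_boot number of bootstrap replicates (the analysis default is 200).
#' @param seed optional RNG seed.
#' @return list with `summary` (tibble: parameter, p2.5, p50, p97.5),
#'   `estimates` (replicate x parameter matrix of converged fits),
#'   `n_converged`, `unreliable`.
#' @export
bootstrap_fits <- function(cohort, fit_fun, n_boot = 200L, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), nrow(cohort$patients) >= 2)
  if (!is.null(seed)) set.seed(seed)
  ids <- cohort$patients$patient_id
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    draw <- sample(ids, length(ids), replace = TRUE)
    bc <- .resample_cohort(cohort, draw)
    fit <- tryCatch(fit_fun(bc), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.list(fit)) {
      if (!is.null(fit$converged) && !isTRUE(fit$converged)) next
      est <- fit$estimates
    } else est <- fit
    reps[[b]] <- est
  }
  ok <- !vapply(reps, is.null, logical(1))
  n_conv <- sum(ok)
  if (n_conv == 0) stop("no bootstrap replicate converged", call. = FALSE)
  mat <- do.call(rbind, reps[ok])
  qs <- apply(mat, 2, .vpc_quantiles)
  summary <- tibble::tibble(parameter = colnames(mat),
                            `p2.5` = qs[1, ], p50 = qs[2, ], `p97.5` = qs[3, ],
                            n_converged = n_conv)
  list(summary = summary, estimates = mat, n_converged = n_conv,
       unreliable = n_conv < n_boot / 2)
}

# Rebuild a cohort from a resampled id vector, assigning fresh unique ids so
# that duplicated subjects remain distinct records.
.resample_cohort <- function(cohort, draw) {
  new_ids <- sprintf("b%04d", seq_along(draw))
  pats <- cohort$patients[match(draw, cohort$patients$patient_id), ]
  pats$patient_id <- new_ids
  pick <- function(tab) {
    idx <- split(seq_len(nrow(tab)), factor(tab$patient_id, levels = unique(tab$patient_id)))
    rows <- idx[draw]
    counts <- lengths(rows)
    out <- tab[unlist(rows, use.names = FALSE), ]
    out$patient_id <- rep(new_ids, counts)
    out
  }
  cohort_table(pats, pick(cohort$visits), pick(cohort$events), validate = FALSE)
}
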