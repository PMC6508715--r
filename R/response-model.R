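# Mixed-effects ordered-categorical (proportional-odds) model of tumour
# response with first-order Markov dependence between scheduled visits.
#
# The cumulative logit for category threshold m in {1, 2} is
#
#   L(m) = sum_{k<=m} beta_k - theta_markov[prev] + sum_c theta_c x_c + eta
#
# with P(Y >= m | eta) = logistic(L(m)), P(Y >= 0) = 1, and category
# probabilities by differencing. The Markov term is absent at the diagnosis
# visit (all patients progressing at diagnosis) and otherwise indexed by the
# previous visit's observed/simulated category. Effects enter the logit with
# a NEGATIVE sign: a larger Markov/covariate coefficient shifts mass towards
# partial response. The subject random effect eta ~ N(0, omega2) is shared by
# both cumulative logits.

MARKOV_KEYS <- c("pr", "sd", "dp")

#' Response model parameters
#'
#' @param beta numeric length-2 vector of baseline logit increments; the
#'   baseline logit for threshold m is the partial sum `sum(beta[1:m])`, so
#'   `beta[2] <= 0` guarantees non-increasing cumulative probabilities.
#' @param theta_markov named numeric vector `c(pr=, sd=, dp=)`: effect of a
#'   previous-visit partial response / stable disease / disease progression,
#'   entering the logit negatively at visits after diagnosis.
#' @param theta_cov optional named numeric vector of covariate coefficients
#'   (keys among `DOX`, `FOLFOX`, `RDT`, `HER2`, `LINITIS`, `DOSE_INT`);
#'   absent keys contribute 0.
#' @param omega2 variance (>= 0) of the subject-level random effect.
#' @return object of class `response_params`.
#' @export
response_params <- function(beta = c(19.7, -4.62),
                            theta_markov = c(pr = 18.1, sd = 19.4, dp = 18.8),
                            theta_cov = NULL,
                            omega2 = 1) {
  stopifnot(length(beta) == 2, is.numeric(beta), all(is.finite(beta)))
  stopifnot(length(theta_markov) == 3)
  if (is.null(names(theta_markov))) names(theta_markov) <- MARKOV_KEYS
  stopifnot(setequal(names(theta_markov), MARKOV_KEYS))
  theta_markov <- theta_markov[MARKOV_KEYS]
  if (!is.null(theta_cov)) {
    stopifnot(is.numeric(theta_cov), !is.null(names(theta_cov)))
    unknown <- setdiff(names(theta_cov), RESPONSE_COV_KEYS)
    if (length(unknown)) {
      stop(sprintf("unknown covariate key(s): %s (known: %s)",
                   paste(unknown, collapse = ", "),
                   paste(RESPONSE_COV_KEYS, collapse = ", ")), call. = FALSE)
    }
  }
  stopifnot(length(omega2) == 1, is.finite(omega2), omega2 >= 0)
  structure(list(beta = unname(beta), theta_markov = theta_markov,
                 theta_cov = theta_cov, omega2 = omega2),
            class = "response_params")
}

RESPONSE_COV_KEYS <- c("DOX", "FOLFOX", "RDT", "HER2", "LINITIS", "DOSE_INT")

#' @export
print.response_params <- function(x, ...) {
  cat("<response_params>\n")
  cat(sprintf("  baseline logits: L1 = %.4g, L2 = %.4g (beta = %.4g, %.4g)\n",
              x$beta[1], sum(x$beta), x$beta[1], x$beta[2]))
  cat(sprintf("  Markov effects (prev PR/SD/DP): %.4g / %.4g / %.4g\n",
              x$theta_markov["pr"], x$theta_markov["sd"], x$theta_markov["dp"]))
  if (!is.null(x$theta_cov)) {
    cat("  covariates:", paste(sprintf("%s=%.4g", names(x$theta_cov), x$theta_cov),
                               collapse = ", "), "\n")
  }
  cat(sprintf("  omega2 = %.4g\n", x$omega2))
  invisible(x)
}

.covariate_term <- function(params, covariates) {
  if (is.null(params$theta_cov) || !length(params$theta_cov)) return(0)
  if (is.null(covariates)) return(0)
  unknown <- setdiff(names(covariates), RESPONSE_COV_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown covariate key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  keys <- intersect(names(params$theta_cov), names(covariates))
  if (!length(keys)) return(0)
  sum(params$theta_cov[keys] * as.numeric(covariates[keys]))
}

.markov_term <- function(params, prev_state) {
  if (is.null(prev_state) || length(prev_state) == 0 || is.na(prev_state)) return(0)
  stopifnot(prev_state %in% 0:2)
  unname(params$theta_markov[[MARKOV_KEYS[prev_state + 1L]]])
}

#' Cumulative logit
#'
#' The logit of `P(Y >= m | eta)` for threshold `m` in `{1, 2}`:
#' baseline partial sum of `beta`, minus the Markov effect of the previous
#' category (if any), plus covariate contributions and the random effect.
#'
#' @param params a [response_params()].
#' @param m threshold, 1 or 2.
#' @param prev_state previous visit's category (0/1/2) or `NULL` at diagnosis.
#' @param covariates optional named indicator vector (keys as in
#'   [response_params()]).
#' @param eta subject random effect value.
#' @return numeric logit value.
#' @export
cumulative_logit <- function(params, m, prev_state = NULL, covariates = NULL,
                             eta = 0) {
  stopifnot(m %in% 1:2)
  sum(params$beta[seq_len(m)]) - .markov_term(params, prev_state) +
    .covariate_term(params, covariates) + eta
}

#' Logistic function
#'
#' `exp(L) / (1 + exp(L))`, evaluated overflow-safely for `|L|` up to several
#' hundred (delegates to the numerically stable [stats::plogis()]).
#'
#' @param L numeric vector of logits.
#' @return probabilities in `[0, 1]`.
#' @export
logistic <- function(L) stats::plogis(L)

#' Category probabilities of the ordered response
#'
#' `P(Y = m | eta)` for m = 0, 1, 2 by differencing the cumulative
#' probabilities: `P(Y >= 0) = 1`, `P(Y >= 3) = 0`.
#'
#' @inheritParams cumulative_logit
#' @return numeric probability vector of length 3 (names `"0"`, `"1"`, `"2"`)
#'   summing to 1.
#' @export
category_probabilities <- function(params, prev_state = NULL, covariates = NULL,
                                   eta = 0) {
  L1 <- cumulative_logit(params, 1, prev_state, covariates, eta)
  L2 <- cumulative_logit(params, 2, prev_state, covariates, eta)
  c1 <- stats::plogis(L1)
  c2 <- stats::plogis(L2)
  if (c2 > c1 + 1e-12) {
    stop("cumulative probabilities non-monotone (beta[2] > 0?)", call. = FALSE)
  }
  p <- c(`0` = 1 - c1, `1` = max(c1 - c2, 0), `2` = c2)
  p / sum(p)
}

#' Markov transition matrix of the response process
#'
#' Row r (previous category PR/SD/DP) holds the category probabilities of the
#' current visit conditioned on the previous visit's category; each row sums
#' to 1.
#'
#' @inheritParams cumulative_logit
#' @return 3x3 row-stochastic matrix, rows `PR`, `SD`, `DP`, columns
#'   `PR`, `SD`, `DP`.
#' @export
transition_matrix <- function(params, covariates = NULL, eta = 0) {
  rows <- t(vapply(0:2, function(s) {
    category_probabilities(params, prev_state = s, covariates = covariates, eta = eta)
  }, numeric(3)))
  dimnames(rows) <- list(c("PR", "SD", "DP"), c("PR", "SD", "DP"))
  rows
}

#' Conditional log-likelihood of one response trajectory
#'
#' Log-probability of an observed category sequence for a single subject at a
#' fixed random-effect value: the diagnosis term carries no Markov effect and
#' each later term conditions on the previous observed category. A
#' zero-probability observation yields `-Inf` (with attribute
#' `zero_probability = TRUE`).
#'
#' @param params a [response_params()].
#' @param dv_sequence integer vector of categories in {0,1,2}, starting at the
#'   diagnosis visit. `NA` entries are skipped (missing responses contribute
#'   nothing) and break the Markov chain for the following visit only if they
#'   are interior (the next term then conditions on the last non-missing
#'   category).
#' @param covariates optional named indicator vector.
#' @param eta random-effect value.
#' @return scalar log-likelihood.
#' @export
trajectory_loglik <- function(params, dv_sequence, covariates = NULL, eta = 0) {
  stopifnot(length(dv_sequence) >= 1)
  ll <- 0
  prev <- NULL
  for (j in seq_along(dv_sequence)) {
    dv <- dv_sequence[j]
    if (is.na(dv)) next
    p <- category_probabilities(params, prev_state = if (j == 1L) NULL else prev,
                                covariates = covariates, eta = eta)[[as.character(dv)]]
    if (p <= 0) {
      out <- -Inf
      attr(out, "zero_probability") <- TRUE
      return(out)
    }
    ll <- ll + log(p)
    prev <- dv
  }
  ll
}

# ---- Vectorised likelihood machinery ---------------------------------------

# Observation-level log-probabilities and derivatives in eta.
# c1, c2: per-observation cumulative logits at eta = 0; eta: per-observation
# random-effect values; dv: observed categories. Returns list(lp, d1, d2).
.obs_logp <- function(dv, c1, c2, eta, derivs = TRUE) {
  a1 <- c1 + eta
  a2 <- c2 + eta
  lp <- numeric(length(dv))
  d1 <- d2 <- if (derivs) numeric(length(dv)) else NULL
  i0 <- dv == 0L; i1 <- dv == 1L; i2 <- dv == 2L
  if (any(i0)) {
    F1 <- stats::plogis(a1[i0])
    lp[i0] <- stats::plogis(a1[i0], lower.tail = FALSE, log.p = TRUE)
    if (derivs) { d1[i0] <- -F1; d2[i0] <- -F1 * (1 - F1) }
  }
  if (any(i2)) {
    F2 <- stats::plogis(a2[i2])
    lp[i2] <- stats::plogis(a2[i2], log.p = TRUE)
    if (derivs) { d1[i2] <- 1 - F2; d2[i2] <- -F2 * (1 - F2) }
  }
  if (any(i1)) {
    l1 <- stats::plogis(a1[i1], log.p = TRUE)
    l2 <- stats::plogis(a2[i1], log.p = TRUE)
    lp[i1] <- l1 + log1p(-pmin(exp(l2 - l1), 1 - 1e-16))
    if (derivs) {
      F1 <- stats::plogis(a1[i1]); F2 <- stats::plogis(a2[i1])
      p <- pmax(F1 - F2, 1e-300)
      f1 <- F1 * (1 - F1); f2 <- F2 * (1 - F2)
      g1 <- (f1 - f2) / p
      g2 <- (f1 * (1 - 2 * F1) - f2 * (1 - 2 * F2)) / p - g1^2
      d1[i1] <- g1; d2[i1] <- g2
    }
  }
  list(lp = lp, d1 = d1, d2 = d2)
}

# Build the flat observation table used by the likelihood: one row per
# non-missing response observation, with the subject index, observed category,
# previous category (NA at the first included visit of a subject) and the
# covariate design matrix.
.response_prep <- function(cohort, cov_keys = NULL, visit_set = 1:3) {
  stopifnot(inherits(cohort, "cohort_table"))
  v <- cohort$visits[cohort$visits$visit_index %in% visit_set, ]
  v <- v[order(v$patient_id, v$visit_index), ]
  keep <- !is.na(v$response_dv)
  prev <- rep(NA_integer_, nrow(v))
  if (nrow(v) > 1) {
    same <- v$patient_id[-1] == v$patient_id[-nrow(v)]
    prev[-1][same] <- v$response_dv[-nrow(v)][same]
  }
  v$prev <- prev
  v <- v[keep, ]
  ids <- unique(cohort$patients$patient_id)
  isubj <- match(v$patient_id, ids)
  X <- NULL
  if (!is.null(cov_keys) && length(cov_keys)) {
    X <- .response_covariate_matrix(cohort$patients, cov_keys)[isubj, , drop = FALSE]
  }
  list(isubj = isubj, dv = as.integer(v$response_dv), prev = v$prev,
       X = X, n_subj = length(ids), ids = ids, n_obs = nrow(v))
}

# Indicator/continuous design columns for the optional response covariates.
.response_covariate_matrix <- function(patients, keys) {
  col <- function(key) {
    switch(key,
      RDT = as.numeric(patients$treatment == "CRT"),
      HER2 = as.numeric(patients$her2 %in% TRUE),
      LINITIS = as.numeric(patients$linitis %in% TRUE),
      DOSE_INT = ifelse(is.na(patients$dose_intensity), 0, patients$dose_intensity),
      DOX = , FOLFOX = {
        nm <- tolower(key)
        if (!nm %in% names(patients)) {
          stop(sprintf("covariate %s requires a '%s' indicator column in patients",
                       key, nm), call. = FALSE)
        }
        as.numeric(patients[[nm]] %in% TRUE)
      },
      stop(sprintf("unknown covariate key: %s", key), call. = FALSE)
    )
  }
  m <- vapply(keys, col, numeric(nrow(patients)))
  matrix(m, nrow = nrow(patients), dimnames = list(NULL, keys))
}

# Per-observation cumulative logits at eta = 0 for a parameter set.
.prep_logits <- function(prep, params) {
  th <- c(0, unname(params$theta_markov))[ifelse(is.na(prep$prev), 0L, prep$prev + 1L) + 1L]
  covterm <- 0
  if (!is.null(prep$X) && !is.null(params$theta_cov)) {
    keys <- colnames(prep$X)
    covterm <- drop(prep$X %*% ifelse(keys %in% names(params$theta_cov),
                                      params$theta_cov[keys], 0))
  }
  base <- covterm - th
  list(c1 = params$beta[1] + base, c2 = params$beta[1] + params$beta[2] + base)
}

# Per-subject joint log-density g(eta) = loglik(eta) + log phi(eta; 0, omega2)
# evaluated at a vector of per-subject eta; returns per-subject values.
.subject_g <- function(prep, lg, eta_subj, omega2) {
  o <- .obs_logp(prep$dv, lg$c1, lg$c2, eta_subj[prep$isubj], derivs = FALSE)
  ll <- .rowsum_by(o$lp, prep$isubj, prep$n_subj)
  ll + stats::dnorm(eta_subj, 0, sqrt(omega2), log = TRUE)
}

.rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Newton search for the per-subject posterior mode of eta. The objective is
# strictly concave (log-concave ordered-logistic terms plus Gaussian prior),
# so undamped Newton with a step cap converges; tolerance on the step.
.laplace_modes <- function(prep, lg, omega2, tol = 1e-8, max_iter = 100L) {
  eta <- numeric(prep$n_subj)
  for (it in seq_len(max_iter)) {
    o <- .obs_logp(prep$dv, lg$c1, lg$c2, eta[prep$isubj])
    g1 <- .rowsum_by(o$d1, prep$isubj, prep$n_subj) - eta / omega2
    g2 <- .rowsum_by(o$d2, prep$isubj, prep$n_subj) - 1 / omega2
    step <- -g1 / g2
    step <- pmax(pmin(step, 5), -5)
    eta <- eta + step
    if (max(abs(step)) < tol) {
      return(list(eta = eta, g2 = g2, converged = TRUE, iter = it))
    }
  }
  o <- .obs_logp(prep$dv, lg$c1, lg$c2, eta[prep$isubj])
  g2 <- .rowsum_by(o$d2, prep$isubj, prep$n_subj) - 1 / omega2
  list(eta = eta, g2 = g2, converged = FALSE, iter = max_iter)
}

.marginal_ll_laplace <- function(prep, params) {
  if (params$omega2 == 0) return(.marginal_ll_conditional0(prep, params))
  lg <- .prep_logits(prep, params)
  m <- .laplace_modes(prep, lg, params$omega2)
  g <- .subject_g(prep, lg, m$eta, params$omega2)
  sum(g + 0.5 * log(2 * pi) - 0.5 * log(-m$g2))
}

.marginal_ll_conditional0 <- function(prep, params) {
  lg <- .prep_logits(prep, params)
  o <- .obs_logp(prep$dv, lg$c1, lg$c2, numeric(prep$n_obs), derivs = FALSE)
  sum(o$lp)
}

.marginal_ll_quadrature <- function(prep, params, nodes = 21L) {
  if (params$omega2 == 0) return(.marginal_ll_conditional0(prep, params))
  lg <- .prep_logits(prep, params)
  m <- .laplace_modes(prep, lg, params$omega2)
  sd_hat <- 1 / sqrt(-m$g2)
  gh <- pracma::gaussHermite(nodes)
  vals <- matrix(NA_real_, nrow = nodes, ncol = prep$n_subj)
  for (k in seq_len(nodes)) {
    eta_k <- m$eta + sqrt(2) * sd_hat * gh$x[k]
    vals[k, ] <- log(gh$w[k]) + gh$x[k]^2 +
      .subject_g(prep, lg, eta_k, params$omega2)
  }
  mx <- apply(vals, 2, max)
  sum(log(sqrt(2) * sd_hat) + mx + log(colSums(exp(sweep(vals, 2, mx)))))
}

.marginal_ll_montecarlo <- function(prep, params, draws = 1e4L, seed = NULL,
                                    chunk = 1e5L) {
  if (params$omega2 == 0) {
    out <- .marginal_ll_conditional0(prep, params)
    attr(out, "mc_se") <- 0
    return(out)
  }
  if (is.null(seed)) stop("montecarlo method requires a seed", call. = FALSE)
  set.seed(seed)
  lg <- .prep_logits(prep, params)
  n <- prep$n_subj
  n_obs <- prep$n_obs
  agg <- matrix(0, nrow = n_obs, ncol = n) # obs -> subject aggregation
  agg[cbind(seq_len(n_obs), prep$isubj)] <- 1
  chunk <- max(1L, min(chunk, ceiling(2e6 / n_obs)))
  all_vals <- vector("list", ceiling(draws / chunk))
  draws_done <- 0L; ci <- 0L
  while (draws_done < draws) {
    nb <- min(chunk, draws - draws_done)
    eta <- matrix(stats::rnorm(nb * n, 0, sqrt(params$omega2)), nrow = nb)
    eta_obs <- eta[, prep$isubj, drop = FALSE] # nb x n_obs
    o <- .obs_logp(rep(prep$dv, each = nb), rep(lg$c1, each = nb),
                   rep(lg$c2, each = nb), as.vector(eta_obs), derivs = FALSE)
    ci <- ci + 1L
    all_vals[[ci]] <- matrix(o$lp, nrow = nb) %*% agg
    draws_done <- draws_done + nb
  }
  clv <- do.call(rbind, all_vals[seq_len(ci)])
  mx <- apply(clv, 2, max)
  w <- exp(sweep(clv, 2, mx))
  mu <- colMeans(w)
  ll <- sum(mx + log(mu))
  se_i <- apply(w, 2, stats::sd) / (mu * sqrt(draws))
  attr(ll, "mc_se") <- sqrt(sum(se_i^2))
  ll
}

#' Marginal log-likelihood of the response model
#'
#' Integrates the conditional trajectory likelihood over the subject random
#' effect eta ~ N(0, omega2), per subject, and sums the logs. Three routes
#' are available: the Laplace approximation (inner Newton mode search per
#' subject, the estimation workhorse), adaptive Gauss-Hermite quadrature
#' centred and scaled at the Laplace mode (the verification oracle), and
#' plain Monte Carlo (attribute `mc_se` holds the delta-method standard error
#' of the total). `omega2 = 0` degenerates to the conditional likelihood at
#' eta = 0 for every method.
#'
#' @param params a [response_params()].
#' @param cohort a `cohort_table`; visits in `visit_set` with non-missing
#'   `response_dv` contribute.
#' @param method `"laplace"`, `"quadrature"` or `"montecarlo"`.
#' @param nodes Gauss-Hermite node count (quadrature).
#' @param draws,seed Monte Carlo draw count and mandatory seed.
#' @param visit_set visit indices entering the likelihood (default 1:3, the
#'   clinical assessments; use `4` for the pathology-based single-visit model).
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(params, cohort,
                            method = c("laplace", "quadrature", "montecarlo"),
                            nodes = 21L, draws = 1e4L, seed = NULL,
                            visit_set = 1:3) {
  method <- match.arg(method)
  prep <- .response_prep(cohort, cov_keys = names(params$theta_cov),
                         visit_set = visit_set)
  switch(method,
    laplace = .marginal_ll_laplace(prep, params),
    quadrature = .marginal_ll_quadrature(prep, params, nodes),
    montecarlo = .marginal_ll_montecarlo(prep, params, draws, seed)
  )
}

# ---- Fitting ----------------------------------------------------------------

.resp_par_vector <- function(params) {
  v <- c(beta1 = params$beta[1], beta2 = params$beta[2],
         theta_pr = unname(params$theta_markov["pr"]),
         theta_sd = unname(params$theta_markov["sd"]),
         theta_dp = unname(params$theta_markov["dp"]))
  if (!is.null(params$theta_cov)) {
    cv <- params$theta_cov
    names(cv) <- paste0("theta_", tolower(names(cv)))
    v <- c(v, cv)
  }
  c(v, omega2 = params$omega2)
}

.resp_par_update <- function(params, v) {
  params$beta <- c(v[["beta1"]], v[["beta2"]])
  params$theta_markov <- c(pr = v[["theta_pr"]], sd = v[["theta_sd"]],
                           dp = v[["theta_dp"]])
  if (!is.null(params$theta_cov)) {
    for (k in names(params$theta_cov)) {
      params$theta_cov[[k]] <- v[[paste0("theta_", tolower(k))]]
    }
  }
  params$omega2 <- v[["omega2"]]
  params
}

# Covariance of the estimates from the observed-information Hessian of the
# OFV. The information matrix can be numerically singular along weakly
# identified directions (the baseline logit and the Markov effects share a
# near-flat common shift when diagnosis observations are deterministic);
# eigenvalues at or below the floor are replaced by the floor, which turns
# "no information" into "very large standard error" instead of a failure.
.cov_from_hessian <- function(H, names) {
  if (is.null(H) || !all(is.finite(H))) return(NULL)
  H <- (H + t(H)) / 2
  d <- sqrt(pmax(diag(H), 0))
  if (any(d == 0) || any(!is.finite(d))) return(NULL)
  Hs <- H / tcrossprod(d) # correlation-like scaling equalises parameter units
  eg <- eigen(Hs, symmetric = TRUE)
  floor_ <- max(abs(eg$values)) * 1e-9
  lam <- pmax(eg$values, floor_)
  inv <- eg$vectors %*% diag(1 / lam, length(lam)) %*% t(eg$vectors)
  cov <- 2 * inv / tcrossprod(d)
  dimnames(cov) <- list(names, names)
  attr(cov, "rank_deficient") <- any(eg$values <= floor_)
  cov
}

# Central-difference Hessian with per-parameter absolute steps chosen for
# smooth deterministic objectives (the Laplace likelihood is smooth to
# near machine precision in the parameters).
.fd_hessian <- function(fn, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x) * 1e-2, 0.02)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(x)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    fp[i] <- fn(x + ei); fm[i] <- fn(x - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ei <- numeric(k); ei[i] <- h[i]
      ej <- numeric(k); ej[j] <- h[j]
      fpp <- fn(x + ei + ej); fmm <- fn(x - ei - ej)
      H[i, j] <- H[j, i] <-
        (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) / (2 * h[i] * h[j])
    }
  }
  H
}

#' Fit the Markov ordered-categorical response model
#'
#' Maximum marginal likelihood over the free parameters, with the variance
#' estimated on the log scale and the objective reported as
#' OFV = -2 log-likelihood. The covariance of the estimates comes from the
#' inverse observed information (central finite differences of the Laplace
#' log-likelihood on the natural scale); RSE% is 100 x SE / |estimate|.
#'
#' @param cohort a `cohort_table` (>= 2 subjects with >= 2 usable visits).
#' @param init a [response_params()] holding starting values; its
#'   `theta_cov` keys define which covariate coefficients exist.
#' @param free character vector of free parameter names among `beta1`,
#'   `beta2`, `theta_pr`, `theta_sd`, `theta_dp`, `theta_<cov>`, `omega2`;
#'   `NULL` frees them all. An empty vector evaluates the OFV at `init`
#'   without searching.
#' @param method likelihood route (see [marginal_loglik()]); quadrature uses
#'   `nodes` nodes.
#' @param visit_set visit indices entering the likelihood.
#' @param nodes,control quadrature nodes; control list passed to
#'   [stats::nlminb()] (default `rel.tol = 1e-6` on the OFV scale).
#' @param compute_covariance set `FALSE` to skip the Hessian (faster, e.g.
#'   inside bootstrap replicates).
#' @return object of class `response_fit`: list with `params` (estimates as
#'   `response_params`), `estimates` (named vector), `ofv`, `covariance`,
#'   `se`, `rse_percent`, `converged`, `n_subjects`, `n_observations`.
#' @export
fit_response_model <- function(cohort, init = response_params(), free = NULL,
                               method = "laplace", visit_set = 1:3,
                               nodes = 21L, control = list(),
                               compute_covariance = TRUE) {
  prep <- .response_prep(cohort, cov_keys = names(init$theta_cov),
                         visit_set = visit_set)
  multi <- tabulate(prep$isubj, prep$n_subj)
  if (sum(multi >= 2) < 2 && !identical(visit_set, 4L) && !identical(visit_set, 4)) {
    stop("need at least 2 subjects with at least 2 usable visits", call. = FALSE)
  }
  full <- .resp_par_vector(init)
  if (is.null(free)) free <- names(full)
  stopifnot(all(free %in% names(full)))

  ll_fun <- function(pv) {
    params <- .resp_par_update(init, pv)
    switch(method,
      laplace = .marginal_ll_laplace(prep, params),
      quadrature = .marginal_ll_quadrature(prep, params, nodes),
      stop("fit supports methods 'laplace' and 'quadrature'", call. = FALSE)
    )
  }
  to_opt <- function(v) { # omega2 on log scale during the search
    if ("omega2" %in% names(v)) v[["omega2"]] <- log(max(v[["omega2"]], 1e-12))
    v
  }
  from_opt <- function(v) {
    if ("omega2" %in% names(v)) v[["omega2"]] <- exp(v[["omega2"]])
    v
  }
  obj <- function(x) {
    v <- full
    v[free] <- from_opt(stats::setNames(x, free))
    ll <- ll_fun(v)
    if (!is.finite(ll)) return(1e10)
    -2 * ll
  }

  if (length(free) == 0L) {
    ofv <- -2 * ll_fun(full)
    est <- full
    conv <- TRUE
    msg <- "no free parameters; OFV evaluated at init"
  } else {
    ctrl <- utils::modifyList(list(rel.tol = 1e-6, iter.max = 500L,
                                   eval.max = 2000L), control)
    start <- to_opt(full[free])
    opt <- stats::nlminb(start, obj, control = ctrl)
    est <- full
    est[free] <- from_opt(stats::setNames(opt$par, free))
    ofv <- opt$objective
    conv <- opt$convergence == 0
    msg <- opt$message
  }

  covariance <- se <- rse <- NULL
  cov_ok <- FALSE
  if (compute_covariance && length(free)) {
    nat_obj <- function(x) { # natural scale for the information matrix
      v <- full
      v[free] <- x
      if (v[["omega2"]] < 0) return(NA_real_)
      ll <- ll_fun(v)
      if (!is.finite(ll)) return(NA_real_)
      -2 * ll
    }
    h <- pmax(abs(est[free]) * 1e-2, 0.02)
    if ("omega2" %in% free) {
      i <- match("omega2", free)
      h[i] <- min(h[i], max(est[["omega2"]] * 0.45, 1e-6))
    }
    H <- tryCatch(.fd_hessian(nat_obj, est[free], h), error = function(e) NULL)
    covariance <- .cov_from_hessian(H, free)
    if (!is.null(covariance)) {
      dg <- diag(covariance)
      if (all(is.finite(dg)) && all(dg > 0)) {
        se <- sqrt(dg)
        rse <- 100 * se / abs(est[free])
        cov_ok <- TRUE
      }
    }
  }

  structure(list(
    params = .resp_par_update(init, est),
    estimates = est,
    ofv = ofv,
    covariance = covariance,
    se = se,
    rse_percent = rse,
    covariance_ok = cov_ok,
    converged = conv,
    message = msg,
    free = free,
    n_subjects = prep$n_subj,
    n_observations = prep$n_obs
  ), class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("<response_fit> OFV = %.4f (%d subjects, %d observations)%s\n",
              x$ofv, x$n_subjects, x$n_observations,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$estimates
  se <- if (!is.null(x$se)) x$se[names(est)] else rep(NA_real_, length(est))
  print(tibble::tibble(parameter = names(est), estimate = unname(est),
                       se = unname(se),
                       rse_percent = 100 * unname(se) / abs(unname(est))))
  invisible(x)
}

# ---- Simulation -------------------------------------------------------------

#' Simulate one response trajectory
#'
#' The diagnosis visit is forced to category 2 (disease progression); later
#' visits are drawn from the category probabilities conditioned on the
#' previously simulated category, with a single subject-level eta drawn from
#' N(0, omega2) unless supplied.
#'
#' @param params a [response_params()].
#' @param covariates optional named indicator vector.
#' @param n_visits number of visits (1..4).
#' @param eta fixed random-effect value, or `NULL` to draw one.
#' @return integer vector of categories of length `n_visits`.
#' @export
simulate_trajectory <- function(params, covariates = NULL, n_visits = 3L,
                                eta = NULL) {
  stopifnot(n_visits %in% 1:4)
  if (is.null(eta)) eta <- stats::rnorm(1, 0, sqrt(params$omega2))
  dv <- integer(n_visits)
  dv[1] <- 2L
  for (j in seq_len(n_visits)[-1]) {
    p <- category_probabilities(params, prev_state = dv[j - 1L],
                                covariates = covariates, eta = eta)
    dv[j] <- sample.int(3L, 1L, prob = p) - 1L
  }
  dv
}

# Vectorised trajectory simulation: n subjects x n_visits matrix.
# covterm: per-subject covariate contribution to the logit; eta: per-subject
# random effects (drawn if NULL).
.simulate_dv_matrix <- function(params, n, n_visits, covterm = 0, eta = NULL) {
  if (is.null(eta)) eta <- stats::rnorm(n, 0, sqrt(params$omega2))
  covterm <- rep_len(covterm, n)
  dv <- matrix(NA_integer_, nrow = n, ncol = n_visits)
  dv[, 1] <- 2L
  th <- unname(params$theta_markov)
  for (j in seq_len(n_visits)[-1]) {
    base <- covterm - th[dv[, j - 1L] + 1L] + eta
    P1 <- stats::plogis(params$beta[1] + base)
    P2 <- stats::plogis(params$beta[1] + params$beta[2] + base)
    u <- stats::runif(n)
    dv[, j] <- ifelse(u < P2, 2L, ifelse(u < P1, 1L, 0L))
  }
  dv
}
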