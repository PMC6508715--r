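# Flat key-value parameter files and fit reports.
#
# Parameter files are plain YAML scalars (keys beta1, beta2, theta_pr,
# theta_sd, theta_dp, theta_<cov>, omega2 for the response model; lambda0,
# shape, delta_stage, delta_linitis, beta_met, family for the hazard model)
# and round-trip exactly.

#' Write / read response parameters as a flat key-value file
#'
#' @param params a [response_params()].
#' @param path file path.
#' @return `read_response_params()` returns a [response_params()].
#' @export
write_response_params <- function(params, path) {
  v <- as.list(.resp_par_vector(params))
  yaml::write_yaml(v, path, precision = 17)
  invisible(path)
}

#' @rdname write_response_params
#' @export
read_response_params <- function(path) {
  v <- yaml::read_yaml(path)
  cov_keys <- grep("^theta_(?!pr$|sd$|dp$)", names(v), perl = TRUE, value = TRUE)
  theta_cov <- NULL
  if (length(cov_keys)) {
    theta_cov <- stats::setNames(unlist(v[cov_keys]),
                                 toupper(sub("^theta_", "", cov_keys)))
  }
  response_params(
    beta = c(v$beta1, v$beta2),
    theta_markov = c(pr = v$theta_pr, sd = v$theta_sd, dp = v$theta_dp),
    theta_cov = theta_cov,
    omega2 = v$omega2
  )
}

#' Write / read hazard parameters as a flat key-value file
#'
#' @param params a [hazard_params()].
#' @param path file path.
#' @export
write_hazard_params <- function(params, path) {
  v <- list(family = params$family, lambda0 = params$lambda0,
            delta_stage = params$delta_stage,
            delta_linitis = params$delta_linitis, beta_met = params$beta_met,
            time_unit_days = params$time_unit_days)
  if (!is.null(params$shape)) v$shape <- params$shape
  if (!is.null(params$delta_extra)) {
    v <- c(v, stats::setNames(as.list(params$delta_extra),
                              paste0("delta_", names(params$delta_extra))))
  }
  yaml::write_yaml(v, path, precision = 17)
  invisible(path)
}

#' @rdname write_hazard_params
#' @export
read_hazard_params <- function(path) {
  v <- yaml::read_yaml(path)
  extra_keys <- setdiff(grep("^delta_", names(v), value = TRUE),
                        c("delta_stage", "delta_linitis"))
  extra <- NULL
  if (length(extra_keys)) {
    extra <- stats::setNames(unlist(v[extra_keys]),
                             sub("^delta_", "", extra_keys))
  }
  hazard_params(family = v$family, lambda0 = v$lambda0, shape = v$shape,
                delta_stage = v$delta_stage, delta_linitis = v$delta_linitis,
                beta_met = v$beta_met, delta_extra = extra,
                time_unit_days = v$time_unit_days)
}

#' Tabular fit report
#'
#' One row per estimated parameter with estimate, standard error, RSE% and
#' the 95% Wald interval; the OFV is carried as an attribute and written as
#' a trailing comment row when exported.
#'
#' @param fit a `response_fit` or `survival_fit`.
#' @param path optional CSV output path.
#' @return tibble (invisibly when `path` is given).
#' @export
fit_report <- function(fit, path = NULL) {
  est <- fit$estimates
  se <- if (!is.null(fit$se)) fit$se[names(est)] else rep(NA_real_, length(est))
  out <- tibble::tibble(
    parameter = names(est), estimate = unname(est), se = unname(se),
    rse_percent = 100 * unname(se) / abs(unname(est)),
    lower95 = unname(est) - 1.96 * unname(se),
    upper95 = unname(est) + 1.96 * unname(se)
  )
  attr(out, "ofv") <- fit$ofv
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, na = "")
    cat(sprintf("# ofv,%0.6f\n", fit$ofv), file = path, append = TRUE)
    return(invisible(out))
  }
  out
}
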