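# Likelihood-ratio covariate screening on the OFV (-2 log-likelihood) scale.
#
# For nested models differing in one parameter the decision ladder
# 3.86 / 6.63 / 7.88 / 11.87 at the 5 / 1 / 0.5 / 0.1% levels is used
# verbatim by default. (The 0.1% entry differs slightly from the exact
# chi-square quantile 10.828; `use_ladder = FALSE` switches to exact
# quantiles.) For df > 1 or non-ladder levels the exact quantile is always
# used.

OFV_LADDER <- c(`0.05` = 3.86, `0.01` = 6.63, `0.005` = 7.88, `0.001` = 11.87)

#' Likelihood-ratio test on the OFV scale
#'
#' @param ofv_reduced OFV of the reduced (nested) model.
#' @param ofv_full OFV of the full model; must not exceed `ofv_reduced` by
#'   more than `tolerance` (nesting).
#' @param df degrees of freedom (parameters added), >= 1.
#' @param alpha significance level.
#' @param use_ladder use the fixed df=1 decision ladder when applicable.
#' @param tolerance slack allowed on the nesting inequality.
#' @return object of class `lrt_result`: list with `delta_ofv`, `df`,
#'   `alpha`, `threshold`, `significant`.
#' @export
lrt <- function(ofv_reduced, ofv_full, df = 1L, alpha = 0.05,
                use_ladder = TRUE, tolerance = 1e-6) {
  stopifnot(df >= 1)
  delta <- ofv_reduced - ofv_full
  if (delta < -tolerance) {
    stop(sprintf("nesting violated: reduced OFV (%.6g) below full OFV (%.6g)",
                 ofv_reduced, ofv_full), call. = FALSE)
  }
  delta <- max(delta, 0)
  key <- as.character(alpha)
  threshold <- if (use_ladder && df == 1L && key %in% names(OFV_LADDER)) {
    unname(OFV_LADDER[key])
  } else {
    stats::qchisq(1 - alpha, df = df)
  }
  structure(list(delta_ofv = delta, df = as.integer(df), alpha = alpha,
                 threshold = threshold,
                 significant = delta >= threshold - 1e-9), # ties reach the ladder
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt> dOFV = %.4f vs %.3f (df = %d, alpha = %g): %s\n",
              x$delta_ofv, x$threshold, x$df, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Greedy forward covariate screen
#'
#' At each round every remaining candidate is added singly to the current
#' model; the candidate with the largest significant OFV drop is retained.
#' The screen stops when no remaining addition is significant. Inner fit
#' failures are recorded in the trace and the candidate is skipped for that
#' round.
#'
#' @param fit_fun closure taking a character vector of covariate keys and
#'   returning a list with at least `ofv` (and optionally `converged`).
#' @param candidates character vector of candidate covariate keys.
#' @param alpha_add inclusion level (each addition is 1 df).
#' @param use_ladder see [lrt()].
#' @return list with `selected` (keys in inclusion order), `trace` (tibble
#'   with one row per candidate per round), `final_ofv`, `base_ofv`.
#' @export
forward_covariate_screen <- function(fit_fun, candidates, alpha_add = 0.05,
                                     use_ladder = TRUE) {
  base <- fit_fun(character(0))
  base_ofv <- base$ofv
  current <- character(0)
  current_ofv <- base_ofv
  remaining <- candidates
  rows <- list()
  round <- 0L
  while (length(remaining)) {
    round <- round + 1L
    deltas <- rep(NA_real_, length(remaining))
    notes <- rep("", length(remaining))
    ths <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      fit <- tryCatch(fit_fun(c(current, remaining[i])), error = function(e) e)
      if (inherits(fit, "error")) {
        notes[i] <- paste("fit failed:", conditionMessage(fit))
        next
      }
      if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
        notes[i] <- "fit did not converge"
        next
      }
      res <- tryCatch(lrt(current_ofv, fit$ofv, df = 1L, alpha = alpha_add,
                          use_ladder = use_ladder), error = function(e) e)
      if (inherits(res, "error")) {
        notes[i] <- conditionMessage(res)
        next
      }
      deltas[i] <- res$delta_ofv
      ths[i] <- res$threshold
    }
    sig <- !is.na(deltas) & !is.na(ths) & deltas >= ths
    pick <- if (any(sig)) remaining[which.max(ifelse(sig, deltas, -Inf))] else NA_character_
    rows[[round]] <- tibble::tibble(
      round = round, candidate = remaining, delta_ofv = deltas,
      threshold = ths, significant = sig,
      selected = !is.na(pick) & remaining == pick, note = notes
    )
    if (is.na(pick)) break
    current <- c(current, pick)
    current_ofv <- current_ofv - deltas[remaining == pick]
    remaining <- setdiff(remaining, pick)
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(round = integer(), candidate = character(),
                   delta_ofv = numeric(), threshold = numeric(),
                   significant = logical(), selected = logical(),
                   note = character())
  list(selected = current, trace = trace, final_ofv = current_ofv,
       base_ofv = base_ofv)
}
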