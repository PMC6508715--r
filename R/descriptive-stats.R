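# Descriptive analyses: Spearman rank correlations between clinical and
# pathologic staging/response, cohort characteristic summaries, and
# Kaplan-Meier point reads.

#' Spearman rank correlation
#'
#' Rank correlation with average (mid) ranks for ties, i.e. the Pearson
#' correlation of midranks, computed on pairwise-complete observations.
#' Returns `NA` (with a warning) when either variable is constant after
#' filtering, since the coefficient is then undefined.
#'
#' @param x,y ordinal/numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 pairwise-complete observations", call. = FALSE)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Clinical-pathologic staging concordance
#'
#' Spearman correlations between the baseline clinical and the post-surgery
#' pathologic assessments:
#' * `rho_t`: baseline clinical T rank (diagnosis visit) vs pathologic ypT
#'   rank;
#' * `rho_n`: baseline nodal positivity (cN+, 0/1) vs pathologic ypN rank;
#' * `rho_response`: final clinical response category (last clinical visit
#'   with a non-missing response) vs the pathologic response category derived
#'   by applying the downstage / no-change / upstage rule to the change from
#'   baseline (cT, cN+) to (ypT, ypN > 0) -- nodal change is compared on
#'   positivity since the baseline N assessment is binary.
#'
#' Patients lacking either side (e.g. not operated) are dropped pairwise.
#'
#' @param cohort a `cohort_table`.
#' @return named list `rho_t`, `rho_n`, `rho_response`.
#' @export
staging_concordance <- function(cohort) {
  p <- cohort$patients
  v <- cohort$visits
  dx <- v[v$visit_index == 1L, ]
  ct <- dx$clinical_t[match(p$patient_id, dx$patient_id)]
  if (all(is.na(ct)) || all(is.na(p$ypt))) {
    stop("no complete clinical/pathologic staging pairs", call. = FALSE)
  }
  cn <- as.integer(p$ct_n_positive)

  clin <- v[v$visit_index %in% 1:3 & !is.na(v$response_dv), ]
  clin <- clin[order(clin$patient_id, clin$visit_index), ]
  last <- clin[!duplicated(clin$patient_id, fromLast = TRUE), ]
  final_dv <- last$response_dv[match(p$patient_id, last$patient_id)]

  path_resp <- mapply(function(ct_i, cn_i, ypt_i, ypn_i) {
    if (is.na(ct_i) || is.na(cn_i) || is.na(ypt_i) || is.na(ypn_i)) return(NA_integer_)
    derive_response(c(ct_i, ypt_i), c(cn_i, as.integer(ypn_i > 0)))[2]
  }, ct, cn, p$ypt, p$ypn)

  list(
    rho_t = spearman_rho(ct, p$ypt),
    rho_n = spearman_rho(cn, p$ypn),
    rho_response = spearman_rho(final_dv, path_resp)
  )
}

#' Cohort characteristics summary
#'
#' Counts and percentages for every categorical characteristic block of the
#' study table (sex, ECOG, tumour site, location, clinical T/N/TNM stage,
#' grade, linitis, Lauren type, treatment arm, pathologic ypT/ypN), the
#' median (range) of age, and the complete-pathologic-response count via
#' [derive_pcr()]. Percentages within a block sum to 100 up to rounding and
#' are computed over non-missing values.
#'
#' @param cohort a non-empty `cohort_table`.
#' @return list with `table` (tibble: block, level, n, percent), `age`
#'   (median, min, max), `pcr` (n, percent of patients with pathology).
#' @export
summarize_cohort <- function(cohort) {
  p <- cohort$patients
  stopifnot(nrow(p) >= 1)
  blocks <- list(
    sex = p$sex,
    ecog = p$ecog,
    tumor_site = p$tumor_site,
    location = p$location,
    clinical_t = {
      dx <- cohort$visits[cohort$visits$visit_index == 1L, ]
      dx$clinical_t[match(p$patient_id, dx$patient_id)]
    },
    cn_positive = p$ct_n_positive,
    ctnm_stage = p$ctnm_stage,
    grade = p$grade,
    linitis = p$linitis,
    lauren = p$lauren,
    treatment = p$treatment,
    ypt = p$ypt,
    ypn = p$ypn
  )
  rows <- list()
  for (nm in names(blocks)) {
    x <- blocks[[nm]]
    x <- x[!is.na(x)]
    if (!length(x)) next
    tab <- table(x)
    rows[[nm]] <- tibble::tibble(block = nm, level = names(tab),
                                 n = as.integer(tab),
                                 percent = 100 * as.integer(tab) / sum(tab))
  }
  pcr <- derive_pcr(p$ypt, p$ypn)
  n_path <- sum(!is.na(pcr))
  list(
    table = do.call(rbind, rows),
    age = c(median = stats::median(p$age_years, na.rm = TRUE),
            min = suppressWarnings(min(p$age_years, na.rm = TRUE)),
            max = suppressWarnings(max(p$age_years, na.rm = TRUE))),
    pcr = c(n = sum(pcr, na.rm = TRUE),
            percent = if (n_path) 100 * sum(pcr, na.rm = TRUE) / n_path else NA_real_)
  )
}
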