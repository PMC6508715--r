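# Cohort container, validation, response-category derivation and CSV I/O.
#
# The canonical on-disk format is three CSV files (patients.csv, visits.csv,
# events.csv), UTF-8, comma-separated, RFC-4180 quoting, with missing values
# written as empty cells. Ordinal TNM encodings used throughout:
#   T ranks:    T0 < T1 < T2 < T3 < T4a < T4b  ->  0..5
#   N ranks:    N0 < N1 < N2 < N3a < N3b       ->  0..4
#   cTNM stage: Ib < II < III                  ->  1 < 2 < 3
# Time is days since diagnosis (0-based, continuous).

PATIENT_COLS <- c(
  patient_id = "character", age_years = "numeric", sex = "character",
  ecog = "integer", tumor_site = "character", location = "character",
  linitis = "logical", lauren = "character", grade = "character",
  her2 = "logical", ctnm_stage = "integer", treatment = "character",
  dose_intensity = "numeric", ct_n_positive = "logical",
  ypt = "integer", ypn = "integer"
)
VISIT_COLS <- c(
  patient_id = "character", visit_index = "integer", time_days = "numeric",
  clinical_t = "integer", clinical_n = "logical", response_dv = "integer"
)
EVENT_COLS <- c(
  patient_id = "character", event_type = "character", time_days = "numeric",
  observed = "logical"
)

PATIENT_OPTIONAL <- c("her2", "dose_intensity", "ypt", "ypn")
VISIT_OPTIONAL <- c("clinical_t", "clinical_n")

SEX_LEVELS <- c("male", "female")
SITE_LEVELS <- c("gastric", "gej")
LOCATION_LEVELS <- c("cardias", "antrum", "body", "pylorus")
LAUREN_LEVELS <- c("diffuse", "intestinal")
GRADE_LEVELS <- c("well", "moderate", "poor")
TREATMENT_LEVELS <- c("ChT", "CRT")
EVENT_LEVELS <- c("metastasis", "death")

#' Assemble a cohort table
#'
#' Bundles the three long-format tables of the analysis -- per-patient
#' covariates, per-visit tumour-response observations and time-to-event
#' records -- into a single validated container. Columns are coerced to the
#' canonical types; missing optional columns are added as all-missing.
#'
#' @param patients data frame of patient-level covariates (one row per
#'   patient). Mandatory columns: `patient_id`, `age_years`, `sex`, `ecog`,
#'   `tumor_site`, `location`, `linitis`, `lauren`, `grade`, `ctnm_stage`,
#'   `treatment`, `ct_n_positive`. Optional: `her2`, `dose_intensity`,
#'   `ypt`, `ypn`.
#' @param visits data frame with `patient_id`, `visit_index` (1--4, 1 =
#'   diagnosis, 4 = surgery/pathology), `time_days`, `response_dv`
#'   (0 = partial response, 1 = stable disease, 2 = disease progression) and
#'   optional `clinical_t`, `clinical_n`.
#' @param events data frame with `patient_id`, `event_type`
#'   (`"metastasis"`/`"death"`), `time_days`, `observed` (`FALSE` means
#'   right-censored at `time_days`).
#' @param validate if `TRUE` (default) stop on any invariant violation,
#'   listing all of them.
#' @return an object of class `cohort_table`: a list with elements
#'   `patients`, `visits`, `events` (tibbles).
#' @export
cohort_table <- function(patients, visits, events, validate = TRUE) {
  ct <- structure(
    list(
      patients = .coerce_table(patients, PATIENT_COLS, PATIENT_OPTIONAL, "patients"),
      visits = .coerce_table(visits, VISIT_COLS, VISIT_OPTIONAL, "visits"),
      events = .coerce_table(events, EVENT_COLS, character(0), "events")
    ),
    class = "cohort_table"
  )
  ord <- order(ct$visits$patient_id, ct$visits$visit_index)
  ct$visits <- ct$visits[ord, ]
  if (validate) assert_valid_cohort(ct)
  ct
}

.coerce_table <- function(df, cols, optional, what) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  mandatory <- setdiff(names(cols), optional)
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s table is missing mandatory column(s): %s",
                 what, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (nm in setdiff(names(cols), names(df))) {
    df[[nm]] <- rep(NA, nrow(df))
  }
  df <- df[names(cols)]
  for (nm in names(cols)) {
    df[[nm]] <- switch(cols[[nm]],
      character = as.character(df[[nm]]),
      numeric = as.numeric(df[[nm]]),
      integer = as.integer(df[[nm]]),
      logical = .as_logical(df[[nm]], nm)
    )
  }
  tibble::as_tibble(df)
}

.as_logical <- function(x, nm) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  if (is.character(x)) {
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "true", "T", "1", "yes")] <- TRUE
    out[x %in% c("FALSE", "false", "F", "0", "no")] <- FALSE
    return(out)
  }
  as.logical(x)
}

#' Validate a cohort table
#'
#' Checks every cohort invariant and returns the complete list of violations
#' (an empty character vector when the cohort is valid) rather than stopping
#' at the first.
#'
#' @param cohort a `cohort_table`.
#' @return character vector of human-readable violation messages.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  p <- cohort$patients; v <- cohort$visits; e <- cohort$events
  bad <- character(0)
  add <- function(msg) bad[[length(bad) + 1L]] <<- msg

  if (anyDuplicated(p$patient_id)) {
    add(sprintf("duplicate patient_id in patients: %s",
                paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", ")))
  }
  chk_level <- function(x, levels, nm) {
    off <- !is.na(x) & !(x %in% levels)
    if (any(off)) add(sprintf("patients$%s outside {%s} in rows %s", nm,
                              paste(levels, collapse = ", "),
                              paste(which(off), collapse = ", ")))
  }
  chk_level(p$sex, SEX_LEVELS, "sex")
  chk_level(p$tumor_site, SITE_LEVELS, "tumor_site")
  chk_level(p$location, LOCATION_LEVELS, "location")
  chk_level(p$lauren, LAUREN_LEVELS, "lauren")
  chk_level(p$grade, GRADE_LEVELS, "grade")
  chk_level(p$treatment, TREATMENT_LEVELS, "treatment")
  chk_level(p$ecog, 0:1, "ecog")
  chk_level(p$ctnm_stage, 1:3, "ctnm_stage")
  if (any(!is.na(p$age_years) & p$age_years < 18)) {
    add(sprintf("age_years < 18 in patient rows %s",
                paste(which(!is.na(p$age_years) & p$age_years < 18), collapse = ", ")))
  }
  di_bad <- !is.na(p$dose_intensity) & (p$dose_intensity <= 0 | p$dose_intensity > 1)
  if (any(di_bad)) add(sprintf("dose_intensity outside (0,1] in rows %s",
                               paste(which(di_bad), collapse = ", ")))
  if (any(!is.na(p$ypt) & (p$ypt < 0 | p$ypt > 5))) add("ypt rank outside 0..5")
  if (any(!is.na(p$ypn) & (p$ypn < 0 | p$ypn > 4))) add("ypn rank outside 0..4")
  mix <- xor(is.na(p$ypt), is.na(p$ypn))
  if (any(mix)) {
    add(sprintf("ypt/ypn must be jointly present (surgery) or jointly missing; rows %s",
                paste(which(mix), collapse = ", ")))
  }

  orphan_v <- setdiff(unique(v$patient_id), p$patient_id)
  if (length(orphan_v)) add(sprintf("visits reference unknown patient_id: %s",
                                    paste(orphan_v, collapse = ", ")))
  orphan_e <- setdiff(unique(e$patient_id), p$patient_id)
  if (length(orphan_e)) add(sprintf("events reference unknown patient_id: %s",
                                    paste(orphan_e, collapse = ", ")))
  if (any(!is.na(v$visit_index) & !(v$visit_index %in% 1:4))) add("visit_index outside 1..4")
  if (any(!is.na(v$response_dv) & !(v$response_dv %in% 0:2))) add("response_dv outside {0,1,2}")
  if (any(!is.na(v$time_days) & v$time_days < 0)) add("negative visit time_days")
  dx <- v$visit_index == 1L & !is.na(v$response_dv) & v$response_dv != 2L
  if (any(dx)) {
    add(sprintf("response_dv at diagnosis visit must be 2 (all patients progressing at diagnosis): patients %s",
                paste(unique(v$patient_id[dx]), collapse = ", ")))
  }
  if (nrow(v)) {
    cnt <- table(v$patient_id)
    over <- names(cnt)[cnt > 4L]
    if (length(over)) add(sprintf("more than 4 visits for patients %s",
                                  paste(over, collapse = ", ")))
    key <- paste(v$patient_id, v$visit_index)
    if (anyDuplicated(key)) {
      add(sprintf("duplicate visit_index within patients %s",
                  paste(unique(v$patient_id[duplicated(key)]), collapse = ", ")))
    }
    vo <- v[order(v$patient_id, v$visit_index), ]
    if (nrow(vo) > 1) {
      same <- vo$patient_id[-1] == vo$patient_id[-nrow(vo)]
      nonmono <- same & (vo$time_days[-1] <= vo$time_days[-nrow(vo)])
      if (any(nonmono, na.rm = TRUE)) {
        add(sprintf("visit times not strictly increasing for patients %s",
                    paste(unique(vo$patient_id[-1][nonmono %in% TRUE]),
                          collapse = ", ")))
      }
    }
  }
  if (any(!is.na(e$event_type) & !(e$event_type %in% EVENT_LEVELS))) {
    add("event_type outside {metastasis, death}")
  }
  if (any(!is.na(e$time_days) & e$time_days <= 0)) add("event time_days must be positive")
  key <- paste(e$patient_id, e$event_type)
  if (anyDuplicated(key)) {
    add(sprintf("more than one record per (patient, event_type): %s",
                paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  met <- e[e$event_type == "metastasis" & e$observed %in% TRUE, ]
  dth <- e[e$event_type == "death", ]
  both <- merge(met[c("patient_id", "time_days")], dth[c("patient_id", "time_days")],
                by = "patient_id", suffixes = c("_met", "_death"))
  late <- both$time_days_met > both$time_days_death
  if (any(late)) {
    add(sprintf("metastasis after death/censoring for patients %s",
                paste(both$patient_id[late], collapse = ", ")))
  }
  bad
}

#' @rdname validate_cohort
#' @export
assert_valid_cohort <- function(cohort) {
  bad <- validate_cohort(cohort)
  if (length(bad)) {
    stop(paste0("invalid cohort:\n", paste("  -", bad, collapse = "\n")), call. = FALSE)
  }
  invisible(cohort)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients, %d visits, %d event records\n",
              nrow(x$patients), nrow(x$visits), nrow(x$events)))
  invisible(x)
}

# ---- I/O -------------------------------------------------------------------

.read_one <- function(path, column_map, cols, optional, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- tryCatch({
    if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
      as.data.frame(readxl::read_excel(path))
    } else {
      utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
                      check.names = FALSE)
    }
  }, error = function(e) stop(sprintf("cannot parse %s table from '%s': %s",
                                      what, path, conditionMessage(e)), call. = FALSE))
  if (!is.null(column_map)) {
    mandatory <- setdiff(names(cols), optional)
    unmapped <- setdiff(mandatory, names(column_map))
    if (length(unmapped)) {
      stop(sprintf("column_map for %s does not cover mandatory field(s): %s",
                   what, paste(unmapped, collapse = ", ")), call. = FALSE)
    }
    absent <- setdiff(unlist(column_map), names(raw))
    if (length(absent)) {
      fields <- names(column_map)[unlist(column_map) %in% absent]
      stop(sprintf("%s: mapped source column(s) absent for field(s) %s",
                   what, paste(fields, collapse = ", ")), call. = FALSE)
    }
    out <- raw[, unlist(column_map), drop = FALSE]
    names(out) <- names(column_map)
    raw <- out
  }
  raw
}

#' Read a cohort from disk
#'
#' Reads the canonical three-table cohort (patients/visits/events). `path`
#' may be a directory containing `patients.csv`, `visits.csv`, `events.csv`,
#' or a named list/vector with elements `patients`, `visits`, `events` giving
#' individual file paths (`.csv` or single-sheet `.xlsx` exports). When the
#' source files use non-canonical column names (e.g. a spreadsheet export of
#' the study database), supply `column_map`.
#'
#' @param path directory or named list of three file paths.
#' @param column_map `NULL` (identity) or a named list with elements
#'   `patients`, `visits`, `events`, each a named character vector mapping
#'   canonical field name -> source column name. An example map ships in
#'   `inst/extdata/example_column_map.yaml`.
#' @param validate validate invariants after reading (default `TRUE`).
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, column_map = NULL, validate = TRUE) {
  if (is.character(path) && length(path) == 1L && dir.exists(path)) {
    path <- list(patients = file.path(path, "patients.csv"),
                 visits = file.path(path, "visits.csv"),
                 events = file.path(path, "events.csv"))
  }
  stopifnot(all(c("patients", "visits", "events") %in% names(path)))
  cm <- function(part) if (is.null(column_map)) NULL else column_map[[part]]
  cohort_table(
    patients = .read_one(path$patients, cm("patients"), PATIENT_COLS, PATIENT_OPTIONAL, "patients"),
    visits = .read_one(path$visits, cm("visits"), VISIT_COLS, VISIT_OPTIONAL, "visits"),
    events = .read_one(path$events, cm("events"), EVENT_COLS, character(0), "events"),
    validate = validate
  )
}

#' Write a cohort to disk
#'
#' Writes `patients.csv`, `visits.csv` and `events.csv` under `dir` in the
#' canonical dialect (UTF-8, comma-separated, header row, missing values as
#' empty cells) such that `read_cohort()` recovers a structurally identical
#' cohort.
#'
#' @param cohort a valid `cohort_table`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "visits.csv", "events.csv"))
  tabs <- list(cohort$patients, cohort$visits, cohort$events)
  for (i in seq_along(paths)) {
    df <- as.data.frame(tabs[[i]])
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), NA_character_, format(x, digits = 15, trim = TRUE, scientific = FALSE))
    })
    tryCatch(
      utils::write.csv(df, paths[i], row.names = FALSE, na = "", fileEncoding = "UTF-8"),
      error = function(e) stop(sprintf("cannot write '%s': %s", paths[i],
                                       conditionMessage(e)), call. = FALSE)
    )
  }
  invisible(stats::setNames(paths, c("patients", "visits", "events")))
}

# ---- Response-category derivation ------------------------------------------

#' Derive per-visit response categories from TNM stage ranks
#'
#' Categorises the per-visit change in TNM stage into the three-level
#' response variable used by the longitudinal model: 0 = partial response
#' (downstaging relative to the previous visit), 1 = stable disease (no
#' change), 2 = disease progression (upstaging). The diagnosis visit is, by
#' the model's structural assumption, always category 2.
#'
#' When both T and N sequences are supplied the combined rule is used:
#' upstaging in either dimension gives 2; otherwise downstaging in either
#' gives 0; otherwise 1. A missing stage at an interior visit propagates a
#' missing response (never imputed).
#'
#' @param t_ranks integer vector of T stage ranks per visit (0..5 scale).
#' @param n_ranks optional integer vector of N ranks per visit, same length.
#' @return integer vector of response categories, same length as input.
#' @export
derive_response <- function(t_ranks, n_ranks = NULL) {
  stopifnot(length(t_ranks) >= 1)
  if (!is.null(n_ranks)) stopifnot(length(n_ranks) == length(t_ranks))
  n <- length(t_ranks)
  out <- rep(NA_integer_, n)
  out[1] <- 2L
  if (n == 1L) return(out)
  dt <- diff(as.numeric(t_ranks))
  dn <- if (is.null(n_ranks)) rep(0, n - 1L) else diff(as.numeric(n_ranks))
  up <- (dt > 0) | (dn > 0)
  down <- (dt < 0) | (dn < 0)
  out[-1] <- ifelse(is.na(up) | is.na(down), NA_integer_,
                    ifelse(up, 2L, ifelse(down, 0L, 1L)))
  out
}

#' Complete pathologic response (ypT0 ypN0)
#'
#' `TRUE` iff the post-surgery specimen shows no residual tumour: pathologic
#' T rank 0 and N rank 0. Missing pathology (patient did not reach surgery)
#' yields `NA`.
#'
#' @param ypt,ypn pathologic T and N ranks (vectors recycle together).
#' @return logical vector.
#' @export
derive_pcr <- function(ypt, ypn) {
  ifelse(is.na(ypt) | is.na(ypn), NA, ypt == 0L & ypn == 0L)
}
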