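test_that("response derivation maps stage changes to the three categories", {
  # T3 -> T2 -> T0: downstaging at both follow-ups
  expect_identical(derive_response(c(3L, 2L, 0L)), c(2L, 0L, 0L))
  # no change
  expect_identical(derive_response(c(3L, 3L)), c(2L, 1L))
  # upstaging
  expect_identical(derive_response(c(2L, 4L)), c(2L, 2L))
  # combined T/N rule: any upstaging dominates a downstage elsewhere
  expect_identical(derive_response(c(3L, 2L), n_ranks = c(1L, 2L)), c(2L, 2L))
  expect_identical(derive_response(c(3L, 2L), n_ranks = c(1L, 1L)), c(2L, 0L))
  expect_identical(derive_response(c(3L, 3L), n_ranks = c(1L, 0L)), c(2L, 0L))
  # missing interior stage propagates missing response, never imputes
  expect_identical(derive_response(c(3L, NA, 2L)), c(2L, NA, NA))
})

test_that("response derivation invariants hold on random stage sequences", {
  set.seed(41)
  for (i in 1:200) {
    len <- sample(1:4, 1)
    tr <- sample(0:5, len, replace = TRUE)
    nr <- if (runif(1) < 0.5) sample(0:4, len, replace = TRUE) else NULL
    out <- derive_response(tr, nr)
    expect_length(out, len)
    expect_identical(out[1], 2L)
    expect_true(all(out %in% c(0L, 1L, 2L)))
  }
})

test_that("complete pathologic response requires ypT0 and ypN0", {
  expect_true(derive_pcr(0L, 0L))
  expect_false(derive_pcr(0L, 1L))
  expect_false(derive_pcr(2L, 0L))
  expect_identical(derive_pcr(NA_integer_, 0L), NA)
  # on a generated cohort the pCR count equals the generator's injected count
  co <- simulate_cohort(simulation_config(n_patients = 200, seed = 5))
  expect_identical(sum(derive_pcr(co$patients$ypt, co$patients$ypn), na.rm = TRUE),
                   as.integer(attr(co, "n_pcr")))
})

test_that("write/read round-trips a synthetic cohort structurally", {
  co <- simulate_cohort(simulation_config(n_patients = 30, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (part in c("patients", "visits", "events")) {
    expect_equal(as.data.frame(back[[part]]), as.data.frame(co[[part]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("empty cohort writes header-only files and missing ypt is an empty cell", {
  empty <- cohort_table(
    data.frame(patient_id = character(), age_years = numeric(),
               sex = character(), ecog = integer(), tumor_site = character(),
               location = character(), linitis = logical(), lauren = character(),
               grade = character(), ctnm_stage = integer(),
               treatment = character(), ct_n_positive = logical()),
    data.frame(patient_id = character(), visit_index = integer(),
               time_days = numeric(), response_dv = integer()),
    data.frame(patient_id = character(), event_type = character(),
               time_days = numeric(), observed = logical())
  )
  dir <- withr::local_tempdir()
  write_cohort(empty, dir)
  lines <- readLines(file.path(dir, "patients.csv"))
  expect_length(lines, 1L)

  co <- mk_cohort(list(c(2L, 1L)))
  write_cohort(co, dir)
  pat_lines <- readLines(file.path(dir, "patients.csv"))
  # ypt/ypn are missing for the fixture patient: trailing empty cells, no sentinel
  expect_match(pat_lines[2], ",,$")
  expect_no_match(pat_lines[2], "-99|NaN")
})

test_that("validation reports every violation, not only the first", {
  co <- mk_cohort(list(c(2L, 1L), c(2L, 0L)))
  co$events <- rbind(co$events, tibble::tibble(
    patient_id = c("S01", "GHOST"), event_type = c("metastasis", "death"),
    time_days = c(1500, 100), observed = c(TRUE, TRUE)))
  bad <- validate_cohort(co)
  expect_true(any(grepl("metastasis after death", bad)))
  expect_true(any(grepl("unknown patient_id", bad)))
  expect_gte(length(bad), 2L)
  expect_error(assert_valid_cohort(co), "metastasis after death")
})

test_that("diagnosis-visit category and visit-time ordering are enforced", {
  co <- mk_cohort(list(c(2L, 1L)))
  co$visits$response_dv[1] <- 0L
  expect_true(any(grepl("diagnosis", validate_cohort(co))))
  co2 <- mk_cohort(list(c(2L, 1L, 1L)))
  co2$visits$time_days[3] <- 10
  expect_true(any(grepl("strictly increasing", validate_cohort(co2))))
})

test_that("column-mapped reading handles renamed and unknown columns", {
  co <- simulate_cohort(simulation_config(n_patients = 10, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  # scramble the patients header and add an ignorable extra column
  p <- utils::read.csv(file.path(dir, "patients.csv"), na.strings = "")
  names(p) <- paste0("col_", names(p))
  p$noise <- seq_len(nrow(p))
  utils::write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE, na = "")
  cmap <- list(patients = stats::setNames(
    paste0("col_", names(neogastric:::PATIENT_COLS)),
    names(neogastric:::PATIENT_COLS)))
  back <- read_cohort(dir, column_map = cmap)
  expect_equal(as.data.frame(back$patients), as.data.frame(co$patients),
               tolerance = 1e-9, ignore_attr = TRUE)
  # an incomplete map errors naming the missing canonical field
  expect_error(read_cohort(dir, column_map = list(patients = c(patient_id = "col_patient_id"))),
               "age_years")
  # a map pointing at an absent source column names the affected field
  cmap$patients[["sex"]] <- "no_such_column"
  expect_error(read_cohort(dir, column_map = cmap), "sex")
})
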