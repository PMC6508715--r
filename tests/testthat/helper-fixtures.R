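# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except in the explicit I/O tests.

# Minimal single/multi-subject cohort from a list of response trajectories.
mk_cohort <- function(dv_list, event_times = NULL) {
  n <- length(dv_list)
  ids <- sprintf("S%02d", seq_len(n))
  pats <- data.frame(
    patient_id = ids, age_years = 60, sex = "male", ecog = 1L,
    tumor_site = "gastric", location = "body", linitis = FALSE,
    lauren = "diffuse", grade = "poor", ctnm_stage = 3L, treatment = "ChT",
    ct_n_positive = TRUE, stringsAsFactors = FALSE
  )
  vis <- do.call(rbind, lapply(seq_len(n), function(i) {
    dv <- dv_list[[i]]
    data.frame(patient_id = ids[i], visit_index = seq_along(dv),
               time_days = c(0, 42, 84, 120)[seq_along(dv)],
               response_dv = dv, stringsAsFactors = FALSE)
  }))
  if (is.null(event_times)) event_times <- rep(1000, n)
  ev <- data.frame(patient_id = ids, event_type = "death",
                   time_days = event_times, observed = FALSE,
                   stringsAsFactors = FALSE)
  cohort_table(pats, vis, ev)
}

# All category sequences of a given length (every visit free to take any of
# the three categories; the diagnosis term then normalises over its own
# category as well, so the probabilities of the full set sum to exactly 1).
all_trajectories <- function(len) {
  g <- expand.grid(rep(list(0:2), len))
  lapply(seq_len(nrow(g)), function(i) as.integer(unlist(g[i, ])))
}

# Event data frame for direct survival-likelihood tests.
mk_event_data <- function(time, observed, stage3 = FALSE, linitis = FALSE,
                          t_met = NA_real_) {
  data.frame(time = time, observed = observed, stage3 = stage3,
             linitis = linitis, t_met = t_met)
}
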