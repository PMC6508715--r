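#!/usr/bin/env Rscript
# Stage 2: descriptive analyses of the cohort.
#
# Characteristics table (counts/percentages per block, age, pCR) and the
# clinical-pathologic staging concordance (Spearman correlations for T, N
# and response category). The study's striking finding -- that clinical and
# pathologic staging correlate poorly -- is what the concordance block
# quantifies.

suppressPackageStartupMessages(library(neogastric))

cohort <- read_cohort("results/cohort")
dir.create("results/descriptive", recursive = TRUE, showWarnings = FALSE)

summ <- summarize_cohort(cohort)
utils::write.csv(summ$table, "results/descriptive/characteristics.csv",
                 row.names = FALSE)
conc <- staging_concordance(cohort)
utils::write.csv(
  data.frame(quantity = c("rho_t", "rho_n", "rho_response",
                          "age_median", "age_min", "age_max",
                          "pcr_n", "pcr_percent"),
             value = c(conc$rho_t, conc$rho_n, conc$rho_response,
                       summ$age, summ$pcr)),
  "results/descriptive/concordance.csv", row.names = FALSE)

message(sprintf("Staging concordance: rho_T = %.2f, rho_N = %.2f, rho_response = %.2f",
                conc$rho_t, conc$rho_n, conc$rho_response))
message(sprintf("pCR: %d patients (%.1f%%); median age %g (range %g-%g)",
                summ$pcr[["n"]], summ$pcr[["percent"]], summ$age[["median"]],
                summ$age[["min"]], summ$age[["max"]]))
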