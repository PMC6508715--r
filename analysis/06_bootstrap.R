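#!/usr/bin/env Rscript
# Stage 6: nonparametric bootstrap of parameter uncertainty.
#
# 200 subject-resampled replicates of the overall-survival fit and of the
# clinical response fit; each parameter's replicate distribution is
# summarised by its 2.5th/50th/97.5th percentiles. The response refits
# integrate the random effect by quadrature, so this stage is the slowest of
# the analysis (a few minutes).

suppressPackageStartupMessages(library(neogastric))

cohort <- read_cohort("results/cohort")
dir.create("results/bootstrap", recursive = TRUE, showWarnings = FALSE)

os_boot <- bootstrap_fits(cohort, function(b) {
  f <- fit_survival_model(os_event_data(b), compute_covariance = FALSE)
  list(estimates = f$estimates, converged = f$converged)
}, n_boot = 200, seed = 601)
utils::write.csv(os_boot$summary, "results/bootstrap/os.csv", row.names = FALSE)
message(sprintf("OS bootstrap: %d/200 converged%s", os_boot$n_converged,
                if (os_boot$unreliable) " [UNRELIABLE]" else ""))

resp_boot <- bootstrap_fits(cohort, function(b) {
  f <- fit_response_model(b, init = response_params(), method = "quadrature",
                          compute_covariance = FALSE)
  list(estimates = f$estimates, converged = f$converged)
}, n_boot = 200, seed = 602)
utils::write.csv(resp_boot$summary, "results/bootstrap/response.csv",
                 row.names = FALSE)
message(sprintf("Response bootstrap: %d/200 converged%s", resp_boot$n_converged,
                if (resp_boot$unreliable) " [UNRELIABLE]" else ""))
print(resp_boot$summary)
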