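#!/usr/bin/env Rscript
# Stage 5: model evaluation by visual predictive checks.
#
# 500 replicate datasets are simulated under the fitted models on the
# observed study design; per-visit category proportions (response model) and
# Kaplan-Meier curves (survival model, overall and stratified by metastasis
# appearance, baseline stage and linitis plastica) are summarised by their
# 2.5th/50th/97.5th percentiles with the observed statistics alongside.
# Percentile tables are written as CSV; any plotting is left to the reader.

suppressPackageStartupMessages(library(neogastric))

cohort <- read_cohort("results/cohort")
dir.create("results/vpc", recursive = TRUE, showWarnings = FALSE)

resp_params <- read_response_params("results/response/params_clinical.yaml")
os_params <- read_hazard_params("results/survival/params_os.yaml")
met_rate <- utils::read.csv("results/survival/fit_metastasis.csv",
                            nrows = 1)$estimate[1]

design <- vpc_design_from_cohort(cohort)
vc <- vpc_categorical(resp_params, design, n_sim = 500, observed = cohort,
                      seed = 501)
utils::write.csv(as.data.frame(vc), "results/vpc/categorical.csv",
                 row.names = FALSE)
inside <- mean(vc$observed >= vc$`p2.5` & vc$observed <= vc$`p97.5`, na.rm = TRUE)
message(sprintf("Categorical VPC (%d simulations): %.0f%% of visit/category cells inside the 95%% envelope",
                attr(vc, "n_sim"), 100 * inside))

grid <- seq(0, 3650, by = 73)
vs_all <- vpc_survival(os_params, design, met_rate = met_rate, time_grid = grid,
                       n_sim = 500, observed = cohort, seed = 502)
utils::write.csv(as.data.frame(vs_all), "results/vpc/km_overall.csv",
                 row.names = FALSE)
for (st in c("metastasis", "stage3", "linitis")) {
  vs <- vpc_survival(os_params, design, met_rate = met_rate, time_grid = grid,
                     n_sim = 500, stratify = st, observed = cohort,
                     seed = 503)
  utils::write.csv(as.data.frame(vs),
                   sprintf("results/vpc/km_by_%s.csv", st), row.names = FALSE)
}
ins <- with(vs_all[vs_all$time > 0, ],
            mean(observed >= `p2.5` & observed <= `p97.5`, na.rm = TRUE))
message(sprintf("KM VPC: %.0f%% of grid points inside the 95%% envelope", 100 * ins))
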