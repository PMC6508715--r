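# neogastric

Population pharmacodynamic modelling of neoadjuvant therapy in locally
advanced gastric and gastroesophageal-junction (GEJ) cancer.

Patients with locally advanced gastric/GEJ adenocarcinoma receive
chemotherapy (ChT) or chemoradiotherapy (CRT) before surgery. Their tumour
response is assessed at a handful of scheduled visits on an ordinal scale
derived from TNM stage change (0 = partial response / downstaging,
1 = stable disease / no change, 2 = disease progression / upstaging), and
their long-term outcome is described by time to metastasis appearance and
overall survival (OS). This package reimplements that analysis as a tested,
reusable pipeline for biostatisticians and pharmacometricians: the
longitudinal response model, the parametric survival models, the
likelihood-ratio covariate screen, the evaluation machinery (visual
predictive checks, nonparametric bootstrap), descriptive
staging-concordance analyses, and a synthetic-cohort generator that emulates
the 115-patient study design so every stage is runnable without the original
data.

## Models

**Tumour response.** An ordered-categorical (proportional-odds) mixed model
with first-order Markov elements. For subject *i* at visit *j*, the
cumulative probability of category *m* is

    P(Y_ij >= m | eta_i) = logistic(L_m),
    L_m = sum_{k<=m} beta_k - theta_{PVR(ij)} + sum_c theta_c x_ic + eta_i

where `PVR(ij)` is the response category observed at the previous visit (no
Markov term at diagnosis, where all patients are in the progression
category by design), `eta_i ~ N(0, omega^2)` is a subject random effect
shared by both cumulative logits, and category probabilities follow by
differencing: `P(Y = m) = P(Y >= m) - P(Y >= m+1)`. Markov and covariate
effects enter the logit **negatively**; this sign convention is what makes
the published parameter magnitudes (baseline logit ~19.7 against Markov
effects of 18–19.4) produce sensible transition probabilities. The marginal
likelihood integrates `eta` out per subject by the Laplace approximation,
adaptive Gauss–Hermite quadrature, or Monte Carlo.

**Survival.** Parametric time-to-event models for metastasis appearance and
OS with `S(t) = exp(-HZ(t))`, where the hazard is

    h(t) = [lambda0 + delta_stage·1(cTNM >= III) + delta_linitis·1(linitis)]
           · b(t) · exp(beta_met · 1(t >= t_met))

with `b(t)` = 1 (constant/exponential), Weibull or Gompertz time profiles.
Baseline covariates act additively on the rate; metastasis appearance acts
multiplicatively from its observed time onward (time-dependent switch), so
`exp(beta_met)` is the metastasis hazard ratio. Model selection uses the
−2LL decision ladder 3.86 / 6.63 / 7.88 / 11.87 (5 / 1 / 0.5 / 0.1%,
1 df).

## Worked example

```r
library(neogastric)

cohort <- simulate_cohort(simulation_config(n_patients = 115, seed = 42))
cohort
#> <cohort_table> 115 patients, 460 visits, 230 event records

unlist(staging_concordance(cohort))
#>        rho_t        rho_n rho_response
#>    0.3201870    0.2193581   -0.3361151

fit <- fit_survival_model(os_event_data(cohort))
hazard_ratio(fit$params, "metastasis")
#> [1] 42.00752

transition_matrix(response_params())
#>           PR        SD         DP
#> PR 0.1679816 0.7854879 0.04653047
#> SD 0.4255575 0.5613172 0.01312532
#> DP 0.2890505 0.6872889 0.02366058
```

The concordance block reproduces the study's central descriptive finding —
clinical and pathologic staging correlate weakly (the generator is
calibrated to rank correlations 0.32 for T and 0.19 for N, with sampling
noise at n = 115 visible above). The transition matrix at the published
response estimates shows the Markov structure: the chance of reaching
partial response at the next visit depends strongly on the current state
(42.6% from stable disease vs 16.8% from partial response). The fitted OS
hazard ratio for metastasis appearance estimates `exp(beta_met)`; its
generating value is `exp(3.43) ≈ 31`, and at n = 115 the estimate is
noisy (42.0 for this seed; the published relative standard error for this
parameter was 21%).

The full analysis is organised as numbered drivers under `analysis/`
(simulate → descriptives → response fit → survival fit + covariate screen →
VPCs → bootstrap), each writing CSV tables under `results/`.

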