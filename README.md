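# cytovar

Association screening and variance decomposition for stimulated
cytokine responses.

## The problem

Whole-blood stimulation assays measure how much of each cytokine a
donor's blood secretes after a fixed challenge (bacterial agonists,
viral mimics, T cell activators), alongside a non-stimulated control.
Across a healthy cohort these induced responses vary widely, and the
question is which donor characteristics — age, sex, smoking history,
latent CMV infection, body-mass index, genetics, DNA methylation,
circulating cell composition — drive that variability, and by how
much. `cytovar` implements the full statistical workflow for such
studies, together with a seeded synthetic-cohort generator that plants
known effects so every stage can be validated by parameter recovery.

## The methods

All models treat the natural-log concentration (floored at the
assay's lower limit of quantification) as a Gaussian outcome.

* **Induction profiling.** A cytokine is *induced* by a stimulation
  when its median concentration deviates from the null-condition
  median by at least 30%: `|median_stim / median_null − 1| ≥ 0.30`.
  Profiles are summarised by the standardized log mean difference
  `SLMD = mean(d) / sd(d)` over paired per-donor log differences `d`,
  and clustered (complete linkage, Euclidean distance). A k-means
  split (k = 2, canonicalized by centroid norm) isolates
  non-responders to T cell receptor cross-linking stimulations.
* **Variable screen.** For each eligible variable `v` and induced
  cytokine `y`, the nested pair `lm(y ~ v + age + sex + batch)` vs
  `lm(y ~ age + sex + batch)` is compared by the Gaussian
  profile-likelihood ratio statistic `n · ln(RSS₀/RSS₁) ~ χ²(df)`.
  Benjamini–Yekutieli correction is applied over the whole
  variable × cytokine family of one stimulation; the significance
  gate is adjusted p < 0.01. Effect sizes are exponentiated
  treatment-coded coefficients with t-based 95% CIs.
* **Mediation screen.** A mediator `M` (cell count, plasma protein or
  CpG beta) *eliminates* an association when
  `lm(y ~ v × M + age + sex + batch)` vs `lm(y ~ M + age + sex +
  batch)` is no longer significant while the baseline test was —
  covariate-elimination screening, not formal effect decomposition.
* **Response pQTLs.** Each SNP dosage (MAF > 5%) is regressed against
  each induced cytokine with covariates projected out once per scan
  (Frisch–Waugh residualization, numerically identical to per-SNP
  OLS). Detection thresholds are 10⁻³ (cis: within 1 Mb of the
  cytokine gene TSS) and 10⁻⁵ (trans), followed by Bonferroni control
  at 0.05 over the scan family. Conditional scans and
  genotype × smoking interaction LRTs probe hit independence and
  effect modification.
* **Variance decomposition.** Each cytokine's explained variance is
  split into nonnegative per-group shares by LMG (Shapley) averaging
  of sequential R² gains over all regressor-group orderings; shares
  sum to the full-model R².

## Worked example

```r
library(cytovar)
library(dplyr)

cfg <- sim_config(n_donors = 800)      # planted smoking/CMV/BMI effects
b   <- simulate_cohort(cfg, seed = 1)  # bundle + ground-truth ledger

ind <- flag_induced(b$cytokines, lloq = b$lloq)
scr <- screen_associations(b$cytokines, b$covariates, "SEB",
                           induced = ind, lloq = b$lloq)
glance(scr)
#>   stimulation n_tests n_significant alpha
#> 1 SEB             209             7  0.01
tidy(scr) %>% filter(significant) %>% arrange(p_adjusted) %>%
  select(variable, cytokine, lrt_statistic, p_adjusted)
#>   variable         cytokine lrt_statistic p_adjusted
#> 1 total_cigarettes IL6              102.    3.94e-21
#> 2 pack_years       IL6              102.    3.94e-21
#> 3 years_smoking    IL6               59.9   4.16e-12
#> 4 cmv_serostatus   IFNg              29.1   2.10e- 5
#> 5 smoking_status   IL2               27.4   2.75e- 4
#> 6 smoking_status   IL6               24.0   1.29e- 3
#> 7 cmv_serostatus   TNF               18.1   3.64e- 3
```

The screen recovers exactly the planted structure: the generator's
default ledger plants a ×1.5 smoking effect on IL-2 under the T cell
superantigen stimulation (carried by both past and current smokers),
a smoking-driven methylation chain into IL-6, and CMV-driven memory
T cell chains into IFN-γ and TNF. Effect sizes read as multiplicative
changes in concentration:

```r
d <- b$cytokines %>%
  filter(stimulation == "SEB", cytokine == "IL2") %>%
  mutate(logc = log(concentration)) %>%
  inner_join(b$covariates, by = "donor")
effect_sizes(d, "logc", "smoking_status") %>%
  select(term, exp_estimate, conf_low, conf_high, p_value)
#>   term                  exp_estimate conf_low conf_high    p_value
#> 1 smoking_statuscurrent         1.55     1.30      1.85 0.00000105
#> 2 smoking_statuspast            1.37     1.15      1.64 0.000608
```

Current smokers secrete an estimated 1.55× the IL-2 of never-smokers
(the planted truth is 1.5), and past smokers remain elevated — the
persistent adaptive-response pattern the generator emulates. The
mediation screen then identifies which cell subsets explain the CMV
associations:

```r
em <- elimination_matrix(b$cytokines, b$covariates, b$cells, "cell",
                         "cmv_serostatus", "SEB", scr,
                         induced = ind, lloq = b$lloq)
tidy(em) %>% filter(eliminated) %>%
  select(mediator, cytokine, p_baseline_adjusted, p_with_mediator_adjusted)
#>   mediator cytokine p_baseline_adjusted p_with_mediator_adjusted
#> 1 CD4_TEM  TNF                0.00364                     1
#> 2 CD8_TEM  IFNg               0.0000210                   1
#> ...
```

The planted chains (CMV → CD8 effector-memory cells → IFN-γ and
CMV → CD4 effector-memory cells → TNF) are the top eliminations.
Finally, the LMG decomposition quantifies each variable's share of
the IL-2 response variance:

```r
variance_report(b$cytokines, b$covariates, "SEB",
                groups = list(age = "age", sex = "sex",
                              smoking = "smoking_status",
                              cmv = "cmv_serostatus", bmi = "bmi"),
                induced = ind, lloq = b$lloq) %>%
  filter(cytokine == "IL2") %>%
  mutate(pct = round(100 * share, 1)) %>%
  select(group, pct, total_r2)
#>   group     pct total_r2
#> 1 age       2.6   0.0664
#> 2 sex       0.6   0.0664
#> 3 smoking   3.1   0.0664
#> 4 cmv       0     0.0664
#> 5 bmi       0.4   0.0664
```

`run_pipeline(b, out_dir)` chains all stages (induction, responder
detection, screens, mediation, pQTL, variance) and writes one
provenance-headed TSV per result.

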