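test_that("identical config and seed give bit-identical bundles", {
  cfg <- small_config(n_donors = 120)
  b1 <- simulate_cohort(cfg, seed = 11)
  b2 <- simulate_cohort(cfg, seed = 11)
  for (tb in c("covariates", "cytokines", "cells", "proteins",
               "methylation", "genotypes")) {
    expect_identical(b1[[tb]], b2[[tb]])
  }
  b3 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(b1$cytokines, b3$cytokines))
})

test_that("smoking prevalence matches the configured multinomial", {
  cfg <- small_config(n_donors = 2000)
  b <- simulate_cohort(cfg, seed = 3)
  counts <- table(b$covariates$smoking_status)
  probs <- c(current = 0.25, never = 0.50, past = 0.25)
  for (lv in names(probs)) {
    expected <- 2000 * probs[[lv]]
    tol <- 3 * sqrt(2000 * probs[[lv]] * (1 - probs[[lv]]))
    expect_lt(abs(counts[[lv]] - expected), tol)
  }
  # sexes balanced, ages within declared range, stratified by decade
  expect_equal(sum(b$covariates$sex == "female"), 1000)
  expect_true(all(b$covariates$age >= 20 & b$covariates$age <= 69))
  decade_counts <- table(b$covariates$age %/% 10)
  expect_true(max(decade_counts) - min(decade_counts) <= 1)
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  specs <- tibble(id = c("s1", "s2"), chrom = c("1", "2"),
                  position = c(1e6, 2e6), maf = c(0.3, 0.2))
  g <- simulate_genotypes(10000, specs, seed = 5)
  d <- g$genotypes$s1
  expect_true(all(d %in% 0:2))
  freq <- tabulate(d + 1L, 3) / 10000
  hwe <- c(0.49, 0.42, 0.09)
  for (i in 1:3) {
    expect_lt(abs(freq[i] - hwe[i]), 3 * sqrt(hwe[i] * (1 - hwe[i]) / 10000))
  }
  # empirical allele frequency close to its target
  p_hat <- mean(g$genotypes$s2) / 2
  expect_lt(abs(p_hat - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))
  # symmetric maf: dosage mean near 1
  g5 <- simulate_genotypes(10000, tibble(id = "s", chrom = "1",
                                         position = 1, maf = 0.5), seed = 6)
  expect_lt(abs(mean(g5$genotypes$s) - 1), 0.05)
  expect_error(simulate_genotypes(100, tibble(id = "s", chrom = "1",
                                              position = 1, maf = 0.6),
                                  seed = 1),
               class = "cytovar_config_error")
})

test_that("methylation betas follow the dose/reversion model", {
  specs <- tibble(id = "cg1", chrom = "5", position = 373378,
                  baseline_beta = 0.85, packyear_effect = 0.05,
                  quit_reversion = 0.04, sd = 0)
  cov0 <- tibble(donor = c("a", "b", "c"),
                 smoking_status = c("never", "current", "current"),
                 pack_years = c(0, 10, 30),
                 years_since_quit = c(NA, NA, NA))
  m <- simulate_methylation(cov0, specs, seed = 1)
  betas <- m$methylation$cg1
  # zero-dose donor sits exactly at the logistic baseline
  expect_equal(betas[1], 0.85, tolerance = 1e-12)
  # heavier dose means strictly lower methylation
  expect_lt(betas[3], betas[2])
  expect_true(all(betas > 0 & betas < 1))

  # reversion after quitting: beta correlates positively with years
  # since quit among past smokers
  n <- 5000
  covp <- tibble(donor = sprintf("d%04d", 1:n),
                 smoking_status = "past",
                 pack_years = runif(n, 5, 40),
                 years_since_quit = runif(n, 0, 30))
  specs$sd <- 0.2
  mp <- simulate_methylation(covp, specs, seed = 2)
  expect_gt(cor(mp$methylation$cg1, covp$years_since_quit), 0)

  expect_error(simulate_methylation(tibble(donor = "a"), specs, seed = 1),
               class = "cytovar_data_error")
})

test_that("generated values respect their domains and the ledger is complete", {
  cfg <- small_config(n_donors = 150)
  b <- simulate_cohort(cfg, seed = 21)
  expect_true(all(b$cytokines$concentration > 0))
  meth <- as.matrix(b$methylation[, -1])
  expect_true(all(meth > 0 & meth < 1))
  geno <- as.matrix(b$genotypes[, -1])
  expect_true(all(geno %in% 0:2))
  # every planted effect is recorded exactly once and references real names
  tr <- b$truth
  expect_identical(nrow(tr$planted_associations), nrow(cfg$effect_ledger))
  expect_true(all(tr$planted_associations$variable %in% names(b$covariates)))
  expect_true(all(tr$planted_pqtls$id %in% names(b$genotypes)))
  expect_true(all(tr$planted_cpgs$id %in% names(b$methylation)))
  meds <- tr$planted_mediators
  panel_names <- c(names(b$cells), names(b$proteins), names(b$methylation))
  expect_true(all(meds$mediator %in% panel_names))
  expect_identical(anyDuplicated(tr$planted_associations), 0L)
})

test_that("a cohort with an empty effect ledger carries no planted signal", {
  cfg <- sim_config(n_donors = 400, stimulations = c("null", "LPS"),
                    effect_ledger = empty_effects(),
                    mediation_specs = empty_mediation(),
                    snp_specs = empty_snps(), cpg_specs = empty_cpgs(),
                    n_extra_numeric = 2, n_extra_categorical = 2,
                    n_extra_snps = 0, n_extra_cpgs = 0)
  b <- simulate_cohort(cfg, seed = 31)
  expect_identical(nrow(b$truth$planted_associations), 0L)
  scr <- screen_associations(b$cytokines, b$covariates, "LPS", lloq = b$lloq)
  expect_false(any(scr$results$significant))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(smoking_prevalence = c(never = 0.6, past = 0.3,
                                                 current = 0.3)),
               "smoking_prevalence")
  expect_error(sim_config(stimulations = c("a", "b"), null_condition = "x"),
               "null")
  expect_error(sim_config(snp_specs = tibble(
    id = "s", chrom = "1", position = 1, maf = 0.04,
    stimulation = "SEB", cytokine = "IL2", slope = 1
  )), "maf")
  cfg <- small_config()
  expect_error(simulate_cohort(cfg, seed = 1.5),
               class = "cytovar_config_error")
})
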