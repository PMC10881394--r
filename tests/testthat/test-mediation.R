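# one moderately sized cohort shared across the elimination tests
med_bundle <- simulate_cohort(small_config(n_donors = 450), seed = 42)
med_ind <- flag_induced(med_bundle$cytokines, lloq = med_bundle$lloq)
med_scr <- screen_associations(med_bundle$cytokines, med_bundle$covariates,
                               "SEB", induced = med_ind,
                               lloq = med_bundle$lloq)

test_that("a planted full-mediation chain is flagged eliminated", {
  em <- elimination_matrix(med_bundle$cytokines, med_bundle$covariates,
                           med_bundle$cells, "cell", "cmv_serostatus",
                           "SEB", med_scr, induced = med_ind)
  rec <- em$records
  # baseline CMV association exists and the planted mediator removes it
  planted <- rec %>% filter(mediator == "CD8_TEM", cytokine == "IFNg")
  expect_true(planted$p_baseline_adjusted < 0.01)
  expect_true(planted$eliminated)
  # a decoy subset unrelated to CMV does not eliminate the association
  decoy <- rec %>% filter(mediator == "neutrophils", cytokine == "IFNg")
  expect_false(decoy$eliminated)
  expect_true(decoy$p_with_mediator_adjusted < 0.01)
})

test_that("elimination is never reported without a significant baseline", {
  em <- elimination_matrix(med_bundle$cytokines, med_bundle$covariates,
                           med_bundle$cells, "cell", "cmv_serostatus",
                           "SEB", med_scr, induced = med_ind)
  rec <- em$records
  gate_violations <- rec %>%
    filter(eliminated, p_baseline_adjusted >= em$alpha)
  expect_identical(nrow(gate_violations), 0L)
  # and the flag definition holds record-wise
  expect_true(all(
    rec$eliminated ==
      (!rec$untestable & rec$p_baseline_adjusted < em$alpha &
         rec$p_with_mediator_adjusted >= em$alpha)
  ))
})

test_that("shuffling the mediator across donors abolishes elimination", {
  shuffled <- med_bundle$cells
  set.seed(77)
  shuffled$CD8_TEM <- sample(shuffled$CD8_TEM)
  em <- elimination_matrix(med_bundle$cytokines, med_bundle$covariates,
                           shuffled %>% select(donor, CD8_TEM), "cell",
                           "cmv_serostatus", "SEB", med_scr,
                           induced = med_ind)
  rec <- em$records %>% filter(mediator == "CD8_TEM", cytokine == "IFNg")
  expect_false(rec$eliminated)
})

test_that("a single-mediator panel forms a family of n_cytokines tests", {
  em <- elimination_matrix(med_bundle$cytokines, med_bundle$covariates,
                           med_bundle$cells %>% select(donor, CD8_TEM),
                           "cell", "cmv_serostatus", "SEB", med_scr,
                           induced = med_ind)
  n_ind <- sum(med_ind$induced[med_ind$stimulation == "SEB"])
  expect_identical(nrow(em$records), n_ind)
  expect_equal(em$records$p_with_mediator_adjusted,
               by_adjust_oracle(em$records$p_raw), tolerance = 1e-12)
})

test_that("permuting panel columns permutes records without changing p-values", {
  pan <- med_bundle$cells
  em1 <- elimination_matrix(med_bundle$cytokines, med_bundle$covariates,
                            pan, "cell", "cmv_serostatus", "SEB", med_scr,
                            induced = med_ind)
  pan2 <- pan[, c("donor", rev(setdiff(names(pan), "donor")))]
  em2 <- elimination_matrix(med_bundle$cytokines, med_bundle$covariates,
                            pan2, "cell", "cmv_serostatus", "SEB", med_scr,
                            induced = med_ind)
  j1 <- em1$records %>% arrange(mediator, cytokine)
  j2 <- em2$records %>% arrange(mediator, cytokine)
  expect_equal(j1$p_raw, j2$p_raw, tolerance = 1e-12)
})

test_that("a mediator collinear with the variable is flagged untestable", {
  d <- tibble(donor = sprintf("d%02d", 1:40),
              y = rnorm(40),
              grp = rep(c("a", "b"), 20)) %>%
    mutate(med = as.numeric(grp == "b"))
  out <- covariate_elimination(d, "y", "grp", "med",
                               covariates = character())
  expect_true(out$untestable)
})

test_that("CpG window tests use a closed 1 Mb same-chromosome interval", {
  n <- 150
  set.seed(20)
  donors <- sprintf("d%03d", 1:n)
  meth <- tibble(donor = donors,
                 cg_in = plogis(rnorm(n)), cg_edge = plogis(rnorm(n)),
                 cg_out = plogis(rnorm(n)), cg_otherchr = plogis(rnorm(n)),
                 cg_causal = plogis(rnorm(n)))
  pos <- tibble(
    id = c("cg_in", "cg_edge", "cg_out", "cg_otherchr", "cg_causal"),
    chrom = c("1", "1", "1", "2", "1"),
    position = c(49.5e6, 51e6, 51e6 + 1, 50e6, 50.2e6)
  )
  tsss <- tibble(gene = "cytA", chrom = "1", tss = 50e6)
  cov <- tibble(donor = donors, age = runif(n, 20, 70),
                sex = sample(c("f", "m"), n, TRUE),
                batch = sample(c("B1", "B2"), n, TRUE))
  cyt <- tibble(donor = donors, stimulation = "stim", cytokine = "cytA",
                concentration = exp(1 + 3 * meth$cg_causal + rnorm(n, 0, 0.3)))
  out <- cpg_window_assoc(meth, pos, cyt, tsss, cov, "stim")
  expect_setequal(out$cpg, c("cg_in", "cg_edge", "cg_causal"))
  # distance exactly at the window edge is included
  expect_true("cg_edge" %in% out$cpg)
  # the planted CpG is recovered at FDR < 0.05
  expect_true(out$significant[out$cpg == "cg_causal"])
  expect_equal(out$p_adjusted, p.adjust(out$p_raw, "fdr"), tolerance = 1e-12)
})

test_that("CpGs without coordinates are skipped with a warning count", {
  n <- 60
  donors <- sprintf("d%03d", 1:n)
  meth <- tibble(donor = donors, cg_a = plogis(rnorm(n)),
                 cg_nopos = plogis(rnorm(n)))
  pos <- tibble(id = "cg_a", chrom = "1", position = 50e6)
  tsss <- tibble(gene = "cytA", chrom = "1", tss = 50e6)
  cov <- tibble(donor = donors, age = runif(n, 20, 70),
                sex = sample(c("f", "m"), n, TRUE),
                batch = "B1")
  cyt <- tibble(donor = donors, stimulation = "stim", cytokine = "cytA",
                concentration = exp(rnorm(n)))
  expect_warning(
    out <- cpg_window_assoc(meth, pos, cyt, tsss, cov, "stim",
                            covariates = c("age", "sex")),
    "without coordinates"
  )
  expect_identical(attr(out, "n_skipped_no_position"), 1L)
})
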