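test_that("the MAF filter removes monomorphic and boundary SNPs", {
  g <- tibble(
    donor = sprintf("d%02d", 1:10),
    mono = rep(0, 10),                         # maf 0
    ok = c(rep(0, 8), 1, 1),                   # maf 0.10
    edge = c(rep(0, 9), 1)                     # maf 0.05, strict cut
  )
  out <- maf_filter(g)
  expect_setequal(setdiff(names(out$genotypes), "donor"), "ok")
  expect_identical(out$n_removed, 2L)
  expect_equal(out$maf$maf[out$maf$id == "ok"], 0.10)
})

test_that("cis/trans classification uses a closed 1 Mb window on the same chromosome", {
  tsss <- tibble(gene = "cytA", chrom = "7", tss = 5e7)
  expect_identical(classify_cis_trans("7", 5e7 + 1e6, "cytA", tsss), "cis")
  expect_identical(classify_cis_trans("7", 5e7 + 1e6 + 1, "cytA", tsss),
                   "trans")
  expect_identical(classify_cis_trans("8", 5e7, "cytA", tsss), "trans")
  expect_identical(classify_cis_trans("7", 5e7, "unknown_gene", tsss),
                   "unclassified")
})

make_scan_fixture <- function(n = 300, m = 50, k = 3, seed = 1,
                              slope = NULL) {
  set.seed(seed)
  donors <- sprintf("d%04d", seq_len(n))
  geno <- tibble(donor = donors)
  mafs <- runif(m, 0.1, 0.5)
  for (j in seq_len(m)) {
    geno[[sprintf("rs%03d", j)]] <- rbinom(n, 1, mafs[j]) +
      rbinom(n, 1, mafs[j])
  }
  snp_map <- tibble(id = sprintf("rs%03d", seq_len(m)),
                    chrom = as.character(1 + (seq_len(m) %% 3)),
                    position = 1e6 * seq_len(m))
  cov <- tibble(donor = donors, age = runif(n, 20, 70),
                sex = sample(c("f", "m"), n, TRUE),
                batch = sample(c("B1", "B2"), n, TRUE))
  cyts <- paste0("cyt", seq_len(k))
  cyt <- purrr::map_dfr(cyts, function(cy) {
    y <- 0.02 * cov$age + 0.3 * (cov$sex == "m") + rnorm(n)
    if (!is.null(slope)) y <- y + slope * geno$rs001
    bind_rows(
      tibble(donor = donors, stimulation = "stim", cytokine = cy,
             concentration = exp(y + 2)),
      tibble(donor = donors, stimulation = "null", cytokine = cy,
             concentration = exp(y))
    )
  })
  tsss <- tibble(gene = cyts, chrom = c("1", "2", "3")[seq_len(k)],
                 tss = 5e7)
  list(geno = geno, snp_map = snp_map, cov = cov, cyt = cyt, tss = tsss)
}

test_that("a noiseless additive phenotype yields the exact per-allele slope", {
  n <- 200
  donors <- sprintf("d%03d", seq_len(n))
  set.seed(2)
  dos <- rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)
  geno <- tibble(donor = donors, rsX = dos,
                 rsY = rbinom(n, 1, 0.4) + rbinom(n, 1, 0.4))
  cyt <- bind_rows(
    tibble(donor = donors, stimulation = "stim", cytokine = "cytA",
           concentration = exp(1 + 0.5 * dos)),
    tibble(donor = donors, stimulation = "null", cytokine = "cytA",
           concentration = exp(1))
  )
  cov <- tibble(donor = donors)
  snp_map <- tibble(id = c("rsX", "rsY"), chrom = "1",
                    position = c(1e6, 2e6))
  tsss <- tibble(gene = "cytA", chrom = "1", tss = 1.5e6)
  sc <- pqtl_scan(geno, snp_map, cyt, cov, "stim", tsss,
                  covariates = character(), keep_all = TRUE)
  hit <- sc$hits %>% filter(snp == "rsX")
  expect_equal(hit$slope, 0.5, tolerance = 1e-12)
  expect_lt(hit$p_raw, 1e-100)
  expect_true(hit$hit)
})

test_that("the matrix scan equals naive per-SNP least squares", {
  fx <- make_scan_fixture(n = 250, m = 40, k = 3, seed = 3)
  sc <- pqtl_scan(fx$geno, fx$snp_map, fx$cyt, fx$cov, "stim", fx$tss,
                  keep_all = TRUE)
  wide <- fx$cyt %>%
    filter(stimulation == "stim") %>%
    mutate(logc = log(concentration)) %>%
    select(donor, cytokine, logc) %>%
    tidyr::pivot_wider(names_from = cytokine, values_from = logc) %>%
    inner_join(fx$cov, by = "donor") %>%
    inner_join(fx$geno, by = "donor")
  for (idx in sample(nrow(sc$all), 25)) {
    row <- sc$all[idx, ]
    fml <- stats::reformulate(c(row$snp, "age", "sex", "batch"),
                              response = row$cytokine)
    cf <- summary(lm(fml, data = wide))$coefficients[row$snp, ]
    expect_equal(row$slope, unname(cf[1]), tolerance = 1e-10)
    expect_equal(row$t_statistic, unname(cf[3]), tolerance = 1e-10)
    expect_equal(row$p_raw, unname(cf[4]), tolerance = 1e-10)
  }
})

test_that("scan statistics respect phenotype shifts, scalings and allele flips", {
  fx <- make_scan_fixture(n = 250, m = 10, k = 1, seed = 4, slope = 0.3)
  sc1 <- pqtl_scan(fx$geno, fx$snp_map, fx$cyt, fx$cov, "stim", fx$tss,
                   keep_all = TRUE)
  # shift and scale the phenotype
  cyt2 <- fx$cyt %>% mutate(concentration = concentration^2 * exp(5))
  sc2 <- pqtl_scan(fx$geno, fx$snp_map, cyt2, fx$cov, "stim", fx$tss,
                   keep_all = TRUE)
  expect_equal(sc2$all$slope, 2 * sc1$all$slope, tolerance = 1e-9)
  expect_equal(sc2$all$t_statistic, sc1$all$t_statistic, tolerance = 1e-9)
  expect_equal(sc2$all$p_raw, sc1$all$p_raw, tolerance = 1e-9)
  # allele flip: dosage d -> 2 - d negates the slope, keeps |t| and p
  geno_f <- fx$geno
  for (s in setdiff(names(geno_f), "donor")) geno_f[[s]] <- 2 - geno_f[[s]]
  sc3 <- pqtl_scan(geno_f, fx$snp_map, fx$cyt, fx$cov, "stim", fx$tss,
                   keep_all = TRUE)
  expect_equal(sc3$all$slope, -sc1$all$slope, tolerance = 1e-10)
  expect_equal(abs(sc3$all$t_statistic), abs(sc1$all$t_statistic),
               tolerance = 1e-10)
  expect_equal(sc3$all$p_raw, sc1$all$p_raw, tolerance = 1e-10)
})

test_that("Bonferroni adjustment multiplies by the scan family size", {
  fx <- make_scan_fixture(n = 300, m = 30, k = 2, seed = 5, slope = 0.5)
  sc <- pqtl_scan(fx$geno, fx$snp_map, fx$cyt, fx$cov, "stim", fx$tss)
  expect_identical(sc$n_tests, 60L)
  expect_equal(sc$hits$p_adjusted,
               pmin(1, sc$hits$p_raw * sc$n_tests), tolerance = 1e-12)
  # labels partition the classified hits
  expect_true(all(sc$hits$cis_trans %in% c("cis", "trans")))
  expect_identical(anyDuplicated(sc$hits[, c("snp", "cytokine")]), 0L)
})

test_that("cytokines identical to the stimulus agonist are excluded", {
  fx <- make_scan_fixture(n = 120, m = 5, k = 2, seed = 6)
  cyt <- fx$cyt %>% mutate(stimulation = ifelse(stimulation == "stim",
                                                "cyt1", stimulation))
  sc <- pqtl_scan(fx$geno, fx$snp_map, cyt, fx$cov, "cyt1", fx$tss,
                  keep_all = TRUE)
  expect_false("cyt1" %in% sc$all$cytokine)
  expect_true("cyt2" %in% sc$all$cytokine)
})

test_that("conditioning on the tested SNP itself is untestable", {
  fx <- make_scan_fixture(n = 200, m = 3, k = 1, seed = 7, slope = 0.5)
  fx$geno$rs_copy <- fx$geno$rs001
  fx$snp_map <- bind_rows(fx$snp_map,
                          tibble(id = "rs_copy", chrom = "1",
                                 position = 1.1e6))
  expect_warning(
    sc <- conditional_scan(fx$geno, fx$snp_map, fx$cyt, fx$cov, "stim",
                           fx$tss, conditioning_snp = "rs001",
                           keep_all = TRUE),
    "untestable"
  )
  expect_true(sc$all$untestable[sc$all$snp == "rs_copy"])
  expect_error(
    conditional_scan(fx$geno, fx$snp_map, fx$cyt, fx$cov, "stim", fx$tss,
                     conditioning_snp = "absent_snp"),
    class = "cytovar_config_error"
  )
})

test_that("conditioning on an independent SNP barely moves the association", {
  fx <- make_scan_fixture(n = 500, m = 10, k = 1, seed = 8, slope = 0.4)
  sc0 <- pqtl_scan(fx$geno, fx$snp_map, fx$cyt, fx$cov, "stim", fx$tss,
                   keep_all = TRUE)
  sc1 <- conditional_scan(fx$geno, fx$snp_map, fx$cyt, fx$cov, "stim",
                          fx$tss, conditioning_snp = "rs010",
                          keep_all = TRUE)
  p0 <- sc0$all$p_raw[sc0$all$snp == "rs001"]
  p1 <- sc1$all$p_raw[sc1$all$snp == "rs001"]
  expect_lt(abs(log10(p0) - log10(p1)), 0.5)
})

test_that("genotype-by-smoking interactions are recovered and null when absent", {
  set.seed(9)
  n <- 600
  donors <- sprintf("d%04d", seq_len(n))
  dos <- rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)
  smoking <- sample(c("never", "past", "current"), n, TRUE,
                    prob = c(0.5, 0.25, 0.25))
  cov <- tibble(donor = donors, age = runif(n, 20, 70),
                sex = sample(c("f", "m"), n, TRUE), batch = "B1",
                smoking_status = smoking)
  geno <- tibble(donor = donors, rsA = dos)
  # effect only in current smokers
  y <- 0.5 * dos * (smoking == "current") + rnorm(n, 0, 0.8)
  cyt <- bind_rows(
    tibble(donor = donors, stimulation = "stim", cytokine = "cytA",
           concentration = exp(y + 2)),
    tibble(donor = donors, stimulation = "null", cytokine = "cytA",
           concentration = exp(rnorm(n)))
  )
  hits <- tibble(snp = "rsA", cytokine = "cytA")
  gx <- gxe_interaction(hits, geno, cyt, cov, "stim",
                        covariates = c("age", "sex"))
  expect_lt(gx$tests$p_adjusted, 0.01)
  int_cur <- gx$coefficients %>%
    filter(grepl("current", term))
  expect_true(int_cur$conf_low < exp(0.5) & exp(0.5) < int_cur$conf_high)

  # exactly uniform effect across strata, noiseless: interaction is zero
  y0 <- 0.4 * dos
  cyt0 <- cyt %>%
    mutate(concentration = ifelse(stimulation == "stim", exp(y0 + 2),
                                  concentration))
  gx0 <- gxe_interaction(hits, geno, cyt0, cov, "stim",
                         covariates = c("age", "sex"))
  expect_equal(max(abs(log(gx0$coefficients$exp_estimate))), 0,
               tolerance = 1e-10)
})
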