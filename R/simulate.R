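# Synthetic cohort generator with a ground-truth ledger of planted effects.

#' Simulate a synthetic cohort bundle
#'
#' Generates every per-donor table the analysis pipeline consumes —
#' donor covariates, stimulated and control cytokine concentrations,
#' immune-cell counts, plasma proteins, CpG methylation and genotype
#' dosages — together with a `truth_ledger` recording each planted
#' effect, so that downstream screens can be validated by parameter
#' recovery.
#'
#' Cytokine concentrations are log-normal: the log concentration is the
#' sum of a per-cytokine baseline, age/sex/batch nuisance terms, the
#' stimulation's induction shift, planted direct effects, mediator-path
#' effects (`b` times the centred observed mediator), per-allele
#' genotype effects, and Gaussian noise with standard deviation
#' `config$noise_sd`. Null-condition concentrations carry only the
#' nuisance terms and noise. Donors drawn as non-responders for the
#' designated responder stimulation receive null-level responses there
#' (all stimulation and planted effects switched off).
#'
#' Randomness is fully seeded: one global `seed` drives a fixed,
#' documented per-table offset sequence (covariates, cells, proteins,
#' methylation, genotypes, cytokines, responders), so regenerating one
#' table never perturbs the others.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `"cohort_bundle"` with elements
#'   `covariates`, `cytokines` (long tibble: donor, stimulation,
#'   cytokine, concentration), `lloq`, `cells`, `proteins`,
#'   `methylation`, `cpg_positions`, `genotypes`, `snp_map`, `tss` and
#'   `truth` (class `"truth_ledger"`).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) {
    abort_config("`config` must be built with sim_config().", "config")
  }
  check_scalar(seed, "seed", int = TRUE)

  cov <- simulate_covariates(config, table_seed(seed, "covariates"))

  # responder labels for the designated mixture stimulation
  set.seed(table_seed(seed, "responders"))
  responder <- if (is.na(config$responder_stimulation)) {
    rep(TRUE, config$n_donors)
  } else {
    runif(config$n_donors) >= config$responder_split
  }
  responder_labels <- tibble(
    donor = cov$donor,
    stimulation = config$responder_stimulation,
    responder = responder
  )

  cells <- simulate_cells(config, cov, table_seed(seed, "cells"))
  proteins <- simulate_proteins(config, cov, table_seed(seed, "proteins"))
  meth <- simulate_methylation(cov,
                               cpg_specs = config$cpg_specs,
                               seed = table_seed(seed, "methylation"),
                               n_extra = config$n_extra_cpgs)
  geno <- simulate_genotypes(config$n_donors,
                             snp_specs = config$snp_specs,
                             seed = table_seed(seed, "genotypes"),
                             n_extra = config$n_extra_snps,
                             donors = cov$donor)

  cyt <- simulate_cytokines(config, cov, cells, proteins, meth$methylation,
                            geno$genotypes, responder,
                            table_seed(seed, "cytokines"))

  truth <- structure(
    list(
      planted_associations = config$effect_ledger,
      planted_mediators = config$mediation_specs %>%
        select("variable", "mediator", "kind", "stimulation", "cytokine"),
      planted_pqtls = config$snp_specs %>%
        mutate(cis_trans = purrr::pmap_chr(
          list(.data$chrom, .data$position, .data$cytokine),
          function(ch, po, cy) classify_cis_trans(ch, po, cy, config$tss)
        )),
      planted_cpgs = config$cpg_specs,
      responder_labels = responder_labels
    ),
    class = "truth_ledger"
  )

  lloq <- tidyr::expand_grid(stimulation = config$stimulations,
                             cytokine = config$cytokines) %>%
    mutate(lloq = config$lloq)

  structure(
    list(
      covariates = cov, cytokines = cyt, lloq = lloq,
      cells = cells, proteins = proteins,
      methylation = meth$methylation, cpg_positions = meth$cpg_positions,
      genotypes = geno$genotypes, snp_map = geno$snp_map,
      tss = config$tss, truth = truth,
      null_condition = config$null_condition,
      responder_stimulation = config$responder_stimulation,
      seed = as.integer(seed)
    ),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  %d donors, %d stimulations x %d cytokines\n",
              nrow(x$covariates),
              dplyr::n_distinct(x$cytokines$stimulation),
              dplyr::n_distinct(x$cytokines$cytokine)))
  cat(sprintf("  panels: %d cell subsets, %d proteins, %d CpGs, %d SNPs\n",
              ncol(x$cells) - 1L, ncol(x$proteins) - 1L,
              ncol(x$methylation) - 1L, ncol(x$genotypes) - 1L))
  invisible(x)
}

# Donor covariates: stratified ages, balanced sex, smoking history with
# dose variables, CMV serostatus, BMI, and null decoy variables.
simulate_covariates <- function(config, seed) {
  set.seed(seed)
  n <- config$n_donors
  donor <- sprintf("D%04d", seq_len(n))

  # equal decade strata spanning the age range; remainder spread from the
  # youngest stratum up
  lo <- config$age_range[1]; hi <- config$age_range[2]
  starts <- seq(lo, hi, by = 10)
  k <- length(starts)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  age <- unlist(purrr::map2(starts, sizes, function(s, m) {
    s + floor(runif(m) * min(10, hi - s + 1))
  }))
  age <- as.integer(sample(age))  # shuffle stratum order

  n_f <- round(n * config$sex_balance)
  sex <- sample(c(rep("female", n_f), rep("male", n - n_f)))
  batch <- sample(paste0("B", seq_len(config$batch_levels)),
                  n, replace = TRUE)

  smoking_status <- sample(names(config$smoking_prevalence), n,
                           replace = TRUE,
                           prob = config$smoking_prevalence)
  ever <- smoking_status != "never"
  years_smoking <- numeric(n)
  years_since_quit <- rep(NA_real_, n)
  cigs_day <- numeric(n)
  max_hist <- pmax(age - 18, 2)
  years_smoking[ever] <- round(runif(sum(ever), 1, max_hist[ever]), 1)
  past <- smoking_status == "past"
  years_since_quit[past] <-
    round(runif(sum(past), 0.5,
                pmax(max_hist[past] - years_smoking[past], 1)), 1)
  cigs_day[ever] <- sample(3:30, sum(ever), replace = TRUE)
  pack_years <- cigs_day / 20 * years_smoking
  total_cigarettes <- round(cigs_day * 365.25 * years_smoking)

  cov <- tibble(
    donor = donor, age = age, sex = sex, batch = batch,
    smoking_status = smoking_status,
    years_smoking = years_smoking,
    years_since_quit = years_since_quit,
    total_cigarettes = total_cigarettes,
    pack_years = pack_years,
    cmv_serostatus = runif(n) < config$cmv_seroprevalence,
    bmi = round(rnorm(n, config$bmi_mean, config$bmi_sd), 1)
  )

  if (config$n_extra_numeric > 0) {
    for (i in seq_len(config$n_extra_numeric)) {
      cov[[sprintf("ecrf_num_%02d", i)]] <- round(rnorm(n), 3)
    }
  }
  if (config$n_extra_categorical > 0) {
    for (i in seq_len(config$n_extra_categorical)) {
      L <- sample(2:4, 1)
      shares <- rgamma(L, 4); shares <- shares / sum(shares)
      cov[[sprintf("ecrf_cat_%02d", i)]] <-
        sample(LETTERS[seq_len(L)], n, replace = TRUE, prob = shares)
    }
  }
  cov
}

# Indicator/numeric signal carried by a planted variable (optionally one
# categorical level).
variable_signal <- function(cov, variable, level = NA) {
  x <- cov[[variable]]
  if (is.null(x)) {
    abort_config(sprintf("planted variable `%s` not in covariates.", variable),
                 "effect_ledger")
  }
  if (!is.na(level)) as.numeric(x == level) else as.numeric(x)
}

simulate_cells <- function(config, cov, seed) {
  set.seed(seed)
  n <- nrow(cov)
  chains <- config$mediation_specs %>% filter(.data$kind == "cell")
  out <- tibble(donor = cov$donor)
  for (subset in config$cell_subsets) {
    base <- runif(1, 5.2, 6.8)
    lg <- base + rnorm(n, 0, 0.4)
    hit <- chains[chains$mediator == subset, ]
    for (j in seq_len(nrow(hit))) {
      lg <- lg + hit$a[j] * variable_signal(cov, hit$variable[j], hit$level[j])
    }
    out[[subset]] <- pmax(round(exp(lg)), 0)
  }
  out
}

simulate_proteins <- function(config, cov, seed) {
  set.seed(seed)
  n <- nrow(cov)
  chains <- config$mediation_specs %>% filter(.data$kind == "protein")
  out <- tibble(donor = cov$donor)
  for (prot in config$protein_names) {
    base <- runif(1, 2, 4)
    lg <- base + rnorm(n, 0, 0.5)
    hit <- chains[chains$mediator == prot, ]
    for (j in seq_len(nrow(hit))) {
      lg <- lg + hit$a[j] * variable_signal(cov, hit$variable[j], hit$level[j])
    }
    out[[prot]] <- exp(lg)
  }
  out
}

#' Simulate smoking-responsive CpG methylation
#'
#' Beta values are generated on the logit scale as
#' `logit(baseline) - packyear_effect * pack_years +
#' quit_reversion * years_since_quit` (the reversion applies to past
#' smokers only) plus Gaussian noise, then mapped back through the
#' logistic function, so betas stay in (0, 1) and are monotone
#' decreasing in smoking dose at fixed history. This reproduces the
#' hypomethylation-with-dose / reversion-after-cessation pattern of
#' smoking-sensitive CpG sites.
#'
#' @param covariates Tibble with `smoking_status`, `pack_years` and
#'   `years_since_quit` columns (and a `donor` id).
#' @param cpg_specs Tibble (id, chrom, position, baseline_beta,
#'   packyear_effect, quit_reversion, sd).
#' @param seed Integer seed.
#' @param n_extra Number of additional smoking-independent CpG sites.
#' @return List with `methylation` (donor x CpG tibble of betas) and
#'   `cpg_positions` (id, chrom, position).
#' @export
simulate_methylation <- function(covariates, cpg_specs, seed, n_extra = 0) {
  need <- c("smoking_status", "pack_years", "years_since_quit")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols)) {
    abort_data(sprintf("covariates lack smoking field(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  check_scalar(seed, "seed", int = TRUE)
  set.seed(seed)
  n <- nrow(covariates)
  past <- covariates$smoking_status == "past"
  ysq <- ifelse(past & !is.na(covariates$years_since_quit),
                covariates$years_since_quit, 0)

  out <- tibble(donor = covariates$donor)
  pos <- tibble(id = character(), chrom = character(), position = numeric())
  for (j in seq_len(nrow(cpg_specs))) {
    sp <- cpg_specs[j, ]
    lg <- qlogis(sp$baseline_beta) -
      sp$packyear_effect * covariates$pack_years +
      sp$quit_reversion * ysq +
      rnorm(n, 0, sp$sd)
    out[[sp$id]] <- plogis(lg)
    pos <- bind_rows(pos, tibble(id = sp$id, chrom = as.character(sp$chrom),
                                 position = sp$position))
  }
  if (n_extra > 0) {
    for (j in seq_len(n_extra)) {
      id <- sprintf("cg_null_%03d", j)
      out[[id]] <- plogis(qlogis(runif(1, 0.2, 0.8)) + rnorm(n, 0, 0.3))
      pos <- bind_rows(pos, tibble(
        id = id, chrom = as.character(sample(1:22, 1)),
        position = round(runif(1, 1e6, 2e8))
      ))
    }
  }
  list(methylation = out, cpg_positions = pos)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each SNP's dosage is the sum of two independent Bernoulli allele
#' draws at its minor allele frequency, giving Hardy-Weinberg genotype
#' proportions ((1-p)^2, 2p(1-p), p^2) for dosages (0, 1, 2).
#'
#' @param n_donors Number of donors (>= 2).
#' @param snp_specs Tibble with at least `id`, `chrom`, `position`,
#'   `maf`; each maf must lie in (0, 0.5].
#' @param seed Integer seed.
#' @param n_extra Number of additional null SNPs with random positions
#'   and maf drawn uniformly in (0.1, 0.5).
#' @param donors Optional donor ids (defaults to `D0001`...).
#' @return List with `genotypes` (donor x SNP tibble of dosages) and
#'   `snp_map` (id, chrom, position, maf).
#' @export
simulate_genotypes <- function(n_donors, snp_specs, seed, n_extra = 0,
                               donors = NULL) {
  check_scalar(n_donors, "n_donors", lo = 2, int = TRUE)
  check_scalar(seed, "seed", int = TRUE)
  snp_specs <- as_tibble(snp_specs)
  if (nrow(snp_specs) && any(snp_specs$maf <= 0 | snp_specs$maf > 0.5)) {
    abort_config("every `maf` must lie in (0, 0.5].", "snp_specs")
  }
  set.seed(seed)
  if (is.null(donors)) donors <- sprintf("D%04d", seq_len(n_donors))

  map <- snp_specs %>%
    select("id", "chrom", "position", "maf") %>%
    mutate(chrom = as.character(.data$chrom))
  if (n_extra > 0) {
    map <- bind_rows(map, tibble(
      id = sprintf("rs_null_%03d", seq_len(n_extra)),
      chrom = as.character(sample(1:22, n_extra, replace = TRUE)),
      position = round(runif(n_extra, 1e6, 2e8)),
      maf = runif(n_extra, 0.1, 0.5)
    ))
  }

  geno <- tibble(donor = donors)
  for (j in seq_len(nrow(map))) {
    p <- map$maf[j]
    geno[[map$id[j]]] <- rbinom(n_donors, 1, p) + rbinom(n_donors, 1, p)
  }
  list(genotypes = geno, snp_map = map)
}

# Cytokine concentrations on the log scale; see simulate_cohort() docs.
simulate_cytokines <- function(config, cov, cells, proteins, methylation,
                               genotypes, responder, seed) {
  set.seed(seed)
  n <- nrow(cov)
  age_c <- cov$age - mean(cov$age)
  male <- as.numeric(cov$sex == "male")
  batch_idx <- as.numeric(factor(cov$batch)) - 1

  baselines <- setNames(runif(length(config$cytokines), 1.5, 3.0),
                        config$cytokines)

  # observed-scale mediator values (exactly what the analysis models use),
  # centred, so conditioning on the mediator removes the variable's path
  mediator_obs <- function(mediator, kind) {
    m <- switch(kind,
      cell = log(cells[[mediator]] + 0.5),
      protein = log(proteins[[mediator]]),
      cpg = methylation[[mediator]]
    )
    m - mean(m)
  }

  rows <- vector("list",
                 length(config$stimulations) * length(config$cytokines))
  k <- 0L
  for (s in config$stimulations) {
    is_null <- s == config$null_condition
    resp <- if (!is.na(config$responder_stimulation) &&
                s == config$responder_stimulation) as.numeric(responder)
            else rep(1, n)
    for (cy in config$cytokines) {
      lin <- baselines[[cy]] + config$age_coef * age_c +
        config$sex_coef * male + config$batch_coef * batch_idx
      if (!is_null) {
        fold <- config$stim_effects$log_fold[
          config$stim_effects$stimulation == s &
            config$stim_effects$cytokine == cy]
        if (length(fold)) lin <- lin + fold[1] * resp

        led <- config$effect_ledger[
          config$effect_ledger$stimulation == s &
            config$effect_ledger$cytokine == cy, ]
        for (j in seq_len(nrow(led))) {
          lin <- lin + led$coefficient[j] * resp *
            variable_signal(cov, led$variable[j], led$level[j])
        }

        med <- config$mediation_specs[
          config$mediation_specs$stimulation == s &
            config$mediation_specs$cytokine == cy, ]
        for (j in seq_len(nrow(med))) {
          lin <- lin + med$b[j] * resp * mediator_obs(med$mediator[j],
                                                      med$kind[j])
          if (!is.na(med$direct[j]) && med$direct[j] != 0) {
            lin <- lin + med$direct[j] * resp *
              variable_signal(cov, med$variable[j], med$level[j])
          }
        }

        snp <- config$snp_specs[
          config$snp_specs$stimulation == s &
            config$snp_specs$cytokine == cy, ]
        for (j in seq_len(nrow(snp))) {
          lin <- lin + snp$slope[j] * resp * genotypes[[snp$id[j]]]
        }
      }
      k <- k + 1L
      rows[[k]] <- tibble(
        donor = cov$donor, stimulation = s, cytokine = cy,
        concentration = exp(lin + rnorm(n, 0, config$noise_sd))
      )
    }
  }
  bind_rows(rows)
}
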