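#' Simulation configuration for synthetic cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()]. The defaults describe a cohort of 1,000 healthy
#' donors balanced by sex within each decade of age from 20 to 69, two
#' technical batches of stimulation tubes, a never/past/current smoking
#' split, latent CMV infection in roughly a third of donors, and
#' log-normal cytokine responses to a panel of whole-blood stimulations
#' that includes one non-stimulated ("null") control condition.
#'
#' Planted structure is described by four tables, all of which end up in
#' the ground-truth ledger of the generated bundle:
#'
#' * `effect_ledger` — direct donor-variable effects on the log
#'   concentration of one cytokine in one stimulation. For categorical
#'   variables the `level` column names the level carrying the effect
#'   (e.g. a persistent smoking effect is planted on both `"past"` and
#'   `"current"`).
#' * `mediation_specs` — full-mediation chains variable -> mediator ->
#'   cytokine. For `cell` and `protein` mediators the chain creates the
#'   mediator column (`a` is the variable-to-mediator path on the
#'   mediator's log scale); for `cpg` mediators the site must be one of
#'   `cpg_specs`, whose smoking dependence provides the first path. The
#'   cytokine receives `b` times the centred observed mediator, so
#'   conditioning on the mediator removes the variable's association
#'   entirely unless a nonzero `direct` path is requested.
#' * `snp_specs` — additive per-allele effects of Hardy-Weinberg
#'   genotypes on one (stimulation, cytokine) response.
#' * `cpg_specs` — smoking-responsive CpG sites: beta values are
#'   generated on the logit scale as baseline minus a per-pack-year
#'   dose effect, with a per-year reversion toward baseline after
#'   quitting (past smokers only).
#'
#' @param n_donors Number of donors.
#' @param seed Default seed stored with the configuration (each
#'   generator still takes an explicit seed argument).
#' @param age_range Two integers, inclusive age bounds; donors are drawn
#'   uniformly within equally sized decade strata.
#' @param sex_balance Proportion of female donors within each decade.
#' @param batch_levels Number of technical batch levels.
#' @param smoking_prevalence Named proportions for never/past/current;
#'   must sum to 1.
#' @param cmv_seroprevalence Probability of CMV seropositivity.
#' @param bmi_mean,bmi_sd Body-mass-index distribution (kg/m^2).
#' @param stimulations Character vector of stimulation names, including
#'   the null condition.
#' @param null_condition Name of the non-stimulated control condition.
#' @param cytokines Character vector of analyte names.
#' @param stim_effects Tibble (stimulation, cytokine, log_fold) of
#'   stimulation-induced log-scale shifts over the null condition. The
#'   default induces every cytokine except the last two in each
#'   stimulation, so each screen family contains non-induced analytes.
#' @param effect_ledger,mediation_specs,snp_specs,cpg_specs Planted
#'   structure; see Details. Empty tibbles are allowed.
#' @param age_coef,sex_coef,batch_coef Log-scale nuisance effects per
#'   year of age (centred), for male vs female, and per batch step.
#' @param noise_sd Log-scale residual standard deviation of cytokine
#'   concentrations.
#' @param responder_stimulation Stimulation with a responder /
#'   non-responder mixture (a T cell receptor cross-linking condition in
#'   the motivating design).
#' @param responder_split Proportion of non-responders for that
#'   stimulation; non-responders receive null-condition-level responses.
#' @param cell_subsets,protein_names Mediator panel column names; chain
#'   mediators are added automatically when missing.
#' @param n_extra_numeric,n_extra_categorical Numbers of null eCRF-style
#'   decoy variables (no planted effect).
#' @param n_extra_snps,n_extra_cpgs Numbers of null SNPs / CpG sites.
#' @param tss Tibble (gene, chrom, tss) of cytokine gene transcription
#'   start sites used for cis/trans classification and CpG windows; the
#'   default places each cytokine gene on its own chromosome.
#' @param lloq Lower limit of quantification applied to every analyte
#'   (concentration units).
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_donors = 1000,
                       seed = 1L,
                       age_range = c(20, 69),
                       sex_balance = 0.5,
                       batch_levels = 2,
                       smoking_prevalence = c(never = 0.50, past = 0.25,
                                              current = 0.25),
                       cmv_seroprevalence = 0.35,
                       bmi_mean = 24.5,
                       bmi_sd = 3.5,
                       stimulations = c("null", "LPS", "E. coli", "SEB",
                                        "aCD3CD28"),
                       null_condition = "null",
                       cytokines = c("CXCL5", "CSF2", "IFNg", "IL1b", "TNF",
                                     "IL2", "IL6", "IL8", "IL10", "IL12p70",
                                     "IL13", "IL17", "IL23"),
                       stim_effects = NULL,
                       effect_ledger = NULL,
                       mediation_specs = NULL,
                       snp_specs = NULL,
                       cpg_specs = NULL,
                       age_coef = 0.008,
                       sex_coef = 0.2,
                       batch_coef = 0.1,
                       noise_sd = 1.0,
                       responder_stimulation = NULL,
                       responder_split = 0.295,
                       cell_subsets = c("monocytes", "neutrophils", "B_naive",
                                        "B_memory", "CD4_naive", "CD4_TEM",
                                        "CD8_TEM", "Treg", "NK"),
                       protein_names = c("CEACAM6", paste0("prot_", sprintf("%02d", 2:6))),
                       n_extra_numeric = 6,
                       n_extra_categorical = 6,
                       n_extra_snps = 40,
                       n_extra_cpgs = 20,
                       tss = NULL,
                       lloq = 0.05) {
  check_scalar(n_donors, "n_donors", lo = 2, int = TRUE)
  check_scalar(seed, "seed", int = TRUE)
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort_config("`age_range` must be two increasing ages.", "age_range")
  }
  check_scalar(sex_balance, "sex_balance", 0, 1)
  check_scalar(batch_levels, "batch_levels", lo = 1, int = TRUE)
  check_proportions(smoking_prevalence, "smoking_prevalence")
  if (!identical(sort(names(smoking_prevalence)),
                 sort(c("never", "past", "current")))) {
    abort_config(
      "`smoking_prevalence` must be named never/past/current.",
      "smoking_prevalence"
    )
  }
  check_scalar(cmv_seroprevalence, "cmv_seroprevalence", 0, 1)
  check_scalar(noise_sd, "noise_sd", lo = 0)
  check_scalar(responder_split, "responder_split", 0, 1)
  check_scalar(lloq, "lloq", lo = 0)

  if (sum(stimulations == null_condition) != 1) {
    abort_config(
      "exactly one stimulation must be the designated null condition.",
      "null_condition"
    )
  }
  if (anyDuplicated(stimulations) || anyDuplicated(cytokines)) {
    abort_config("stimulation and cytokine names must be unique.",
                 "stimulations")
  }
  if (is.null(responder_stimulation)) {
    # by default the T cell receptor cross-linking condition, when present
    responder_stimulation <- if ("aCD3CD28" %in% stimulations) "aCD3CD28"
                             else NA_character_
  }
  if (!is.na(responder_stimulation) &&
      !responder_stimulation %in% stimulations) {
    abort_config("`responder_stimulation` must be one of `stimulations`.",
                 "responder_stimulation")
  }

  if (is.null(tss)) {
    tss <- tibble(
      gene  = cytokines,
      chrom = as.character(seq_along(cytokines)),
      tss   = 6e7 + 1e6 * seq_along(cytokines)
    )
  }

  if (is.null(stim_effects)) {
    active <- setdiff(stimulations, null_condition)
    induced <- cytokines[seq_len(max(0, length(cytokines) - 2))]
    stim_effects <- tidyr::expand_grid(stimulation = active,
                                       cytokine = induced) %>%
      mutate(log_fold = 2.0)
  }

  # default planted tables are trimmed to the configured stimulation and
  # cytokine sets; user-supplied tables are validated strictly below
  trim_default <- function(tbl) {
    tbl %>% filter(.data$stimulation %in% stimulations,
                   .data$cytokine %in% cytokines)
  }
  effect_default <- is.null(effect_ledger)
  mediation_default <- is.null(mediation_specs)
  snp_default <- is.null(snp_specs)
  if (is.null(effect_ledger)) {
    effect_ledger <- tibble(
      variable    = c("smoking_status", "smoking_status",
                      "smoking_status", "smoking_status", "bmi"),
      level       = c("current", "past", "current", "past", NA),
      stimulation = c("SEB", "SEB", "aCD3CD28", "aCD3CD28", "SEB"),
      cytokine    = c("IL2", "IL2", "IL13", "IL13", "IL2"),
      coefficient = c(log(1.5), log(1.5), log(1.4), log(1.4), 0.02)
    )
  }
  effect_ledger <- as_tibble(effect_ledger)
  if (effect_default) effect_ledger <- trim_default(effect_ledger)

  if (is.null(cpg_specs)) {
    cpg_specs <- tibble(
      id              = c("cg_AHRR_01", "cg_AHRR_02", "cg_F2RL3_01",
                          "cg_GPR15_01", "cg_PRSS23_01"),
      chrom           = c("5", "5", "19", "3", "11"),
      position        = c(373378, 399360, 17000585, 98251294, 86510915),
      baseline_beta   = c(0.85, 0.80, 0.75, 0.80, 0.70),
      packyear_effect = c(0.06, 0.05, 0.05, 0.04, 0.04),
      quit_reversion  = c(0.05, 0.04, 0.04, 0.03, 0.03),
      sd              = 0.25
    )
  }
  cpg_specs <- as_tibble(cpg_specs)
  if (nrow(cpg_specs) &&
      any(cpg_specs$baseline_beta <= 0 | cpg_specs$baseline_beta >= 1)) {
    abort_config("every `baseline_beta` must lie in (0, 1).", "cpg_specs")
  }

  if (is.null(mediation_specs)) {
    mediation_specs <- tibble(
      variable    = c("cmv_serostatus", "cmv_serostatus",
                      "smoking_status", "smoking_status"),
      level       = c(NA, NA, "current", "current"),
      mediator    = c("CD8_TEM", "CD4_TEM", "CEACAM6", "cg_AHRR_01"),
      kind        = c("cell", "cell", "protein", "cpg"),
      stimulation = c("SEB", "SEB", "LPS", "SEB"),
      cytokine    = c("IFNg", "TNF", "CXCL5", "IL6"),
      a           = c(0.8, 0.7, 0.5, NA),
      b           = c(0.6, 0.5, 0.8, -3.0),
      direct      = 0
    )
  }
  mediation_specs <- as_tibble(mediation_specs)
  if (mediation_default) mediation_specs <- trim_default(mediation_specs)
  if (nrow(mediation_specs)) {
    bad <- setdiff(mediation_specs$kind, c("cell", "protein", "cpg"))
    if (length(bad)) {
      abort_config("`mediation_specs$kind` must be cell/protein/cpg.",
                   "mediation_specs")
    }
    cpg_chain <- mediation_specs$mediator[mediation_specs$kind == "cpg"]
    if (!all(cpg_chain %in% cpg_specs$id)) {
      abort_config(
        "cpg-kind mediators must reference a site in `cpg_specs`.",
        "mediation_specs"
      )
    }
  }

  if (is.null(snp_specs)) {
    cxcl5 <- tss[tss$gene == "CXCL5", ]
    snp_specs <- tibble(
      id          = c("rs_cis_CXCL5", "rs_trans_IL2"),
      chrom       = c(cxcl5$chrom[1] %||% "1", "20"),
      position    = c((cxcl5$tss[1] %||% 6e7) + 5e4, 33e6),
      maf         = c(0.30, 0.25),
      stimulation = c("LPS", "SEB"),
      cytokine    = c("CXCL5", "IL2"),
      slope       = c(0.40, 0.30)
    )
  }
  snp_specs <- as_tibble(snp_specs)
  if (snp_default) snp_specs <- trim_default(snp_specs)
  if (nrow(snp_specs) && any(snp_specs$maf <= 0.05 | snp_specs$maf > 0.5)) {
    abort_config("every planted `maf` must lie in (0.05, 0.5].", "snp_specs")
  }

  bad_stim <- setdiff(
    c(effect_ledger$stimulation, mediation_specs$stimulation,
      snp_specs$stimulation),
    stimulations
  )
  if (length(bad_stim)) {
    abort_config(
      sprintf("planted effects reference unknown stimulation(s): %s",
              paste(bad_stim, collapse = ", ")),
      "effect_ledger"
    )
  }
  bad_cyt <- setdiff(
    c(effect_ledger$cytokine, mediation_specs$cytokine, snp_specs$cytokine),
    cytokines
  )
  if (length(bad_cyt)) {
    abort_config(
      sprintf("planted effects reference unknown cytokine(s): %s",
              paste(bad_cyt, collapse = ", ")),
      "effect_ledger"
    )
  }

  # chain mediators materialise as panel columns
  cell_subsets <- union(cell_subsets,
                        mediation_specs$mediator[mediation_specs$kind == "cell"])
  protein_names <- union(protein_names,
                         mediation_specs$mediator[mediation_specs$kind == "protein"])

  structure(
    list(
      n_donors = as.integer(n_donors), seed = as.integer(seed),
      age_range = as.integer(age_range), sex_balance = sex_balance,
      batch_levels = as.integer(batch_levels),
      smoking_prevalence = smoking_prevalence[c("never", "past", "current")],
      cmv_seroprevalence = cmv_seroprevalence,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd,
      stimulations = stimulations, null_condition = null_condition,
      cytokines = cytokines, stim_effects = as_tibble(stim_effects),
      effect_ledger = effect_ledger, mediation_specs = mediation_specs,
      snp_specs = snp_specs, cpg_specs = cpg_specs,
      age_coef = age_coef, sex_coef = sex_coef, batch_coef = batch_coef,
      noise_sd = noise_sd,
      responder_stimulation = responder_stimulation,
      responder_split = responder_split,
      cell_subsets = cell_subsets, protein_names = protein_names,
      n_extra_numeric = as.integer(n_extra_numeric),
      n_extra_categorical = as.integer(n_extra_categorical),
      n_extra_snps = as.integer(n_extra_snps),
      n_extra_cpgs = as.integer(n_extra_cpgs),
      tss = as_tibble(tss), lloq = lloq
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  donors: %d, ages %d-%d, %d batch level(s)\n",
              x$n_donors, x$age_range[1], x$age_range[2], x$batch_levels))
  cat(sprintf("  stimulations: %s (null: %s)\n",
              paste(x$stimulations, collapse = ", "), x$null_condition))
  cat(sprintf("  cytokines: %d; planted effects: %d direct, %d chains, %d SNPs, %d CpGs\n",
              length(x$cytokines), nrow(x$effect_ledger),
              nrow(x$mediation_specs), nrow(x$snp_specs), nrow(x$cpg_specs)))
  invisible(x)
}
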