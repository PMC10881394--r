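# End-to-end orchestration: induction -> responder detection -> variable
# screen -> mediation -> pQTL -> variance decomposition, with TSV
# outputs, provenance headers and a stage report.

#' Default stimulation-to-main-cell-subset map
#'
#' The pQTL and CpG models adjust for one major cell subset per
#' stimulation (e.g. monocytes for bacterial stimulations, effector
#' memory T cells for T cell receptor cross-linking). This builds the
#' default mapping for whatever subsets are available; override it via
#' the `subset_map` argument of [run_pipeline()].
#'
#' @param stimulations Stimulation names (non-null).
#' @param cell_subsets Available cell-subset column names.
#' @return Tibble (stimulation, subset).
#' @export
main_subset_map <- function(stimulations, cell_subsets) {
  preferred <- c("LPS" = "monocytes", "E. coli" = "monocytes",
                 "C. albicans" = "monocytes", "SEB" = "CD4_TEM",
                 "aCD3CD28" = "CD8_TEM", "BCG" = "monocytes")
  tibble(
    stimulation = stimulations,
    subset = purrr::map_chr(stimulations, function(s) {
      cand <- preferred[[s]] %||% cell_subsets[1]
      if (cand %in% cell_subsets) cand else cell_subsets[1]
    })
  )
}

pipeline_log <- function(report, stage, status, detail = "") {
  inform(sprintf("[%s] %s %s", stage, status,
                 if (nzchar(detail)) paste0("- ", detail) else ""))
  bind_rows(report, tibble(stage = stage, status = status, detail = detail))
}

#' Run the full analysis pipeline on a cohort bundle
#'
#' Executes, in order: induction flagging and SLMD profiling, responder
#' detection for the designated stimulation, the per-stimulation
#' variable screen, mediator-elimination matrices for the cell and
#' protein panels (for the configured variable of interest), CpG
#' TSS-window association tests, the pQTL scan (skipped, and recorded
#' as skipped, when the bundle carries no genotypes), and the LMG
#' variance decomposition over the variables found associated. Every
#' output table is written as TSV with a provenance header; a
#' `report.tsv` records each stage with donor/test counts. Re-running
#' with identical inputs and seeds reproduces identical tables.
#'
#' @param bundle A `"cohort_bundle"` (from [simulate_cohort()] or
#'   [read_bundle()]).
#' @param out_dir Output directory.
#' @param variable_of_interest Variable driving the mediation stage.
#' @param thresholds Named list; defaults match
#'   [load_pipeline_config()].
#' @param seeds Named list of seeds (`responders`, `varpart`).
#' @param subset_map Optional tibble (stimulation, subset) overriding
#'   [main_subset_map()].
#' @return Invisibly, a list with every stage result and the report.
#' @export
run_pipeline <- function(bundle, out_dir,
                         variable_of_interest = "smoking_status",
                         thresholds = list(), seeds = list(),
                         subset_map = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- modifyList(list(
    induction = 0.30, screen_alpha = 0.01, cpg_fdr = 0.05, maf = 0.05,
    cis_window = 1e6, cis_detection = 1e-3, trans_detection = 1e-5,
    bonferroni_alpha = 0.05, variance_q = 0.05
  ), thresholds)
  sd <- modifyList(list(responders = 1L, varpart = 1L), seeds)
  report <- tibble(stage = character(), status = character(),
                   detail = character())
  results <- list()
  null_cond <- bundle$null_condition %||% "null"
  stims <- setdiff(unique(bundle$cytokines$stimulation), null_cond)

  run_stage <- function(stage, expr) {
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      report <<- pipeline_log(report, stage, "failed", conditionMessage(out))
      write_tsv_prov(report, file.path(out_dir, "report.tsv"),
                     stage = "report")
      abort(sprintf("pipeline halted at stage `%s`: %s", stage,
                    conditionMessage(out)),
            class = "cytovar_pipeline_error")
    }
    out
  }

  # induction profile
  results$induced <- run_stage("induction", {
    flag_induced(bundle$cytokines, null_cond, th$induction, bundle$lloq)
  })
  results$slmd <- run_stage("induction", {
    compute_slmd(bundle$cytokines, null_cond, lloq = bundle$lloq)
  })
  write_tsv_prov(results$induced, file.path(out_dir, "induction_flags.tsv"),
                 stage = "induction")
  write_tsv_prov(results$slmd, file.path(out_dir, "slmd.tsv"),
                 stage = "induction")
  report <- pipeline_log(report, "induction", "ok",
                         sprintf("%d induced pairs",
                                 sum(results$induced$induced)))

  # responder detection
  resp_stim <- bundle$responder_stimulation %||% NA_character_
  if (!is.na(resp_stim) && resp_stim %in% stims) {
    cyt_set <- results$induced %>%
      filter(.data$stimulation == resp_stim, .data$induced) %>%
      pull("cytokine")
    results$responders <- run_stage("responders", {
      detect_responders(bundle$cytokines, resp_stim, cyt_set,
                        seed = sd$responders)
    })
    write_tsv_prov(results$responders, file.path(out_dir, "responders.tsv"),
                   stage = "responders", seed = sd$responders)
    report <- pipeline_log(report, "responders", "ok",
                           sprintf("%d/%d responders",
                                   sum(results$responders$responder),
                                   nrow(results$responders)))
  } else {
    results$responders <- NULL
    report <- pipeline_log(report, "responders", "skipped",
                           "no responder-restricted stimulation")
  }
  resp_for <- function(s) {
    if (!is.na(resp_stim) && identical(s, resp_stim)) results$responders
    else NULL
  }

  # variable screen per stimulation
  results$screens <- list()
  for (s in stims) {
    scr <- run_stage(paste0("screen/", s), {
      screen_associations(bundle$cytokines, bundle$covariates, s,
                          induced = results$induced,
                          responders = resp_for(s),
                          null_condition = null_cond,
                          alpha = th$screen_alpha, lloq = bundle$lloq)
    })
    results$screens[[s]] <- scr
    write_tsv_prov(scr$results,
                   file.path(out_dir, paste0("screen_", gsub("[^A-Za-z0-9]", "_", s), ".tsv")),
                   stage = paste0("screen/", s))
    report <- pipeline_log(report, paste0("screen/", s), "ok",
                           sprintf("%d tests, %d significant",
                                   nrow(scr$results),
                                   sum(scr$results$significant %||% logical())))
  }

  # mediation over cell and protein panels where the variable associates
  cellcols <- setdiff(names(bundle$cells %||% tibble()), "donor")
  panels <- list(cell = bundle$cells, protein = bundle$proteins)
  results$elimination <- list()
  for (kind in names(panels)) {
    pan <- panels[[kind]]
    if (is.null(pan)) {
      report <- pipeline_log(report, paste0("mediation/", kind), "skipped",
                             "panel absent")
      next
    }
    for (s in stims) {
      scr <- results$screens[[s]]
      sig <- scr$results %>%
        filter(.data$variable == variable_of_interest, .data$significant)
      if (!nrow(sig)) next
      em <- run_stage(paste0("mediation/", kind, "/", s), {
        elimination_matrix(bundle$cytokines, bundle$covariates, pan, kind,
                           variable_of_interest, s, scr,
                           induced = results$induced,
                           responders = resp_for(s),
                           null_condition = null_cond,
                           alpha = th$screen_alpha, lloq = bundle$lloq)
      })
      results$elimination[[paste(kind, s, sep = "/")]] <- em
      write_tsv_prov(em$records,
                     file.path(out_dir, sprintf("elimination_%s_%s.tsv", kind,
                                                gsub("[^A-Za-z0-9]", "_", s))),
                     stage = paste0("mediation/", kind))
      report <- pipeline_log(report, paste0("mediation/", kind, "/", s), "ok",
                             sprintf("%d eliminated",
                                     sum(em$records$eliminated)))
    }
  }

  # CpG TSS-window associations
  if (!is.null(bundle$methylation) && !is.null(bundle$tss)) {
    results$cpg_window <- list()
    sm <- subset_map %||% main_subset_map(stims, cellcols)
    for (s in stims) {
      subset <- sm$subset[sm$stimulation == s][1]
      cov2 <- bundle$covariates
      covs <- c("age", "sex", "batch")
      if (!is.na(subset) && length(cellcols)) {
        cov2 <- cov2 %>%
          left_join(bundle$cells %>%
                      dplyr::transmute(.data$donor,
                                       main_subset = log(.data[[subset]] + 0.5)),
                    by = "donor")
        covs <- c(covs, "main_subset")
      }
      cw <- run_stage(paste0("cpg_window/", s), {
        cpg_window_assoc(bundle$methylation, bundle$cpg_positions,
                         bundle$cytokines, bundle$tss, cov2, s,
                         covariates = covs, window = th$cis_window,
                         alpha = th$cpg_fdr, responders = resp_for(s),
                         lloq = bundle$lloq)
      })
      results$cpg_window[[s]] <- cw
      write_tsv_prov(cw, file.path(out_dir,
                                   sprintf("cpg_window_%s.tsv",
                                           gsub("[^A-Za-z0-9]", "_", s))),
                     stage = paste0("cpg_window/", s))
    }
    report <- pipeline_log(report, "cpg_window", "ok",
                           sprintf("%d stimulation(s)", length(stims)))
  } else {
    report <- pipeline_log(report, "cpg_window", "skipped",
                           "methylation or TSS table absent")
  }

  # pQTL scans
  if (!is.null(bundle$genotypes)) {
    flt <- maf_filter(bundle$genotypes, bundle$snp_map, th$maf)
    sm <- subset_map %||% main_subset_map(stims, cellcols)
    results$pqtl <- list()
    for (s in stims) {
      subset <- sm$subset[sm$stimulation == s][1]
      cov2 <- bundle$covariates
      covs <- c("age", "sex", "batch")
      if (!is.na(subset) && length(cellcols)) {
        cov2 <- cov2 %>%
          left_join(bundle$cells %>%
                      dplyr::transmute(.data$donor,
                                       main_subset = log(.data[[subset]] + 0.5)),
                    by = "donor")
        covs <- c(covs, "main_subset")
      }
      sc <- run_stage(paste0("pqtl/", s), {
        pqtl_scan(flt$genotypes, flt$snp_map, bundle$cytokines, cov2, s,
                  bundle$tss, covariates = covs,
                  cis_threshold = th$cis_detection,
                  trans_threshold = th$trans_detection,
                  alpha = th$bonferroni_alpha,
                  induced = results$induced, responders = resp_for(s),
                  null_condition = null_cond, lloq = bundle$lloq)
      })
      results$pqtl[[s]] <- sc
      write_tsv_prov(sc$hits, file.path(out_dir,
                                        sprintf("pqtl_%s.tsv",
                                                gsub("[^A-Za-z0-9]", "_", s))),
                     stage = paste0("pqtl/", s))
      report <- pipeline_log(report, paste0("pqtl/", s), "ok",
                             sprintf("%d tests, %d hits", sc$n_tests,
                                     sum(sc$hits$hit %||% logical())))
    }
  } else {
    report <- pipeline_log(report, "pqtl", "skipped", "no genotypes in bundle")
  }

  # variance decomposition over associated variables
  results$varpart <- list()
  sm <- subset_map %||% main_subset_map(stims, cellcols)
  for (s in stims) {
    scr <- results$screens[[s]]
    assoc_vars <- scr$results %>%
      filter(.data$p_adjusted < th$variance_q) %>%
      pull("variable") %>% unique()
    groups <- c(
      list(age = "age", sex = "sex", batch = "batch"),
      setNames(as.list(assoc_vars), assoc_vars)
    )
    reg <- bundle$covariates
    subset <- sm$subset[sm$stimulation == s][1]
    if (!is.na(subset) && length(cellcols)) {
      reg <- reg %>%
        left_join(bundle$cells %>%
                    dplyr::transmute(.data$donor,
                                     main_subset = log(.data[[subset]] + 0.5)),
                  by = "donor")
      groups$main_subset <- "main_subset"
    }
    if (!is.null(results$pqtl[[s]]) && nrow(results$pqtl[[s]]$hits)) {
      snps <- unique(results$pqtl[[s]]$hits$snp[results$pqtl[[s]]$hits$hit])
      if (length(snps)) {
        reg <- reg %>% left_join(bundle$genotypes[, c("donor", snps)],
                                 by = "donor")
        for (sn in snps) groups[[sn]] <- sn
      }
    }
    cw <- results$cpg_window[[s]]
    if (!is.null(cw) && nrow(cw) && "significant" %in% names(cw)) {
      cpgs <- unique(cw$cpg[cw$significant])
      if (length(cpgs)) {
        reg <- reg %>% left_join(bundle$methylation[, c("donor", cpgs)],
                                 by = "donor")
        for (cg in cpgs) groups[[cg]] <- cg
      }
    }
    vp <- run_stage(paste0("varpart/", s), {
      variance_report(bundle$cytokines, reg, s, groups,
                      induced = results$induced, responders = resp_for(s),
                      null_condition = null_cond, lloq = bundle$lloq,
                      mode = if (length(groups) <= 12) "exact" else "sampled",
                      seed = sd$varpart)
    })
    results$varpart[[s]] <- vp
    write_tsv_prov(vp, file.path(out_dir,
                                 sprintf("varpart_%s.tsv",
                                         gsub("[^A-Za-z0-9]", "_", s))),
                   stage = paste0("varpart/", s), seed = sd$varpart)
    report <- pipeline_log(report, paste0("varpart/", s), "ok",
                           sprintf("%d group(s)", length(groups)))
  }

  results$report <- report
  write_tsv_prov(report, file.path(out_dir, "report.tsv"), stage = "report")
  invisible(results)
}
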