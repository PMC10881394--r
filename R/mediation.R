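# Covariate-elimination mediation screening: a mediator "explains" a
# variable-cytokine association when adding it (with interaction) to
# the model renders the variable's LRT non-significant while the
# baseline association was significant.

# Kind-specific mediator transform used throughout: raw cell counts are
# log-transformed with a half-count offset for zeros, protein
# abundances are log-transformed, CpG beta values enter untransformed.
transform_mediator <- function(x, kind) {
  switch(kind,
    cell = log(x + 0.5),
    protein = log(x),
    cpg = x,
    abort_config("mediator kind must be cell/protein/cpg.", "kind")
  )
}

#' Covariate-elimination test for one mediator
#'
#' Compares, by likelihood-ratio test, the full model
#' `response ~ variable * mediator + covariates` against the reduced
#' model `response ~ mediator + covariates`, so the test measures what
#' the variable adds once the mediator (and its interaction with the
#' variable) is accounted for. The degrees of freedom are the
#' variable's main-effect plus interaction parameters.
#'
#' @param data Tibble containing all columns.
#' @param response (Log) response column name.
#' @param variable Variable of interest column name.
#' @param mediator Mediator column name (already transformed per its
#'   kind; see [transform_mediator()]).
#' @param covariates Adjustment covariates.
#' @param reference Reference level for a categorical variable.
#' @param interaction Include the variable-by-mediator interaction in
#'   the full model (default TRUE, matching the screening convention).
#' @return List (n_used, lrt_statistic, df, p_raw, untestable).
#' @export
covariate_elimination <- function(data, response, variable, mediator,
                                  covariates = c("age", "sex", "batch"),
                                  reference = NULL, interaction = TRUE) {
  use <- unique(c(response, variable, mediator, covariates))
  keep <- complete.cases(data[, use, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  d[[variable]] <- as_model_factor(d[[variable]], variable, reference)
  for (cv in covariates) {
    if (!is.numeric(d[[cv]])) d[[cv]] <- factor(as.character(d[[cv]]))
  }
  red_terms <- c(mediator, covariates)
  full_terms <- c(variable, red_terms,
                  if (interaction) sprintf("%s:%s", variable, mediator))
  X_red <- model.matrix(stats::reformulate(red_terms), d)
  X_full <- model.matrix(stats::reformulate(full_terms), d)
  extra <- setdiff(colnames(X_full), colnames(X_red))
  fit <- tryCatch(
    lrt_core(d[[response]], X_red, X_full, extra),
    cytovar_collinearity_error = function(e) e,
    cytovar_insufficient_variation = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(n_used = nrow(d), lrt_statistic = NA_real_, df = NA_integer_,
                p_raw = NA_real_, untestable = TRUE,
                reason = conditionMessage(fit)))
  }
  c(fit[c("n_used", "lrt_statistic", "df", "p_raw")],
    list(untestable = FALSE))
}

#' Mediator-elimination matrix for one stimulation
#'
#' Runs [covariate_elimination()] for every mediator in a panel against
#' every induced cytokine of a stimulation, applies Benjamini-Yekutieli
#' correction over that whole mediator-by-cytokine family, and compares
#' each adjusted p-value with the baseline screen (the same variable
#' tested without any mediator). A mediator is declared to eliminate an
#' association when the baseline adjusted p falls below `alpha` while
#' the with-mediator adjusted p does not.
#'
#' @param cyt Long cytokine tibble.
#' @param cov Donor covariate tibble.
#' @param panel Tibble (donor + one column per mediator) of raw panel
#'   values.
#' @param kind Panel kind: `"cell"`, `"protein"` or `"cpg"`; decides
#'   the mediator transform.
#' @param variable Variable of interest (e.g. `"smoking_status"`).
#' @param stimulation Stimulation to analyse.
#' @param baseline Baseline screen for this stimulation: a
#'   `"cytovar_screen"` object or its `results` tibble.
#' @param covariates Adjustment covariates.
#' @param induced Optional induction flags; computed when absent.
#' @param responders Optional responder labels (donor, responder).
#' @param null_condition,lloq As in [screen_associations()].
#' @param alpha Significance gate on adjusted p-values.
#' @param interaction Include variable-by-mediator interactions.
#' @return Object of class `"cytovar_elimination"`: list with `records`
#'   (variable, mediator, stimulation, cytokine, both adjusted ps,
#'   eliminated flag) sorted so eliminated mediators come first by
#'   descending with-mediator p.
#' @export
elimination_matrix <- function(cyt, cov, panel, kind, variable, stimulation,
                               baseline,
                               covariates = c("age", "sex", "batch"),
                               induced = NULL, responders = NULL,
                               null_condition = "null", lloq = NULL,
                               alpha = 0.01, interaction = TRUE) {
  check_cytokine_long(cyt)
  base_tbl <- if (inherits(baseline, "cytovar_screen")) baseline$results
              else baseline
  base_tbl <- base_tbl %>%
    filter(.data$variable == !!variable,
           .data$stimulation == !!stimulation) %>%
    select("cytokine", p_baseline_adjusted = "p_adjusted")

  if (is.null(induced)) {
    induced <- flag_induced(cyt, null_condition = null_condition, lloq = lloq)
  }
  ind_cyt <- induced %>%
    filter(.data$stimulation == !!stimulation, .data$induced) %>%
    pull("cytokine")
  mediators <- setdiff(names(panel), "donor")
  if (!length(mediators)) {
    inform("empty mediator panel; empty elimination table.")
    return(structure(list(records = tibble(), alpha = alpha, kind = kind),
                     class = "cytovar_elimination"))
  }

  dat <- cyt %>%
    filter(.data$stimulation == !!stimulation,
           .data$cytokine %in% ind_cyt)
  if (!is.null(responders)) {
    dat <- dat %>% filter(.data$donor %in% responders$donor[responders$responder])
  }
  wide <- dat %>%
    mutate(logc = log_clamped(.data$concentration)) %>%
    select("donor", "cytokine", "logc") %>%
    tidyr::pivot_wider(names_from = "cytokine", values_from = "logc") %>%
    inner_join(cov, by = "donor")
  pan <- panel
  for (m in mediators) pan[[m]] <- transform_mediator(pan[[m]], kind)
  wide <- wide %>% left_join(pan, by = "donor")

  rec <- purrr::map_dfr(mediators, function(m) {
    purrr::map_dfr(ind_cyt, function(cy) {
      fit <- covariate_elimination(wide, cy, variable, m, covariates,
                                   interaction = interaction)
      tibble(variable = variable, mediator = m, stimulation = stimulation,
             cytokine = cy, n_used = fit$n_used,
             lrt_statistic = fit$lrt_statistic, df = fit$df,
             p_raw = fit$p_raw, untestable = fit$untestable)
    })
  })
  rec <- rec %>%
    mutate(p_with_mediator_adjusted = p.adjust(.data$p_raw, method = "BY")) %>%
    left_join(base_tbl, by = "cytokine") %>%
    mutate(eliminated = !.data$untestable &
             !is.na(.data$p_baseline_adjusted) &
             .data$p_baseline_adjusted < alpha &
             .data$p_with_mediator_adjusted >= alpha) %>%
    arrange(dplyr::desc(.data$eliminated),
            dplyr::desc(.data$p_with_mediator_adjusted))
  structure(list(records = rec, alpha = alpha, kind = kind,
                 stimulation = stimulation, variable = variable),
            class = "cytovar_elimination")
}

#' @export
print.cytovar_elimination <- function(x, ...) {
  cat(sprintf("<cytovar_elimination> %s / %s (%s panel): %d records, %d eliminated at alpha = %g\n",
              x$variable, x$stimulation, x$kind, nrow(x$records),
              sum(x$records$eliminated %||% logical()), x$alpha))
  invisible(x)
}

#' CpG associations within a TSS window
#'
#' For each cytokine gene, tests every CpG site lying on the same
#' chromosome within `window` bases of the gene's transcription start
#' site (closed interval, 1 Mb by default) for association with the
#' log cytokine level in one stimulation, via [fit_lrt()] with the
#' stated covariates (age, sex, batch and, when supplied in `cov`,
#' major cell counts). P-values are FDR-adjusted (Benjamini-Hochberg)
#' over the whole table and called significant below `alpha` (0.05).
#'
#' @param methylation Tibble (donor + one column per CpG) of betas.
#' @param cpg_positions Tibble (id, chrom, position).
#' @param cyt Long cytokine tibble.
#' @param tss Tibble (gene, chrom, tss); genes are cytokine names.
#' @param cov Donor covariates (include cell-count columns here and
#'   name them in `covariates` to adjust for them).
#' @param stimulation Stimulation to analyse.
#' @param covariates Adjustment covariates.
#' @param window Window half-width in bases.
#' @param alpha FDR significance threshold.
#' @param responders Optional responder labels.
#' @param lloq Optional LLOQ tibble.
#' @return Tibble (cytokine, cpg, chrom, position, distance, n_used,
#'   lrt_statistic, df, p_raw, p_adjusted, significant); CpGs without
#'   coordinates are skipped and counted in attribute
#'   `"n_skipped_no_position"`.
#' @export
cpg_window_assoc <- function(methylation, cpg_positions, cyt, tss, cov,
                             stimulation,
                             covariates = c("age", "sex", "batch"),
                             window = 1e6, alpha = 0.05,
                             responders = NULL, lloq = NULL) {
  check_cytokine_long(cyt)
  cpgs <- setdiff(names(methylation), "donor")
  no_pos <- setdiff(cpgs, cpg_positions$id)
  if (length(no_pos)) {
    warn(sprintf("%d CpG(s) without coordinates skipped.", length(no_pos)))
  }
  pos <- cpg_positions %>% filter(.data$id %in% cpgs)

  dat <- cyt %>% filter(.data$stimulation == !!stimulation)
  if (!is.null(responders)) {
    dat <- dat %>% filter(.data$donor %in% responders$donor[responders$responder])
  }
  wide <- dat %>%
    mutate(logc = log_clamped(.data$concentration)) %>%
    select("donor", "cytokine", "logc") %>%
    tidyr::pivot_wider(names_from = "cytokine", values_from = "logc") %>%
    inner_join(cov, by = "donor") %>%
    left_join(methylation, by = "donor")

  out <- purrr::map_dfr(seq_len(nrow(tss)), function(i) {
    gene <- tss$gene[i]
    if (!gene %in% names(wide)) return(tibble())
    hits <- pos %>%
      filter(as.character(.data$chrom) == as.character(tss$chrom[i]),
             abs(.data$position - tss$tss[i]) <= window)
    purrr::map_dfr(seq_len(nrow(hits)), function(j) {
      fit <- tryCatch(
        fit_lrt(wide, gene, hits$id[j], covariates),
        error = function(e) NULL
      )
      if (is.null(fit)) return(tibble())
      tibble(cytokine = gene, cpg = hits$id[j],
             chrom = as.character(hits$chrom[j]),
             position = hits$position[j],
             distance = abs(hits$position[j] - tss$tss[i]),
             n_used = fit$n_used, lrt_statistic = fit$lrt_statistic,
             df = fit$df, p_raw = fit$p_raw)
    })
  })
  if (nrow(out)) {
    out <- out %>%
      mutate(p_adjusted = p.adjust(.data$p_raw, method = "fdr"),
             significant = .data$p_adjusted < alpha)
  }
  attr(out, "n_skipped_no_position") <- length(no_pos)
  out
}
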