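# Response-pQTL mapping: matrix least-squares scan of induced cytokine
# levels on genotype dosages after projecting out covariates
# (Frisch-Waugh residualization), cis/trans classification against the
# cytokine gene TSS, Bonferroni control, conditional analysis, and
# genotype-by-smoking interaction tests.

#' Filter SNPs by minor allele frequency
#'
#' Minor allele frequencies are recomputed from the non-missing
#' dosages (`maf = min(p, 1 - p)` with `p = mean(dosage) / 2`) and
#' SNPs are retained only when strictly above `threshold`.
#'
#' @param genotypes Tibble (donor + one dosage column in {0, 1, 2} per
#'   SNP; NA allowed).
#' @param snp_map Optional tibble (id, chrom, position, ...) filtered
#'   alongside.
#' @param threshold MAF threshold (strict inequality), default 0.05.
#' @return List (genotypes, snp_map, maf, n_removed).
#' @export
maf_filter <- function(genotypes, snp_map = NULL, threshold = 0.05) {
  snps <- setdiff(names(genotypes), "donor")
  maf <- purrr::map_dbl(snps, function(s) {
    d <- genotypes[[s]]
    d <- d[!is.na(d)]
    if (!length(d)) return(0)
    p <- mean(d) / 2
    min(p, 1 - p)
  })
  keep <- maf > threshold
  if (!any(keep)) inform("all SNPs removed by the MAF filter; empty scan.")
  list(
    genotypes = genotypes[, c("donor", snps[keep]), drop = FALSE],
    snp_map = if (!is.null(snp_map)) {
      snp_map %>% filter(.data$id %in% snps[keep])
    },
    maf = tibble(id = snps, maf = maf)[keep, ],
    n_removed = sum(!keep)
  )
}

#' Classify a SNP as cis or trans for a gene
#'
#' A SNP is cis-acting for a gene when it lies on the same chromosome
#' within `window` bases (closed interval, 1-based positions) of the
#' gene's transcription start site; otherwise trans. Genes absent from
#' the TSS table yield `"unclassified"`.
#'
#' @param chrom,position SNP coordinates.
#' @param gene Gene (cytokine) name.
#' @param tss Tibble (gene, chrom, tss).
#' @param window Window half-width in bases (default 1 Mb).
#' @return `"cis"`, `"trans"` or `"unclassified"`.
#' @export
classify_cis_trans <- function(chrom, position, gene, tss, window = 1e6) {
  i <- match(gene, tss$gene)
  if (is.na(i)) return("unclassified")
  if (as.character(chrom) == as.character(tss$chrom[i]) &&
      abs(position - tss$tss[i]) <= window) "cis" else "trans"
}

#' Scan induced cytokines for response pQTLs
#'
#' For every (retained SNP, induced cytokine) pair in one stimulation,
#' fits ordinary least squares of the log cytokine concentration on
#' the additive genotype dosage plus covariates, and keeps the
#' per-allele slope and its t-test. For speed the covariates are
#' projected out of phenotypes and genotypes once per scan
#' (Frisch-Waugh residualization), with degrees of freedom corrected
#' for the projected columns — numerically identical to per-SNP full
#' fits. Missing dosages are mean-imputed per SNP (count reported).
#'
#' Records are retained when the raw p-value falls below the
#' class-specific detection threshold (`1e-3` for cis, `1e-5` for
#' trans), then Bonferroni-adjusted over the full family of tests run
#' in the scan (all retained SNPs times all tested cytokines); hits
#' are adjusted p < `alpha`. The cytokine identical to the stimulation
#' agonist is excluded, since it was added to the stimulation tube and
#' does not reflect endogenous secretion.
#'
#' @param genotypes Dosage tibble (donor + SNP columns), already MAF
#'   filtered (see [maf_filter()]).
#' @param snp_map Tibble (id, chrom, position).
#' @param cyt Long cytokine tibble.
#' @param cov Donor covariates; include the stimulation's main
#'   associated cell-subset column here and name it in `covariates`.
#' @param stimulation Stimulation to scan.
#' @param tss Tibble (gene, chrom, tss) for cis/trans classification.
#' @param covariates Adjustment covariate column names.
#' @param cis_threshold,trans_threshold Detection thresholds on raw p.
#' @param alpha Bonferroni-adjusted significance level.
#' @param induced Optional induction flags; computed when absent.
#' @param responders Optional responder labels (donor, responder).
#' @param exclude_cytokines Cytokines to drop; defaults to any cytokine
#'   whose name equals the stimulation.
#' @param null_condition,lloq As in [screen_associations()].
#' @param keep_all Also return every (SNP, cytokine) test (for small
#'   scans / cross-checks).
#' @return Object of class `"cytovar_pqtl"`: list with `hits` (records
#'   passing the detection thresholds, Bonferroni-adjusted, cis/trans
#'   labelled), `n_tests`, `n_used`, `df_resid`, and optionally `all`.
#' @export
pqtl_scan <- function(genotypes, snp_map, cyt, cov, stimulation, tss,
                      covariates = c("age", "sex", "batch"),
                      cis_threshold = 1e-3, trans_threshold = 1e-5,
                      alpha = 0.05, induced = NULL, responders = NULL,
                      exclude_cytokines = NULL, null_condition = "null",
                      lloq = NULL, keep_all = FALSE) {
  check_cytokine_long(cyt)
  if (is.null(induced)) {
    induced <- flag_induced(cyt, null_condition = null_condition, lloq = lloq)
  }
  ind_cyt <- induced %>%
    filter(.data$stimulation == !!stimulation, .data$induced) %>%
    pull("cytokine")
  if (is.null(exclude_cytokines)) {
    exclude_cytokines <- intersect(ind_cyt, stimulation)
  }
  ind_cyt <- setdiff(ind_cyt, exclude_cytokines)
  if (!length(ind_cyt)) {
    inform("no induced cytokines to scan; empty result.")
    return(structure(list(hits = tibble(), n_tests = 0L),
                     class = "cytovar_pqtl"))
  }

  dat <- cyt %>%
    filter(.data$stimulation == !!stimulation, .data$cytokine %in% ind_cyt)
  if (!is.null(responders)) {
    dat <- dat %>% filter(.data$donor %in% responders$donor[responders$responder])
  }
  wide <- dat %>%
    mutate(logc = log_clamped(.data$concentration)) %>%
    select("donor", "cytokine", "logc") %>%
    tidyr::pivot_wider(names_from = "cytokine", values_from = "logc") %>%
    inner_join(cov, by = "donor") %>%
    inner_join(genotypes, by = "donor")

  snps <- intersect(setdiff(names(genotypes), "donor"), names(wide))
  use_rows <- complete.cases(wide[, c(ind_cyt, covariates), drop = FALSE])
  wide <- wide[use_rows, , drop = FALSE]
  n <- nrow(wide)
  for (cv in covariates) {
    if (!is.numeric(wide[[cv]])) wide[[cv]] <- factor(as.character(wide[[cv]]))
  }
  X <- if (length(covariates)) {
    model.matrix(stats::reformulate(covariates), wide)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  qX <- qr(X)
  if (qX$rank < ncol(X)) {
    aliased <- colnames(X)[qX$pivot[(qX$rank + 1):ncol(X)]]
    abort_data(sprintf("collinear covariate column(s): %s",
                       paste(aliased, collapse = ", ")),
               class = "cytovar_collinearity_error")
  }
  df_resid <- n - qX$rank - 1L
  if (df_resid < 1) abort_data("too few donors for the pQTL model.")

  G <- as.matrix(wide[, snps, drop = FALSE])
  n_imputed <- sum(is.na(G))
  if (n_imputed) {
    inform(sprintf("mean-imputing %d missing dosage value(s).", n_imputed))
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- mean(G[!nas, j])
    }
  }
  Y <- as.matrix(wide[, ind_cyt, drop = FALSE])

  Yr <- qr.resid(qX, Y)
  Gr <- qr.resid(qX, G)
  g2 <- colSums(Gr^2)
  testable <- g2 > 1e-10 * n
  if (!all(testable)) {
    warn(sprintf("%d SNP(s) collinear with covariates flagged untestable.",
                 sum(!testable)))
  }
  yss <- colSums(Yr^2)
  num <- crossprod(Gr, Yr)                      # m x k
  slope <- sweep(num, 1, g2, "/")
  rss <- outer(rep(1, length(g2)), yss) - num^2 / g2
  se <- sqrt(rss / df_resid / g2)
  tval <- slope / se
  pval <- 2 * pt(abs(tval), df_resid, lower.tail = FALSE)

  all_tbl <- tibble(
    snp = rep(snps, times = length(ind_cyt)),
    cytokine = rep(ind_cyt, each = length(snps)),
    slope = as.vector(slope), t_statistic = as.vector(tval),
    p_raw = as.vector(pval),
    untestable = rep(!testable, times = length(ind_cyt))
  ) %>%
    mutate(stimulation = stimulation, n_used = n)
  map_idx <- match(all_tbl$snp, snp_map$id)
  all_tbl$cis_trans <- purrr::pmap_chr(
    list(snp_map$chrom[map_idx], snp_map$position[map_idx],
         all_tbl$cytokine),
    function(ch, po, cy) {
      if (is.na(ch)) "unclassified" else classify_cis_trans(ch, po, cy, tss)
    }
  )
  if (any(all_tbl$cis_trans == "unclassified")) {
    warn("SNP-cytokine pair(s) without TSS information labelled unclassified; trans detection threshold applied.")
  }
  n_tests <- sum(!all_tbl$untestable)
  detect <- ifelse(all_tbl$cis_trans == "cis", cis_threshold, trans_threshold)
  hits <- all_tbl %>%
    mutate(detection_threshold = detect) %>%
    filter(!.data$untestable, .data$p_raw < .data$detection_threshold) %>%
    mutate(p_adjusted = pmin(1, .data$p_raw * n_tests),
           hit = .data$p_adjusted < alpha) %>%
    arrange(.data$p_adjusted) %>%
    select("snp", "stimulation", "cytokine", "slope", "t_statistic",
           "p_raw", "p_adjusted", "cis_trans", "n_used", "hit")
  structure(
    list(hits = hits, n_tests = n_tests, n_used = n, df_resid = df_resid,
         n_imputed = n_imputed, alpha = alpha,
         cis_threshold = cis_threshold, trans_threshold = trans_threshold,
         all = if (keep_all) all_tbl),
    class = "cytovar_pqtl"
  )
}

#' @export
print.cytovar_pqtl <- function(x, ...) {
  cat(sprintf("<cytovar_pqtl> %d tests over %d donors: %d record(s) past detection, %d hit(s) at Bonferroni-adjusted p < %g\n",
              x$n_tests, x$n_used %||% 0L, nrow(x$hits),
              sum(x$hits$hit %||% logical()), x$alpha %||% 0.05))
  invisible(x)
}

#' Conditional pQTL analysis
#'
#' Re-runs [pqtl_scan()] with the dosage of a conditioning SNP appended
#' to the covariates, to test whether other associations are
#' independent of that locus. A tested SNP in perfect LD with the
#' conditioning SNP has no residual dosage variance and is flagged
#' untestable.
#'
#' @inheritParams pqtl_scan
#' @param conditioning_snp SNP id present in `genotypes`.
#' @param ... Further arguments passed to [pqtl_scan()].
#' @return A `"cytovar_pqtl"` object; the conditioning SNP itself is
#'   removed from the tested set.
#' @export
conditional_scan <- function(genotypes, snp_map, cyt, cov, stimulation, tss,
                             conditioning_snp,
                             covariates = c("age", "sex", "batch"), ...) {
  if (!conditioning_snp %in% names(genotypes)) {
    abort_config(sprintf("conditioning SNP `%s` not in genotypes.",
                         conditioning_snp), "conditioning_snp")
  }
  cond_col <- paste0("cond_", conditioning_snp)
  cov2 <- cov %>%
    left_join(genotypes %>%
                select("donor", !!cond_col := dplyr::all_of(conditioning_snp)),
              by = "donor")
  geno2 <- genotypes[, setdiff(names(genotypes), conditioning_snp),
                     drop = FALSE]
  pqtl_scan(geno2, snp_map, cyt, cov2, stimulation, tss,
            covariates = c(covariates, cond_col), ...)
}

#' Genotype-by-smoking interaction tests for pQTL hits
#'
#' For each pQTL hit, compares by LRT the model with
#' `dosage * smoking_status` interaction terms against the additive
#' model `dosage + smoking_status` (both with covariates), applies
#' Benjamini-Yekutieli adjustment over the tested hits, and reports
#' exponentiated interaction coefficients with confidence intervals.
#'
#' @param hits Tibble with `snp` and `cytokine` columns (e.g. the
#'   `hits` element of a [pqtl_scan()] result).
#' @param genotypes Dosage tibble.
#' @param cyt Long cytokine tibble.
#' @param cov Donor covariates including the smoking column.
#' @param stimulation Stimulation analysed.
#' @param smoking Smoking status column name.
#' @param covariates Adjustment covariates.
#' @param responders Optional responder labels.
#' @param conf_level Confidence level for interaction coefficients.
#' @param lloq Optional LLOQ tibble.
#' @return List of class `"cytovar_gxe"` with `tests` (snp, cytokine,
#'   LRT, BY-adjusted p) and `coefficients` (per interaction term,
#'   exponentiated with CIs).
#' @export
gxe_interaction <- function(hits, genotypes, cyt, cov, stimulation,
                            smoking = "smoking_status",
                            covariates = c("age", "sex", "batch"),
                            responders = NULL, conf_level = 0.95,
                            lloq = NULL) {
  check_cytokine_long(cyt)
  if (!smoking %in% names(cov)) {
    abort_data(sprintf("smoking column `%s` not in covariates.", smoking))
  }
  dat <- cyt %>% filter(.data$stimulation == !!stimulation)
  if (!is.null(responders)) {
    dat <- dat %>% filter(.data$donor %in% responders$donor[responders$responder])
  }
  wide <- dat %>%
    mutate(logc = log_clamped(.data$concentration)) %>%
    select("donor", "cytokine", "logc") %>%
    tidyr::pivot_wider(names_from = "cytokine", values_from = "logc") %>%
    inner_join(cov, by = "donor") %>%
    inner_join(genotypes, by = "donor")
  wide[[smoking]] <- as_model_factor(wide[[smoking]], smoking)

  tests <- list(); coefs <- list()
  for (i in seq_len(nrow(hits))) {
    snp <- hits$snp[i]; cy <- hits$cytokine[i]
    if (!snp %in% names(wide) || !cy %in% names(wide)) next
    use <- unique(c(cy, snp, smoking, covariates))
    d <- wide[complete.cases(wide[, use, drop = FALSE]), , drop = FALSE]
    cross <- table(d[[snp]] > 0, d[[smoking]])
    if (any(cross == 0)) {
      warn(sprintf("empty genotype-smoking cell(s) for %s / %s.", snp, cy))
    }
    for (cv in covariates) {
      if (!is.numeric(d[[cv]])) d[[cv]] <- factor(as.character(d[[cv]]))
    }
    X_red <- model.matrix(
      stats::reformulate(c(snp, smoking, covariates)), d)
    X_full <- model.matrix(
      stats::reformulate(c(snp, smoking, covariates,
                           sprintf("%s:%s", snp, smoking))), d)
    extra <- setdiff(colnames(X_full), colnames(X_red))
    fit <- tryCatch(
      lrt_core(d[[cy]], X_red, X_full, extra, conf_level),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    tests[[length(tests) + 1L]] <- tibble(
      snp = snp, stimulation = stimulation, cytokine = cy,
      n_used = fit$n_used, lrt_statistic = fit$lrt_statistic,
      df = fit$df, p_raw = fit$p_raw
    )
    coefs[[length(coefs) + 1L]] <- fit$coefficients %>%
      mutate(snp = snp, cytokine = cy, .before = 1)
  }
  tests <- bind_rows(tests)
  if (nrow(tests)) {
    tests <- tests %>%
      mutate(p_adjusted = p.adjust(.data$p_raw, method = "BY"))
  }
  structure(list(tests = tests, coefficients = bind_rows(coefs),
                 stimulation = stimulation),
            class = "cytovar_gxe")
}
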