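# Induction profiling: which cytokines respond to which stimulation,
# standardized log mean differences, profile clustering, responder
# detection and a PCA overview.

check_cytokine_long <- function(cyt) {
  need <- c("donor", "stimulation", "cytokine", "concentration")
  missing_cols <- setdiff(need, names(cyt))
  if (length(missing_cols)) {
    abort_data(sprintf("cytokine table lacks column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  invisible(cyt)
}

#' Flag induced cytokines
#'
#' A cytokine is flagged as induced in a stimulation when the median
#' concentration across donors deviates from the null-condition median
#' by at least `threshold` (30% by default) in relative terms, in
#' either direction: `|median_stim / median_null - 1| >= threshold`.
#' When the null-condition median sits at the assay's quantification
#' floor (LLOQ) and the stimulated median exceeds it, the cytokine is
#' flagged induced regardless of the ratio (degenerate-null rule).
#'
#' @param cyt Long cytokine tibble (donor, stimulation, cytokine,
#'   concentration); concentrations are positive, missing values
#'   allowed.
#' @param null_condition Name of the non-stimulated control condition.
#' @param threshold Minimum relative deviation of medians.
#' @param lloq Optional tibble (stimulation, cytokine, lloq) used for
#'   the degenerate-null rule and LLOQ clamping.
#' @return Tibble (stimulation, cytokine, median_null, median_stim,
#'   ratio_deviation, induced).
#' @export
flag_induced <- function(cyt, null_condition = "null", threshold = 0.30,
                         lloq = NULL) {
  check_cytokine_long(cyt)
  if (!null_condition %in% cyt$stimulation) {
    abort_data(sprintf("null condition `%s` absent from cytokine table.",
                       null_condition))
  }
  nul <- cyt %>%
    filter(.data$stimulation == null_condition, !is.na(.data$concentration))
  stim <- cyt %>%
    filter(.data$stimulation != null_condition, !is.na(.data$concentration))
  if (!nrow(dplyr::semi_join(stim, nul, by = c("donor", "cytokine")))) {
    abort_data("no overlapping donors between stimulated and null conditions.")
  }

  med_null <- nul %>%
    group_by(.data$cytokine) %>%
    summarise(median_null = median(.data$concentration), .groups = "drop")
  out <- stim %>%
    group_by(.data$stimulation, .data$cytokine) %>%
    summarise(median_stim = median(.data$concentration), .groups = "drop") %>%
    left_join(med_null, by = "cytokine") %>%
    mutate(ratio_deviation = abs(.data$median_stim / .data$median_null - 1),
           induced = .data$ratio_deviation >= threshold)

  if (!is.null(lloq)) {
    floor_null <- lloq %>%
      filter(.data$stimulation == null_condition) %>%
      select("cytokine", lloq_null = "lloq")
    out <- out %>%
      left_join(floor_null, by = "cytokine") %>%
      mutate(induced = .data$induced |
               (!is.na(.data$lloq_null) &
                  .data$median_null <= .data$lloq_null &
                  .data$median_stim > .data$lloq_null)) %>%
      select(-"lloq_null")
  }
  out %>%
    select("stimulation", "cytokine", "median_null", "median_stim",
           "ratio_deviation", "induced")
}

#' Standardized log mean differences
#'
#' For each (stimulation, cytokine), computes the mean of the per-donor
#' paired differences between the stimulated and null conditions,
#' divided by the standard deviation of those paired differences.
#' Differences are taken on natural-log concentrations by default
#' (after optional LLOQ clamping), over donors with both measurements.
#' Pairs whose difference standard deviation is zero yield a non-finite
#' value and a warning; they are excluded from clustering downstream.
#'
#' @inheritParams flag_induced
#' @param log_scale Compute differences on log concentrations (default)
#'   or on the raw scale.
#' @return Tibble (stimulation, cytokine, slmd, n_pairs).
#' @export
compute_slmd <- function(cyt, null_condition = "null", log_scale = TRUE,
                         lloq = NULL) {
  check_cytokine_long(cyt)
  trans <- if (log_scale) function(x, l) log_clamped(x, l) else function(x, l) x
  lloq_of <- function(s, cy) {
    if (is.null(lloq)) return(NULL)
    v <- lloq$lloq[lloq$stimulation == s & lloq$cytokine == cy]
    if (length(v)) v[1] else NULL
  }

  nul <- cyt %>% filter(.data$stimulation == null_condition)
  out <- cyt %>%
    filter(.data$stimulation != null_condition) %>%
    inner_join(nul %>% select("donor", "cytokine", null_conc = "concentration"),
               by = c("donor", "cytokine")) %>%
    filter(!is.na(.data$concentration), !is.na(.data$null_conc)) %>%
    group_by(.data$stimulation, .data$cytokine) %>%
    summarise(
      slmd = {
        d <- trans(.data$concentration,
                   lloq_of(.data$stimulation[1], .data$cytokine[1])) -
          trans(.data$null_conc, lloq_of(null_condition, .data$cytokine[1]))
        s <- sd(d)
        if (is.na(s) || s == 0) NaN else mean(d) / s
      },
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
  if (any(!is.finite(out$slmd))) {
    warn(sprintf(
      "%d (stimulation, cytokine) pair(s) have zero-variance differences; slmd set to NaN.",
      sum(!is.finite(out$slmd))
    ))
  }
  out
}

#' Hierarchically cluster an induction profile
#'
#' Complete-linkage agglomerative clustering with Euclidean distance on
#' both rows (stimulations) and columns (cytokines) of the SLMD matrix.
#' Rows or columns containing non-finite entries are dropped first.
#' `stats::hclust` is deterministic given input order; ties merge the
#' pair with the lower original index first.
#'
#' @param slmd Tibble from [compute_slmd()], or a numeric matrix with
#'   dimnames.
#' @return List of class `"induction_clustering"` with `matrix`,
#'   `row_hclust`, `col_hclust`, `row_order`, `col_order`.
#' @export
cluster_profile <- function(slmd) {
  m <- if (is.matrix(slmd)) slmd else {
    slmd %>%
      select("stimulation", "cytokine", "slmd") %>%
      tidyr::pivot_wider(names_from = "cytokine", values_from = "slmd") %>%
      tibble::column_to_rownames("stimulation") %>%
      as.matrix()
  }
  keep_row <- apply(m, 1, function(r) all(is.finite(r)))
  keep_col <- apply(m, 2, function(cc) all(is.finite(cc)))
  dropped <- sum(!keep_row) + sum(!keep_col)
  if (dropped) {
    warn(sprintf("%d row(s)/column(s) with non-finite slmd excluded from clustering.",
                 dropped))
  }
  m <- m[keep_row, keep_col, drop = FALSE]
  if (nrow(m) < 2) {
    inform("fewer than 2 rows with finite values; clustering skipped.")
    return(structure(list(matrix = m, row_hclust = NULL, col_hclust = NULL,
                          row_order = rownames(m), col_order = colnames(m)),
                     class = "induction_clustering"))
  }
  rh <- hclust(dist(m, method = "euclidean"), method = "complete")
  ch <- if (ncol(m) >= 2) {
    hclust(dist(t(m), method = "euclidean"), method = "complete")
  } else NULL
  structure(
    list(matrix = m, row_hclust = rh, col_hclust = ch,
         row_order = rownames(m)[rh$order],
         col_order = if (is.null(ch)) colnames(m) else colnames(m)[ch$order]),
    class = "induction_clustering"
  )
}

#' Detect responders to a stimulation
#'
#' Splits donors into responders and non-responders by k-means
#' clustering (k = 2, 25 seeded restarts) on the log concentrations of
#' a chosen cytokine set for one stimulation. The cluster whose
#' centroid has the larger Euclidean norm is labelled the responder
#' group, so labels do not depend on k-means' arbitrary cluster
#' indices. Donors with incomplete measurements are dropped. A cohort
#' with one well-separated low mixture component — as seen for T cell
#' receptor cross-linking stimulations, where an Fc-gamma receptor
#' polymorphism abolishes the response — splits cleanly.
#'
#' @param cyt Long cytokine tibble.
#' @param stimulation Stimulation to analyse.
#' @param cytokine_set Cytokines whose log levels feed the clustering.
#' @param seed Integer seed (required; no ambient randomness).
#' @param nstart Number of k-means restarts.
#' @param lloq Optional LLOQ tibble for clamping.
#' @return Tibble (donor, responder) with attribute `"centers"`.
#' @export
detect_responders <- function(cyt, stimulation, cytokine_set, seed,
                              nstart = 25, lloq = NULL) {
  check_cytokine_long(cyt)
  check_scalar(seed, "seed", int = TRUE)
  wide <- cyt %>%
    filter(.data$stimulation == !!stimulation,
           .data$cytokine %in% cytokine_set) %>%
    mutate(logc = log_clamped(.data$concentration)) %>%
    select("donor", "cytokine", "logc") %>%
    tidyr::pivot_wider(names_from = "cytokine", values_from = "logc") %>%
    filter(complete.cases(.))
  if (nrow(wide) < 2) {
    abort_data("need at least 2 donors with complete data for responder detection.")
  }
  x <- as.matrix(wide[, -1, drop = FALSE])
  if (all(apply(x, 2, function(cc) max(cc) - min(cc)) == 0)) {
    warn("all donors identical; labelling every donor a responder.")
    return(tibble(donor = wide$donor, responder = TRUE))
  }
  set.seed(seed)
  km <- kmeans(x, centers = 2, nstart = nstart)
  norms <- sqrt(rowSums(km$centers^2))
  responder_cluster <- which.max(norms)
  out <- tibble(donor = wide$donor,
                responder = km$cluster == responder_cluster)
  attr(out, "centers") <- km$centers
  out
}

#' PCA overview of a cytokine matrix
#'
#' Donors-by-analyte principal component analysis: concentrations are
#' log-transformed, missing values mean-imputed per analyte, then
#' centred and scaled to unit variance before singular value
#' decomposition. Zero-variance analytes (after imputation) are
#' dropped with a warning. Variance fractions sum to one over the
#' retained components.
#'
#' @param cyt Long cytokine tibble; features are (stimulation,
#'   cytokine) pairs.
#' @param lloq Optional LLOQ tibble for clamping.
#' @param scale. Scale features to unit variance (default TRUE).
#' @return List of class `"cytokine_pca"`: `scores`, `loadings`
#'   (tibbles) and `variance` (component, sdev, var_fraction).
#' @export
pca_overview <- function(cyt, lloq = NULL, scale. = TRUE) {
  check_cytokine_long(cyt)
  wide <- cyt %>%
    mutate(feature = paste(.data$stimulation, .data$cytokine, sep = "|"),
           logc = log_clamped(.data$concentration)) %>%
    select("donor", "feature", "logc") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "logc")
  x <- as.matrix(wide[, -1, drop = FALSE])
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort_data("PCA needs at least 2 donors and 2 features.")
  }
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[!nas, j])
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance feature(s) before PCA.",
                 sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = bind_cols(tibble(donor = wide$donor), as_tibble(pc$x)),
      loadings = bind_cols(tibble(feature = rownames(pc$rotation)),
                           as_tibble(pc$rotation)),
      variance = tibble(component = paste0("PC", seq_along(vf)),
                        sdev = pc$sdev, var_fraction = vf)
    ),
    class = "cytokine_pca"
  )
}
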