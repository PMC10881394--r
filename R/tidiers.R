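# generics::tidy / glance methods so fitted objects drop straight into
# tidyverse workflows.

#' @exportS3Method
tidy.cytovar_lrt <- function(x, ...) x$coefficients

#' @exportS3Method
glance.cytovar_lrt <- function(x, ...) {
  tibble(variable = x$variable, response = x$response, n_used = x$n_used,
         lrt_statistic = x$lrt_statistic, df = x$df, p_raw = x$p_raw,
         rss_full = x$rss_full, rss_reduced = x$rss_reduced)
}

#' @exportS3Method
tidy.cytovar_screen <- function(x, ...) x$results

#' @exportS3Method
glance.cytovar_screen <- function(x, ...) {
  tibble(stimulation = x$stimulation, n_tests = nrow(x$results),
         n_significant = sum(x$results$significant %||% logical()),
         alpha = x$alpha)
}

#' @exportS3Method
tidy.cytovar_elimination <- function(x, ...) x$records

#' @exportS3Method
glance.cytovar_elimination <- function(x, ...) {
  tibble(variable = x$variable, stimulation = x$stimulation, kind = x$kind,
         n_records = nrow(x$records),
         n_eliminated = sum(x$records$eliminated %||% logical()),
         alpha = x$alpha)
}

#' @exportS3Method
tidy.cytovar_pqtl <- function(x, ...) x$hits

#' @exportS3Method
glance.cytovar_pqtl <- function(x, ...) {
  tibble(n_tests = x$n_tests, n_used = x$n_used %||% NA_integer_,
         n_detected = nrow(x$hits),
         n_hits = sum(x$hits$hit %||% logical()),
         n_imputed_dosages = x$n_imputed %||% 0L)
}

#' @exportS3Method
tidy.cytovar_gxe <- function(x, ...) x$coefficients

#' @exportS3Method
glance.cytovar_gxe <- function(x, ...) {
  tibble(stimulation = x$stimulation, n_tests = nrow(x$tests),
         min_p_adjusted = suppressWarnings(min(x$tests$p_adjusted, Inf)))
}

#' @exportS3Method
tidy.cytovar_varpart <- function(x, ...) {
  x$shares %>% mutate(total_r2 = x$total_r2, method = x$method)
}

#' @exportS3Method
glance.cytovar_varpart <- function(x, ...) {
  tibble(response = x$response, total_r2 = x$total_r2,
         n_groups = nrow(x$shares), method = x$method, n_used = x$n_used)
}

#' @exportS3Method
tidy.cytokine_pca <- function(x, ...) x$variance

#' @exportS3Method
tidy.truth_ledger <- function(x, ...) {
  purrr::map_dfr(names(x), function(nm) {
    if (!is.data.frame(x[[nm]])) return(tibble())
    tibble(table = nm, n = nrow(x[[nm]]))
  })
}
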