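# Internal helpers shared across modules.

abort_config <- function(msg, field = NULL) {
  abort(msg, class = "cytovar_config_error", field = field)
}

abort_data <- function(msg, class = NULL, ...) {
  abort(msg, class = c(class, "cytovar_data_error"), ...)
}

abort_numeric <- function(msg, ...) {
  abort(msg, class = "cytovar_numeric_error", ...)
}

# Per-table seed streams: one global seed plus a fixed, documented offset per
# table, so adding a table never perturbs the draws of another.
.table_seed_offsets <- c(
  covariates  = 101L,
  cells       = 202L,
  proteins    = 303L,
  methylation = 404L,
  genotypes   = 505L,
  cytokines   = 606L,
  responders  = 707L
)

table_seed <- function(seed, table) {
  offset <- .table_seed_offsets[[table]]
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# Checks that `x` is a single finite number within (optionally) a range.
check_scalar <- function(x, field, lo = -Inf, hi = Inf, int = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number.", field), field)
  }
  if (x < lo || x > hi) {
    abort_config(
      sprintf("`%s` must lie in [%s, %s]; got %s.", field, lo, hi, x), field
    )
  }
  if (int && x != round(x)) {
    abort_config(sprintf("`%s` must be an integer.", field), field)
  }
  invisible(x)
}

check_proportions <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_config(sprintf("`%s` entries must lie in [0, 1].", field), field)
  }
  if (abs(sum(x) - 1) > 1e-8) {
    abort_config(sprintf("`%s` must sum to 1.", field), field)
  }
  invisible(x)
}

# log with LLOQ clamping: concentrations below the analyte's lower limit of
# quantification are floored at that limit before the (natural) log.
log_clamped <- function(x, lloq = NULL) {
  if (!is.null(lloq)) x <- pmax(x, lloq)
  log(x)
}

first_reached <- function(x) x[which.max(!is.na(x))]
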