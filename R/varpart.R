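# LMG (Shapley) decomposition of explained variance: each regressor
# group's share is its R^2 contribution averaged over all orderings in
# which groups can enter the model.

# Expand one group's columns into a numeric design block (treatment
# dummies for categoricals); all columns of a group enter together.
group_block <- function(data, cols) {
  blocks <- lapply(cols, function(cl) {
    x <- data[[cl]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, cl))
    } else {
      f <- factor(as.character(x))
      m <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(cl, levels(f)[-1])
    }
    m
  })
  do.call(cbind, blocks)
}

rsq_of <- function(y, X, tss) {
  if (is.null(X) || ncol(X) == 0) return(0)
  fit_qr <- qr(cbind(1, X))
  1 - sum(qr.resid(fit_qr, y)^2) / tss
}

#' LMG (Shapley) variance shares for regressor groups
#'
#' Decomposes the full-model R^2 of a least-squares regression into
#' nonnegative per-group shares. The share of group k is the average,
#' over all orderings of the groups, of the increase in R^2 when k is
#' added after the groups preceding it:
#' `share(k) = sum over S not containing k of
#' |S|! (p - |S| - 1)! / p! * (R^2(S + k) - R^2(S))`.
#' Shares sum to the full-model R^2 (efficiency) and exchangeable
#' duplicate groups receive equal shares (symmetry). A multi-level
#' factor is one group: all its treatment-coded columns move together
#' through the orderings.
#'
#' Exact mode enumerates all `2^p` subsets (capped at p = 20); sampled
#' mode averages sequential gains over `n_orderings` seeded random
#' orderings and reports a Monte-Carlo standard error per share.
#' Rank-deficient subsets are handled by pivoted QR, so collinear
#' groups are permitted (with a warning).
#'
#' @param data Tibble with the response and all group columns.
#' @param response (Log) response column name.
#' @param groups Named list; each element is a character vector of
#'   column names forming one group.
#' @param mode `"exact"` or `"sampled"`.
#' @param seed Integer seed, required for sampled mode.
#' @param n_orderings Number of sampled orderings.
#' @return Object of class `"cytovar_varpart"`: list with `shares`
#'   (group, share[, mc_se]), `total_r2`, `method`, `n_used`.
#' @export
lmg_shares <- function(data, response, groups, mode = c("exact", "sampled"),
                       seed = NULL, n_orderings = 1000) {
  mode <- match.arg(mode)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort_config("`groups` must be a named list.", "groups")
  }
  p <- length(groups)
  use <- unique(c(response, unlist(groups)))
  missing_cols <- setdiff(use, names(data))
  if (length(missing_cols)) {
    abort_data(sprintf("column(s) not found: %s",
                       paste(missing_cols, collapse = ", ")))
  }
  d <- data[complete.cases(data[, use, drop = FALSE]), use, drop = FALSE]
  n <- nrow(d)
  y <- d[[response]]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort_data("response has zero variance.")
  blocks <- lapply(groups, function(cols) group_block(d, cols))
  full_cols <- do.call(cbind, blocks)
  if (qr(cbind(1, full_cols))$rank < ncol(full_cols) + 1) {
    warn("collinear regressor groups; R^2 computed via pivoted QR.")
  }

  subset_X <- function(mask) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    if (!length(idx)) NULL else do.call(cbind, blocks[idx])
  }

  if (mode == "exact") {
    if (p > 20) {
      abort_config("more than 20 groups: use mode = \"sampled\".", "groups")
    }
    r2 <- numeric(2^p)
    for (mask in seq_len(2^p) - 1L) {
      r2[mask + 1L] <- rsq_of(y, subset_X(mask), tss)
    }
    lfact <- lfactorial(0:p)
    shares <- numeric(p)
    for (k in seq_len(p)) {
      bit_k <- bitwShiftL(1L, k - 1L)
      acc <- 0
      for (mask in seq_len(2^p) - 1L) {
        if (bitwAnd(mask, bit_k) != 0L) next
        s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
        w <- exp(lfact[s + 1] + lfact[p - s] - lfact[p + 1])
        acc <- acc + w * (r2[bitwOr(mask, bit_k) + 1L] - r2[mask + 1L])
      }
      shares[k] <- acc
    }
    out <- tibble(group = names(groups), share = shares)
    total <- r2[2^p]
    method <- "exact"
  } else {
    if (is.null(seed)) {
      abort_config("sampled mode requires an explicit `seed`.", "seed")
    }
    set.seed(seed)
    gains <- matrix(0, n_orderings, p)
    for (it in seq_len(n_orderings)) {
      ord <- sample.int(p)
      mask <- 0L
      prev <- 0
      for (k in ord) {
        mask <- bitwOr(mask, bitwShiftL(1L, k - 1L))
        cur <- rsq_of(y, subset_X(mask), tss)
        gains[it, k] <- cur - prev
        prev <- cur
      }
    }
    out <- tibble(
      group = names(groups),
      share = colMeans(gains),
      mc_se = apply(gains, 2, sd) / sqrt(n_orderings)
    )
    total <- rsq_of(y, full_cols, tss)
    method <- sprintf("sampled (%d orderings, seed %d)", n_orderings, seed)
  }
  structure(list(shares = out, total_r2 = total, method = method,
                 n_used = n, response = response),
            class = "cytovar_varpart")
}

#' @export
print.cytovar_varpart <- function(x, ...) {
  cat(sprintf("<cytovar_varpart> %s: total R^2 = %.4f (%s, n = %d)\n",
              x$response, x$total_r2, x$method, x$n_used))
  print(x$shares)
  invisible(x)
}

#' Variance-explained report for one stimulation
#'
#' For each induced cytokine of a stimulation, decomposes the variance
#' of the log concentration over the supplied regressor groups (the
#' variables found associated in the screens — demographics, smoking,
#' CMV, BMI, the main cell subset, associated SNP dosages and CpG
#' betas) via [lmg_shares()].
#'
#' @param cyt Long cytokine tibble.
#' @param data Donor-level regressor table (one row per donor,
#'   containing every column referenced by `groups`, keyed by
#'   `donor`).
#' @param stimulation Stimulation to report.
#' @param groups Named list of column sets, as in [lmg_shares()].
#' @param induced Optional induction flags; computed when absent.
#' @param responders Optional responder labels.
#' @param null_condition,lloq As elsewhere.
#' @param mode,seed,n_orderings Passed to [lmg_shares()].
#' @return Tibble (stimulation, cytokine, group, share, total_r2,
#'   method, n_used).
#' @export
variance_report <- function(cyt, data, stimulation, groups,
                            induced = NULL, responders = NULL,
                            null_condition = "null", lloq = NULL,
                            mode = "exact", seed = NULL,
                            n_orderings = 1000) {
  check_cytokine_long(cyt)
  if (!length(groups)) {
    inform("empty regressor group set; report skipped.")
    return(tibble())
  }
  if (is.null(induced)) {
    induced <- flag_induced(cyt, null_condition = null_condition, lloq = lloq)
  }
  ind_cyt <- induced %>%
    filter(.data$stimulation == !!stimulation, .data$induced) %>%
    pull("cytokine")
  dat <- cyt %>%
    filter(.data$stimulation == !!stimulation, .data$cytokine %in% ind_cyt)
  if (!is.null(responders)) {
    dat <- dat %>% filter(.data$donor %in% responders$donor[responders$responder])
  }
  wide <- dat %>%
    mutate(logc = log_clamped(.data$concentration)) %>%
    select("donor", "cytokine", "logc") %>%
    tidyr::pivot_wider(names_from = "cytokine", values_from = "logc") %>%
    inner_join(data, by = "donor")

  purrr::map_dfr(ind_cyt, function(cy) {
    vp <- lmg_shares(wide, cy, groups, mode = mode, seed = seed,
                     n_orderings = n_orderings)
    vp$shares %>%
      mutate(stimulation = stimulation, cytokine = cy,
             total_r2 = vp$total_r2, method = vp$method,
             n_used = vp$n_used, .before = 1)
  })
}
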