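# Variable screening against induced cytokines: nested Gaussian linear
# models compared by likelihood-ratio tests, Benjamini-Yekutieli FDR
# control per stimulation, effect sizes and pairwise group contrasts.

#' Variables eligible for association testing
#'
#' Numeric variables are always eligible. A categorical variable with L
#' observed levels is eligible only if at least `ceiling(L / 2)` of its
#' levels each contain at least `min_share` (5% by default) of the
#' non-missing donors — a guard against levels too sparse to estimate.
#'
#' @param cov Donor covariate tibble.
#' @param id_cols Identifier columns to ignore.
#' @param min_share Minimum share of donors per qualifying level.
#' @return Tibble (variable, type, n_levels, levels_ge_share, eligible).
#' @export
eligible_variables <- function(cov, id_cols = "donor", min_share = 0.05) {
  vars <- setdiff(names(cov), id_cols)
  purrr::map_dfr(vars, function(v) {
    x <- cov[[v]][!is.na(cov[[v]])]
    if (is.numeric(x)) {
      return(tibble(variable = v, type = "numeric", n_levels = NA_integer_,
                    levels_ge_share = NA_integer_, eligible = TRUE))
    }
    tab <- table(as.character(x))
    L <- length(tab)
    ok <- sum(tab / sum(tab) >= min_share)
    tibble(variable = v, type = "categorical", n_levels = L,
           levels_ge_share = as.integer(ok),
           eligible = L >= 2 && ok >= ceiling(L / 2))
  })
}

# Coerce a screening variable into a modelling column: factors get
# treatment coding against a declared reference ("never" by default for
# smoking status).
as_model_factor <- function(x, variable, reference = NULL) {
  if (is.numeric(x)) return(x)
  x <- as.character(x)
  lev <- sort(unique(x[!is.na(x)]))
  if (is.null(reference) && variable == "smoking_status" && "never" %in% lev) {
    reference <- "never"
  }
  if (!is.null(reference)) {
    if (!reference %in% lev) {
      abort_data(sprintf("reference level `%s` not observed for `%s`.",
                         reference, variable))
    }
    lev <- c(reference, setdiff(lev, reference))
  }
  factor(x, levels = lev)
}

# Gaussian profile-likelihood LRT between two nested design matrices,
# vectorized over the columns of a response matrix Y (one QR pair
# serves every response). statistic = n * ln(RSS_reduced / RSS_full),
# chi-square reference with df = added rank. Returns per-column
# estimates/SEs for `extra_cols`.
lrt_core_multi <- function(Y, X_red, X_full, extra_cols, conf_level = 0.95) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  qr_f <- qr(X_full)
  if (qr_f$rank < ncol(X_full)) {
    aliased <- colnames(X_full)[qr_f$pivot[(qr_f$rank + 1):ncol(X_full)]]
    abort_data(sprintf("full model is rank deficient; aliased column(s): %s",
                       paste(aliased, collapse = ", ")),
               class = "cytovar_collinearity_error")
  }
  qr_r <- qr(X_red)
  df <- qr_f$rank - qr_r$rank
  if (df < 1) {
    abort_data("variable adds no parameters (insufficient variation).",
               class = "cytovar_insufficient_variation")
  }
  if (n <= qr_f$rank) {
    abort_data("fewer observations than full-model parameters.")
  }
  rss_f <- colSums(qr.resid(qr_f, Y)^2)
  rss_r <- colSums(qr.resid(qr_r, Y)^2)
  stat <- n * log(rss_r / rss_f)
  p <- pchisq(stat, df = df, lower.tail = FALSE)

  beta <- qr.coef(qr_f, Y)
  df_resid <- n - qr_f$rank
  sigma2 <- rss_f / df_resid
  xtx_inv <- chol2inv(qr.R(qr_f))[order(qr_f$pivot), order(qr_f$pivot),
                                  drop = FALSE]
  keep <- intersect(extra_cols, colnames(X_full))
  idx <- match(keep, colnames(X_full))
  dvar <- diag(xtx_inv)[idx]
  tcrit <- qt(1 - (1 - conf_level) / 2, df_resid)
  k <- ncol(Y)
  resp_names <- colnames(Y) %||% as.character(seq_len(k))
  est <- matrix(beta[idx, ], nrow = length(idx))
  se <- sqrt(outer(dvar, sigma2))
  tstat <- est / se
  coefs <- tibble(
    response = rep(resp_names, each = length(keep)),
    term = rep(keep, times = k),
    estimate = as.vector(est), std_error = as.vector(se),
    statistic = as.vector(tstat),
    p_value = as.vector(2 * pt(abs(tstat), df_resid, lower.tail = FALSE)),
    exp_estimate = as.vector(exp(est)),
    conf_low = as.vector(exp(est - tcrit * se)),
    conf_high = as.vector(exp(est + tcrit * se))
  )
  list(n_used = n, lrt_statistic = unname(stat), df = df, p_raw = unname(p),
       rss_full = unname(rss_f), rss_reduced = unname(rss_r),
       coefficients = coefs, df_resid = df_resid)
}

lrt_core <- function(y, X_red, X_full, extra_cols, conf_level = 0.95) {
  m <- lrt_core_multi(matrix(y, ncol = 1), X_red, X_full, extra_cols,
                      conf_level)
  list(n_used = m$n_used, lrt_statistic = m$lrt_statistic[1], df = m$df,
       p_raw = m$p_raw[1], rss_full = m$rss_full[1],
       rss_reduced = m$rss_reduced[1],
       coefficients = m$coefficients %>% select(-"response"),
       df_resid = m$df_resid)
}

# Build reduced/full design matrices for one variable on complete cases.
build_lrt_design <- function(data, variable, covariates, reference = NULL,
                             age_interaction = FALSE) {
  use <- unique(c(variable, covariates))
  keep <- complete.cases(data[, use, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  d[[variable]] <- as_model_factor(d[[variable]], variable, reference)
  if (is.factor(d[[variable]]) && nlevels(droplevels(d[[variable]])) < 2) {
    abort_data("variable adds no parameters (insufficient variation).",
               class = "cytovar_insufficient_variation")
  }
  for (cv in covariates) {
    if (!is.numeric(d[[cv]])) d[[cv]] <- factor(as.character(d[[cv]]))
  }
  f_red <- if (length(covariates)) {
    stats::reformulate(covariates)
  } else ~1
  full_terms <- c(variable, covariates)
  if (age_interaction) {
    if (!"age" %in% covariates) {
      abort_config("age interaction requested but `age` is not a covariate.",
                   "age_interaction")
    }
    full_terms <- c(full_terms, sprintf("%s:age", variable))
  }
  f_full <- stats::reformulate(full_terms)
  X_red <- model.matrix(f_red, d)
  X_full <- model.matrix(f_full, d)
  extra <- setdiff(colnames(X_full), colnames(X_red))
  list(data = d, keep = keep, X_red = X_red, X_full = X_full,
       extra_cols = extra)
}

#' Likelihood-ratio association test for one variable
#'
#' Fits two nested ordinary-least-squares models to a (log) response:
#' the reduced model with the adjustment covariates only (age, sex and
#' technical batch by default) and the full model adding the variable
#' of interest (and, when `age_interaction = TRUE`, its interaction
#' with age, so the LRT then tests main effect and interaction
#' jointly). The test statistic is the Gaussian profile-likelihood
#' deviance `n * ln(RSS_reduced / RSS_full)`, referred to a chi-square
#' distribution with as many degrees of freedom as parameters added.
#' Complete-case analysis; the donor count actually used is recorded.
#'
#' @param data Tibble with the response, variable and covariates.
#' @param response Name of the (already log-transformed) response
#'   column.
#' @param variable Name of the variable under test.
#' @param covariates Adjustment covariates for both models.
#' @param reference Reference level for a categorical variable
#'   (`"never"` is the default reference for `smoking_status`).
#' @param age_interaction Also add `variable:age` to the full model.
#' @param conf_level Confidence level for per-level intervals (t
#'   quantile with residual degrees of freedom).
#' @return Object of class `"cytovar_lrt"`; see [tidy()] and
#'   [glance()] methods.
#' @export
fit_lrt <- function(data, response, variable,
                    covariates = c("age", "sex", "batch"),
                    reference = NULL, age_interaction = FALSE,
                    conf_level = 0.95) {
  if (!response %in% names(data)) {
    abort_data(sprintf("response column `%s` not found.", response))
  }
  if (!variable %in% names(data)) {
    abort_data(sprintf("variable `%s` not found.", variable))
  }
  des <- build_lrt_design(
    data[!is.na(data[[response]]), , drop = FALSE],
    variable, covariates, reference, age_interaction
  )
  y <- des$data[[response]]
  res <- lrt_core(y, des$X_red, des$X_full, des$extra_cols, conf_level)
  structure(
    c(list(variable = variable, response = response,
           covariates = covariates, age_interaction = age_interaction),
      res),
    class = "cytovar_lrt"
  )
}

#' @export
print.cytovar_lrt <- function(x, ...) {
  cat(sprintf("<cytovar_lrt> %s on %s: LRT = %.4f (df %d), p = %.3g, n = %d\n",
              x$variable, x$response, x$lrt_statistic, x$df, x$p_raw,
              x$n_used))
  invisible(x)
}

#' Screen donor variables against induced cytokines
#'
#' Runs [fit_lrt()] for every eligible variable against every induced
#' cytokine of one stimulation, on natural-log concentrations (clamped
#' at the LLOQ when supplied), then applies Benjamini-Yekutieli
#' correction over exactly that family of tests — all variables crossed
#' with all induced cytokines within the stimulation. For a
#' responder-restricted stimulation, pass the responder labels so only
#' responding donors are modelled.
#'
#' @param cyt Long cytokine tibble.
#' @param cov Donor covariate tibble (`donor` id column).
#' @param stimulation Stimulation to screen.
#' @param variables Variables to test; defaults to the eligible set
#'   from [eligible_variables()] minus the adjustment covariates.
#' @param covariates Adjustment covariates.
#' @param induced Optional induction flags from [flag_induced()];
#'   computed from `cyt` when absent.
#' @param responders Optional tibble (donor, responder); only
#'   responders are retained.
#' @param null_condition Null condition name (used when computing
#'   induction flags).
#' @param alpha Adjusted-p significance gate (0.01 as in the screening
#'   convention).
#' @param age_interaction Test main effect and age interaction jointly.
#' @param lloq Optional LLOQ tibble.
#' @return Object of class `"cytovar_screen"`: a list with `results`
#'   (one row per test, BY-adjusted) and `coefficients` (per-level
#'   effect estimates).
#' @export
screen_associations <- function(cyt, cov, stimulation,
                                variables = NULL,
                                covariates = c("age", "sex", "batch"),
                                induced = NULL, responders = NULL,
                                null_condition = "null", alpha = 0.01,
                                age_interaction = FALSE, lloq = NULL) {
  check_cytokine_long(cyt)
  if (is.null(induced)) {
    induced <- flag_induced(cyt, null_condition = null_condition, lloq = lloq)
  }
  ind_cyt <- induced %>%
    filter(.data$stimulation == !!stimulation, .data$induced) %>%
    pull("cytokine")
  if (!length(ind_cyt)) {
    inform(sprintf("no induced cytokines for stimulation `%s`; empty result.",
                   stimulation))
    return(structure(list(results = tibble(), coefficients = tibble(),
                          stimulation = stimulation, alpha = alpha),
                     class = "cytovar_screen"))
  }
  if (is.null(variables)) {
    elig <- eligible_variables(cov)
    variables <- setdiff(elig$variable[elig$eligible], covariates)
  }

  dat <- cyt %>%
    filter(.data$stimulation == !!stimulation,
           .data$cytokine %in% ind_cyt)
  if (!is.null(responders)) {
    keep <- responders$donor[responders$responder]
    dat <- dat %>% filter(.data$donor %in% keep)
  }
  lq <- if (!is.null(lloq)) {
    lloq %>% filter(.data$stimulation == !!stimulation)
  } else NULL
  wide <- dat %>%
    mutate(logc = log_clamped(
      .data$concentration,
      if (!is.null(lq)) lq$lloq[match(.data$cytokine, lq$cytokine)] else NULL
    )) %>%
    select("donor", "cytokine", "logc") %>%
    tidyr::pivot_wider(names_from = "cytokine", values_from = "logc") %>%
    inner_join(cov, by = "donor")

  res <- list(); coefs <- list()
  for (v in variables) {
    des <- tryCatch(
      build_lrt_design(wide, v, covariates,
                       age_interaction = age_interaction),
      error = function(e) e
    )
    if (inherits(des, "error")) {
      warn(sprintf("skipping `%s`: %s", v, conditionMessage(des)))
      next
    }
    Y <- as.matrix(des$data[, ind_cyt, drop = FALSE])
    if (!anyNA(Y)) {
      # one QR pair serves every cytokine of the stimulation
      fit <- tryCatch(
        lrt_core_multi(Y, des$X_red, des$X_full, des$extra_cols),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        warn(sprintf("skipping `%s`: %s", v, conditionMessage(fit)))
        next
      }
      res[[length(res) + 1L]] <- tibble(
        variable = v, stimulation = stimulation, cytokine = ind_cyt,
        n_used = fit$n_used, lrt_statistic = fit$lrt_statistic,
        df = fit$df, p_raw = fit$p_raw
      )
      coefs[[length(coefs) + 1L]] <- fit$coefficients %>%
        rename(cytokine = "response") %>%
        mutate(variable = v, stimulation = stimulation, .before = 1)
      next
    }
    for (cy in ind_cyt) {
      y <- des$data[[cy]]
      ok <- !is.na(y)
      fit <- tryCatch(
        lrt_core(y[ok], des$X_red[ok, , drop = FALSE],
                 des$X_full[ok, , drop = FALSE], des$extra_cols),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        warn(sprintf("skipping `%s` ~ %s: %s", v, cy, conditionMessage(fit)))
        next
      }
      res[[length(res) + 1L]] <- tibble(
        variable = v, stimulation = stimulation, cytokine = cy,
        n_used = fit$n_used, lrt_statistic = fit$lrt_statistic,
        df = fit$df, p_raw = fit$p_raw
      )
      coefs[[length(coefs) + 1L]] <- fit$coefficients %>%
        mutate(variable = v, stimulation = stimulation, cytokine = cy,
               .before = 1)
    }
  }
  results <- bind_rows(res)
  if (nrow(results)) {
    results <- results %>%
      mutate(p_adjusted = p.adjust(.data$p_raw, method = "BY"),
             significant = .data$p_adjusted < alpha)
  }
  structure(
    list(results = results, coefficients = bind_rows(coefs),
         stimulation = stimulation, alpha = alpha,
         n_family = nrow(results)),
    class = "cytovar_screen"
  )
}

#' @export
print.cytovar_screen <- function(x, ...) {
  cat(sprintf("<cytovar_screen> %s: %d tests, %d significant at BY-adjusted p < %g\n",
              x$stimulation, nrow(x$results),
              sum(x$results$significant %||% logical()), x$alpha))
  invisible(x)
}

#' Per-level effect sizes with confidence intervals
#'
#' Treatment-coded coefficient estimates for each non-reference level
#' of the variable (or the slope for a numeric variable) from the full
#' adjusted model, exponentiated so they read as multiplicative effects
#' on the concentration scale, with t-based confidence intervals.
#' Levels whose coefficient t-test p-value falls below `sig_level` are
#' marked significant (the convention used to colour effect-size
#' plots).
#'
#' @inheritParams fit_lrt
#' @param sig_level Per-coefficient significance mark threshold.
#' @return Tibble (term, estimate, std_error, statistic, p_value,
#'   exp_estimate, conf_low, conf_high, significant) with the LRT p as
#'   attribute `"lrt"`.
#' @export
effect_sizes <- function(data, response, variable,
                         covariates = c("age", "sex", "batch"),
                         reference = NULL, conf_level = 0.95,
                         sig_level = 0.01) {
  fit <- fit_lrt(data, response, variable, covariates, reference,
                 conf_level = conf_level)
  out <- fit$coefficients %>%
    mutate(significant = .data$p_value < sig_level)
  attr(out, "lrt") <- list(statistic = fit$lrt_statistic, df = fit$df,
                           p_raw = fit$p_raw, n_used = fit$n_used)
  out
}

#' Pairwise Wilcoxon rank-sum tests between groups
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of group levels
#' (exact for small tie-free samples, normal approximation with tie
#' correction otherwise, as decided by [stats::wilcox.test()]), with
#' Holm adjustment across the pairs by default.
#'
#' @param data Tibble with the response and grouping columns.
#' @param response Numeric response column name.
#' @param group Grouping column name.
#' @param adjust Multiple-comparison method passed to [stats::p.adjust()].
#' @return Tibble (group1, group2, n1, n2, p_raw, p_adjusted).
#' @export
pairwise_group_tests <- function(data, response, group, adjust = "holm") {
  y <- data[[response]]; g <- as.character(data[[group]])
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  counts <- table(g)
  empty <- setdiff(unique(g), names(counts)[counts > 0])
  if (length(empty)) warn("group(s) with zero observations excluded.")
  levs <- names(counts)[counts > 0]
  if (length(levs) < 2) abort_data("need at least 2 non-empty groups.")
  pairs <- combn(levs, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tibble(
      group1 = a, group2 = b,
      n1 = sum(g == a), n2 = sum(g == b),
      p_raw = suppressWarnings(
        wilcox.test(y[g == a], y[g == b], alternative = "two.sided")$p.value
      )
    )
  })
  out %>% mutate(p_adjusted = p.adjust(.data$p_raw, method = adjust))
}
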