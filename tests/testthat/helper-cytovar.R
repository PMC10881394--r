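# Shared fixtures and independent oracles used across test files.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

cyt13 <- c("CXCL5", "CSF2", "IFNg", "IL1b", "TNF", "IL2", "IL6", "IL8",
           "IL10", "IL12p70", "IL13", "IL17", "IL23")

empty_effects <- function() {
  tibble(variable = character(), level = character(),
         stimulation = character(), cytokine = character(),
         coefficient = numeric())
}
empty_mediation <- function() {
  tibble(variable = character(), level = character(), mediator = character(),
         kind = character(), stimulation = character(),
         cytokine = character(), a = numeric(), b = numeric(),
         direct = numeric())
}
empty_snps <- function() {
  tibble(id = character(), chrom = character(), position = numeric(),
         maf = numeric(), stimulation = character(), cytokine = character(),
         slope = numeric())
}
empty_cpgs <- function() {
  tibble(id = character(), chrom = character(), position = numeric(),
         baseline_beta = numeric(), packyear_effect = numeric(),
         quit_reversion = numeric(), sd = numeric())
}

# a small default cohort configuration for fast tests
small_config <- function(n_donors = 300, ...) {
  sim_config(n_donors = n_donors, n_extra_numeric = 3,
             n_extra_categorical = 3, n_extra_snps = 5, n_extra_cpgs = 3,
             ...)
}

# long cytokine tibble from a plain matrix of concentrations
as_cyt_long <- function(stim_mat, null_mat, stimulation = "stim",
                        cytokine = "cytA") {
  donors <- sprintf("D%03d", seq_along(stim_mat))
  bind_rows(
    tibble(donor = donors, stimulation = stimulation, cytokine = cytokine,
           concentration = as.numeric(stim_mat)),
    tibble(donor = donors, stimulation = "null", cytokine = cytokine,
           concentration = as.numeric(null_mat))
  )
}

# Benjamini-Yekutieli step-up, written out from the definition: order
# raw p ascending, multiply by m * c(m) / rank with the harmonic
# constant c(m) = sum(1/i), enforce monotonicity by a cumulative
# minimum from the largest rank down, cap at 1.
by_adjust_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  stepped <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Holm step-down from the definition.
holm_adjust_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- (m - seq_len(m) + 1) * p[o]
  adj <- pmin(cummax(stepped), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Gaussian LRT statistic via maximized log-likelihoods of the two
# models (independent of the RSS-ratio route used by the package).
lrt_loglik_oracle <- function(y, x_full_df, x_red_df) {
  fit_f <- lm(y ~ ., data = x_full_df)
  fit_r <- if (ncol(x_red_df) == 0) lm(y ~ 1) else lm(y ~ ., data = x_red_df)
  as.numeric(2 * (logLik(fit_f) - logLik(fit_r)))
}

# LMG shares by literal enumeration of all p! orderings.
lmg_bruteforce_oracle <- function(y, blocks) {
  p <- length(blocks)
  r2 <- function(cols) {
    if (is.null(cols)) return(0)
    X <- do.call(cbind, blocks[cols])
    fit <- lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(rest) c(v[i], rest))
    }))
  }
  shares <- numeric(p)
  all_orders <- perms(seq_len(p))
  for (ord in all_orders) {
    prev <- 0
    seen <- integer()
    for (k in ord) {
      seen <- c(seen, k)
      cur <- r2(seen)
      shares[k] <- shares[k] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(all_orders)
}

# two-locus genotypes with a set LD correlation, via haplotype draws
simulate_ld_pair <- function(n, p = 0.3, r = 0.8) {
  D <- r * sqrt(p * (1 - p) * p * (1 - p))
  f11 <- p * p + D
  haps <- matrix(0L, 2 * n, 2)
  u <- runif(2 * n)
  f10 <- p - f11; f01 <- p - f11
  a <- u < f11
  b <- u >= f11 & u < f11 + f10
  c3 <- u >= f11 + f10 & u < f11 + f10 + f01
  haps[a, ] <- 1L
  haps[b, 1] <- 1L
  haps[c3, 2] <- 1L
  dos_a <- haps[seq_len(n), 1] + haps[n + seq_len(n), 1]
  dos_b <- haps[seq_len(n), 2] + haps[n + seq_len(n), 2]
  tibble(donor = sprintf("D%04d", seq_len(n)), snpA = dos_a, snpB = dos_b)
}
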