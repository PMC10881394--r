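test_that("variable eligibility follows the 5%-of-donors-per-level rule", {
  n <- 200
  cov <- tibble(
    donor = sprintf("d%03d", 1:n),
    three_lv = rep(c("a", "b", "c"), times = c(180, 12, 8)),
    two_lv = rep(c("a", "b"), times = c(194, 6)),
    four_lv = rep(c("a", "b", "c", "d"), times = c(188, 4, 4, 4)),
    num = rnorm(n)
  )
  el <- eligible_variables(cov)
  get <- function(v) el$eligible[el$variable == v]
  expect_true(get("three_lv"))   # 2 of 3 levels >= 5%, need ceil(3/2) = 2
  expect_true(get("two_lv"))     # 1 of 2 levels >= 5%, need ceil(2/2) = 1
  expect_false(get("four_lv"))   # 1 of 4 levels >= 5%, need 2
  expect_true(get("num"))        # numeric always eligible
})

test_that("the LRT engine matches an independent log-likelihood computation", {
  d <- tibble(y = c(1, 2, 3, 4), x = c("g0", "g0", "g1", "g1"))
  fit <- fit_lrt(d, "y", "x", covariates = character())
  expect_equal(fit$lrt_statistic, 4 * log(5), tolerance = 1e-10)
  expect_identical(fit$df, 1L)
  expect_equal(fit$p_raw, pchisq(4 * log(5), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fit$rss_reduced, 5)
  expect_equal(fit$rss_full, 1)
  # oracle route: twice the difference in maximized Gaussian log-likelihoods
  oracle <- lrt_loglik_oracle(d$y, data.frame(x = d$x),
                              data.frame(row.names = 1:4))
  expect_equal(fit$lrt_statistic, oracle, tolerance = 1e-10)

  # with covariates, against the same oracle on fresh data
  set.seed(8)
  d2 <- tibble(y = rnorm(80), x = rnorm(80), age = runif(80, 20, 70),
               sex = sample(c("f", "m"), 80, TRUE))
  fit2 <- fit_lrt(d2, "y", "x", covariates = c("age", "sex"))
  oracle2 <- lrt_loglik_oracle(d2$y, data.frame(x = d2$x, age = d2$age,
                                                sex = d2$sex),
                               data.frame(age = d2$age, sex = d2$sex))
  expect_equal(fit2$lrt_statistic, oracle2, tolerance = 1e-10)
})

test_that("the LRT is invariant to shifting y and rescaling covariates", {
  set.seed(9)
  d <- tibble(y = rnorm(100), x = sample(c("a", "b"), 100, TRUE),
              age = runif(100, 20, 70))
  f0 <- fit_lrt(d, "y", "x", covariates = "age")
  f1 <- fit_lrt(d %>% mutate(y = y + 57), "y", "x", covariates = "age")
  f2 <- fit_lrt(d %>% mutate(age = (age - 45) / 10), "y", "x",
                covariates = "age")
  expect_equal(f0$lrt_statistic, f1$lrt_statistic, tolerance = 1e-9)
  expect_equal(f0$lrt_statistic, f2$lrt_statistic, tolerance = 1e-9)
})

test_that("degenerate designs raise informative errors", {
  d <- tibble(y = rnorm(10), x = rep("only", 10), z = rnorm(10))
  expect_error(fit_lrt(d, "y", "x", covariates = character()),
               class = "cytovar_insufficient_variation")
  d2 <- tibble(y = rnorm(10), x = rnorm(10)) %>% mutate(x2 = x)
  expect_error(fit_lrt(d2, "y", "x2", covariates = "x"),
               class = "cytovar_collinearity_error")
  expect_error(fit_lrt(tibble(y = rnorm(3), x = c("a", "b", "c"),
                              age = 1:3),
                       "y", "x", covariates = "age"))
})

test_that("LRT and coefficient t-test agree asymptotically for one added scalar", {
  set.seed(10)
  n <- 10000
  d <- tibble(y = rnorm(n) + 0.03 * rnorm(n), x = rnorm(n))
  d$y <- d$y + 0.03 * d$x
  fit <- fit_lrt(d, "y", "x", covariates = character())
  expect_equal(log(fit$p_raw), log(fit$coefficients$p_value[1]),
               tolerance = 1e-3)
})

test_that("Benjamini-Yekutieli adjustment matches the step-up oracle", {
  # worked example: equal adjusted values through the cumulative minimum
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BY"), rep(0.01 * 4 * (25 / 12), 4),
               tolerance = 1e-12)
  expect_equal(p.adjust(p, "BY"), by_adjust_oracle(p), tolerance = 1e-12)
  # single test: c(1) = 1, adjustment is the identity
  expect_equal(p.adjust(0.037, "BY"), 0.037)
  # randomized vectors of varying size against the oracle
  set.seed(11)
  for (m in c(3, 17, 100, 10000)) {
    pr <- runif(m)^2
    expect_equal(p.adjust(pr, "BY"), by_adjust_oracle(pr), tolerance = 1e-12)
  }
  # adjustment never decreases a p-value and is monotone in raw p
  pr <- runif(50)
  adj <- by_adjust_oracle(pr)
  expect_true(all(adj >= pr))
  expect_true(all(diff(adj[order(pr)]) >= -1e-15))
})

test_that("the screen tests eligible variables against induced cytokines with one BY family", {
  cfg <- small_config(n_donors = 250)
  b <- simulate_cohort(cfg, seed = 12)
  scr <- screen_associations(b$cytokines, b$covariates, "SEB", lloq = b$lloq)
  induced <- flag_induced(b$cytokines, lloq = b$lloq) %>%
    filter(stimulation == "SEB", induced)
  expect_identical(sort(unique(scr$results$cytokine)),
                   sort(induced$cytokine))
  # BY adjustment applied over exactly this family
  expect_equal(scr$results$p_adjusted, by_adjust_oracle(scr$results$p_raw),
               tolerance = 1e-12)
  expect_true(all(scr$results$lrt_statistic >= 0))
  expect_true(all(scr$results$df >= 1))
  expect_true(all(scr$results$p_adjusted >= scr$results$p_raw))
  # screening a stimulation with no induced cytokines yields an empty result
  no_ind <- flag_induced(b$cytokines, lloq = b$lloq) %>%
    mutate(induced = FALSE)
  expect_message(
    scr0 <- screen_associations(b$cytokines, b$covariates, "SEB",
                                induced = no_ind),
    "no induced"
  )
  expect_identical(nrow(scr0$results), 0L)
})

test_that("effect sizes recover a noiseless multiplicative effect exactly", {
  n <- 60
  d <- tibble(
    donor = sprintf("d%02d", 1:n),
    smoking_status = rep(c("never", "past", "current"), each = n / 3),
    age = seq(20, 69, length.out = n), y = 1
  ) %>%
    mutate(y = y + log(1.5) * (smoking_status == "current"))
  es <- effect_sizes(d, "y", "smoking_status", covariates = "age")
  cur <- es %>% filter(term == "smoking_statuscurrent")
  expect_equal(cur$exp_estimate, 1.5, tolerance = 1e-12)
  expect_equal(cur$conf_low, 1.5, tolerance = 1e-9)
  expect_equal(cur$conf_high, 1.5, tolerance = 1e-9)
  expect_true(cur$significant)
  pst <- es %>% filter(term == "smoking_statuspast")
  expect_equal(pst$exp_estimate, 1, tolerance = 1e-12)

  # swapping the reference level negates the log-scale contrast
  es2 <- effect_sizes(d, "y", "smoking_status", covariates = "age",
                      reference = "current")
  nev <- es2 %>% filter(term == "smoking_statusnever")
  expect_equal(log(nev$exp_estimate), -log(cur$exp_estimate),
               tolerance = 1e-12)
})

test_that("pairwise Wilcoxon tests are exact and Holm-adjusted", {
  d <- tibble(y = c(1, 2, 3, 4, 5, 6),
              g = rep(c("lo", "hi"), each = 3))
  pw <- pairwise_group_tests(d, "y", "g")
  # all 20 rank splits: only the observed extreme split on each side -> 2/20
  expect_equal(pw$p_raw, 0.1, tolerance = 1e-12)

  set.seed(13)
  d2 <- tibble(y = rnorm(60), g = rep(c("a", "b", "c"), each = 20)) %>%
    mutate(y = y + 0.9 * (g == "c"))
  pw2 <- pairwise_group_tests(d2, "y", "g")
  expect_identical(nrow(pw2), 3L)
  expect_equal(pw2$p_adjusted, holm_adjust_oracle(pw2$p_raw),
               tolerance = 1e-12)
  # identical groups are not distinguishable
  d3 <- tibble(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(pairwise_group_tests(d3, "y", "g")$p_raw, 1, tolerance = 0.01)
})

test_that("the age-interaction variant adds the interaction parameters to the test", {
  set.seed(14)
  n <- 300
  d <- tibble(y = rnorm(n), x = sample(c("a", "b"), n, TRUE),
              age = runif(n, 20, 70), sex = sample(c("f", "m"), n, TRUE),
              batch = sample(c("B1", "B2"), n, TRUE))
  f_main <- fit_lrt(d, "y", "x")
  f_int <- fit_lrt(d, "y", "x", age_interaction = TRUE)
  expect_identical(f_main$df, 1L)
  expect_identical(f_int$df, 2L)
  # oracle: joint test of x and x:age via log-likelihoods
  oracle <- local({
    full <- lm(y ~ x + age + x:age + sex + batch, data = d)
    red <- lm(y ~ age + sex + batch, data = d)
    as.numeric(2 * (logLik(full) - logLik(red)))
  })
  expect_equal(f_int$lrt_statistic, oracle, tolerance = 1e-9)
})
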