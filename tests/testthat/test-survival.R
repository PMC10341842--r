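# Kaplan-Meier, logrank, Cox PH, FDR and the normality gate.

test_that("the product-limit estimate matches hand-computed examples", {
  # all events at 1, 2, 3: S = 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_equal(km$median, 2)
  # censoring at 2: S(1) = 2/3, S(3) = 0
  km2 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km_surv_at(km2, c(0.5, 1, 2.5, 3)), c(1, 2/3, 2/3, 0))
  # all censored: flat at 1, median undefined
  km3 <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median))
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("KM curves are non-increasing with S(0) = 1 on random inputs", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    km <- km_estimate(rexp(n, 0.1), runif(n) < 0.7)
    expect_true(all(diff(c(1, km$surv)) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_equal(km_surv_at(km, 0), 1)
  }
})

test_that("the logrank test matches a hand tabulation and its degrees of freedom", {
  # duplicated data in two groups: no difference at all
  t0 <- c(1, 2, 3, 1, 2, 3); e0 <- rep(TRUE, 6)
  r0 <- logrank_test(rep(c("a", "b"), each = 3), t0, e0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # hand-tabulated O-E/V: group1 deaths at 1,2; group2 at 3,4
  # O1 = 2, E1 = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36
  # chi-square = (7/6)^2 / (17/36) = 49/17
  r1 <- logrank_test(c("g1", "g1", "g2", "g2"), c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(r1$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(r1$df, 1L)
  # three groups give 2 degrees of freedom
  set.seed(15)
  r2 <- logrank_test(rep(c("a", "b", "c"), each = 10), rexp(30),
                     rep(TRUE, 30))
  expect_equal(r2$df, 2L)
  expect_error(logrank_test(rep("a", 5), rexp(5), rep(TRUE, 5)), "two")
})

test_that("the Cox score test equals the logrank statistic for a binary covariate", {
  set.seed(16)
  for (i in 1:15) {
    n <- sample(30:80, 1)
    d <- data.frame(os_time = rexp(n, 0.1),     # continuous: no ties
                    os_event = runif(n) < 0.8,
                    g = sample(c(0, 1), n, replace = TRUE))
    if (length(unique(d$g)) < 2 || sum(d$os_event) == 0) next
    fit <- coxph_fit(d, "g")
    lr <- logrank_test(d$g, d$os_time, d$os_event)
    expect_equal(unname(fit$statistics["score_logrank"]), lr$statistic,
                 tolerance = 1e-8)
  }
})

test_that("a null covariate gives HR near 1 and non-significant tests", {
  set.seed(17)
  n <- 600
  d <- data.frame(os_time = rexp(n, 0.05), os_event = TRUE,
                  g = rep(c(0, 1), n / 2))
  fit <- coxph_fit(d, "g")
  expect_true(fit$converged)
  expect_true(abs(fit$coefficients$log_hr) < 0.2)
  expect_true(fit$coefficients$hr_lower < 1 && fit$coefficients$hr_upper > 1)
})

test_that("Cox recovers a known log hazard ratio across simulated cohorts", {
  set.seed(18)
  n_rep <- 200; n <- 300
  est <- numeric(n_rep); covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    g <- rep(c(0, 1), n / 2)
    t <- rexp(n, 0.05 * exp(log(2) * g))
    cens <- runif(n, 0, 60)
    d <- data.frame(os_time = pmin(t, cens), os_event = t <= cens, g = g)
    fit <- coxph_fit(d, "g")
    est[r] <- fit$coefficients$log_hr
    covered[r] <- fit$coefficients$hr_lower <= 2 &&
      2 <= fit$coefficients$hr_upper
  }
  expect_lt(abs(mean(est) - log(2)), 0.1)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("separation or non-convergence is flagged with no hazard ratios", {
  # perfectly separating covariate
  d <- data.frame(os_time = c(1, 2, 3, 10, 11, 12),
                  os_event = TRUE, g = c(1, 1, 1, 0, 0, 0))
  fit <- coxph_fit(d, "g")
  expect_false(fit$converged)
  expect_equal(nrow(fit$coefficients), 0L)
  expect_error(coxph_fit(transform(d, g = 1), "g"), "constant")
})

test_that("BH adjustment matches hand values and is order-invariant", {
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(c(1, 0.5, 1)), c(1, 1, 1))
  p <- c(0.001, 0.3, 0.04, 0.9, 0.02)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  perm <- sample(length(p))
  expect_equal(fdr_adjust(p[perm])[order(perm)], q)
  expect_error(fdr_adjust(1.2), "\\[0, 1\\]")
})

test_that("the Shapiro-Wilk gate routes to the right test family", {
  set.seed(19)
  normal <- rnorm(50)
  heavy <- c(0.1 * (1:20), 5, 40, 300)  # strongly right-skewed fixture
  expect_equal(normality_gate(normal, 2), "t_test")
  expect_equal(normality_gate(heavy, 2), "wilcoxon")
  expect_equal(normality_gate(normal, 3), "anova")
  expect_equal(normality_gate(heavy, 3), "kruskal_wallis")
  expect_error(normality_gate(c(1, 2), 2), "3 values")
  cmp <- compare_groups(heavy, rep(c("a", "b"), length.out = length(heavy)))
  expect_equal(cmp$test, "wilcoxon")
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})
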