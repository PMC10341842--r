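# Patient aggregation, TPS/burden categories, cohort summaries, Fisher's
# exact comparison and the burden density.

test_that("patient aggregation counts distinct genomic variants", {
  clinical <- data.frame(patient_id = c("P1", "P2"), stringsAsFactors = FALSE)
  mutations <- data.frame(
    patient_id = c("P1", "P1", "P1", "P1"),
    variant_id = c("v1", "v2", "v3", "v3"),  # v3 on two transcripts
    stringsAsFactors = FALSE)
  processing <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    is_processing = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  rec <- aggregate_patients(clinical, mutations, processing)
  expect_equal(rec$mutational_load, c(3L, 0L))
  expect_equal(rec$processing_count, c(2L, 0L))
  expect_equal(rec$burden_group, c("high", "none"))
  # a processing call with no matching mutation is a data error
  bad <- rbind(processing, data.frame(variant_id = "v9", is_processing = TRUE))
  expect_error(aggregate_patients(clinical, mutations, bad), "v9")
})

test_that("burden dichotomization follows the more-than-one rule", {
  expect_equal(dichotomize_burden(c(0, 1, 2, 5)),
               c("none", "low", "high", "high"))
  expect_equal(burden_two_level(c(0, 1, 2)), c("low_none", "low_none", "high"))
  # monotone in the count
  lv <- c(none = 0, low = 1, high = 2)
  x <- lv[dichotomize_burden(0:10)]
  expect_true(all(diff(x) >= 0))
  expect_error(dichotomize_burden(-1), "non-negative")
})

test_that("TPS categories use the <1 / 1-49 / >=50 cut-points", {
  expect_equal(tps_category(c(0, 0.9, 1, 49, 49.9, 50, 100)),
               c("negative", "negative", "low", "low", "low", "high", "high"))
  expect_equal(tps_category(NA), "unknown")
  expect_error(tps_category(101), "0, 100")
})

test_that("cohort summaries compute percentages against evaluable denominators", {
  rec <- data.frame(patient_id = sprintf("P%d", 1:8),
                    grp = c("a", "a", "a", "b", "b", NA, "unknown", "a"),
                    stringsAsFactors = FALSE)
  s <- cohort_summary(rec, "grp")
  expect_equal(s$denominator, c(6L, 6L))
  expect_equal(s$count[s$category == "a"], 4L)
  expect_equal(sum(s$count), unique(s$denominator))
  one <- cohort_summary(data.frame(patient_id = "P1", grp = "x"), "grp")
  expect_equal(one$percentage, 100)
  # count-table form with half-up rounding at the requested precision
  tab <- data.frame(variable = c("age", "tps"), category = c("gt60", "ge1"),
                    count = c(125L, 147L), denominator = 179L)
  s2 <- cohort_summary(tab)
  expect_equal(s2$percentage, c(69.8, 82.1))
})

test_that("the sample odds ratio is the cross-product and p comes from enumeration", {
  f1 <- fisher_or(matrix(c(5, 5, 5, 5), 2))
  expect_equal(f1$odds_ratio, 1)
  expect_equal(f1$p_value, 1)
  f2 <- fisher_or(matrix(c(10, 2, 5, 8), 2))  # [[10,5],[2,8]] row-wise
  expect_equal(f2$odds_ratio, (10 * 8) / (5 * 2))
  f3 <- fisher_or(matrix(c(1, 0, 0, 1), 2))
  expect_equal(f3$p_value, 1)  # both tables with these margins are equiprobable
  expect_equal(f3$odds_ratio, Inf)
  f4 <- fisher_or(matrix(c(1, 0, 0, 1), 2), haldane = TRUE)
  expect_equal(f4$odds_ratio, (1.5 * 1.5) / (0.5 * 0.5))
  und <- fisher_or(matrix(c(0, 0, 3, 4), 2))
  expect_false(und$or_defined)
})

test_that("enumeration p-values match fisher.test across random tables", {
  set.seed(12)
  for (i in 1:200) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    mine <- fisher_or(tab)
    ref <- fisher.test(tab)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    # conditional MLE agrees with the reference implementation
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      cm <- fisher_or(tab, or_method = "cmle")
      expect_equal(unname(cm$odds_ratio), unname(ref$estimate),
                   tolerance = 1e-2)
    }
  }
})

test_that("processing prevalence comparison builds the double-dichotomous table", {
  res <- compare_processing_prevalence(60, 145, 10, 48)
  expect_equal(res$odds_ratio, (60 * 38) / (85 * 10))
  expect_equal(res$p_value,
               fisher.test(matrix(c(60, 10, 85, 38), 2))$p.value,
               tolerance = 1e-9)
})

test_that("burden density reports frequencies, median and discrete modes", {
  d0 <- burden_density(rep(0, 10))
  expect_equal(d0$modes, 0)
  expect_equal(d0$median, 0)
  d1 <- burden_density(c(0, 0, 1, 1, 2, 2))
  expect_equal(d1$modes, c(0, 1, 2))  # tied maxima at 0, 1 and 2
  d2 <- burden_density(c(0, 1, 1, 1, 5))
  expect_equal(d2$median, 1)
  expect_true(1 %in% d2$modes)
  expect_false(0 %in% d2$modes)
  expect_equal(sum(d1$freq$n), 6L)
  expect_equal(sum(d1$freq$proportion), 1)
})

test_that("stage labels group into early (I-IIIA) and advanced (IIIB-IV)", {
  expect_equal(stage_group(c("IA1", "IIB", "IIIA", "IIIB", "IIIC", "IVA", "IVB")),
               c("early", "early", "early", "advanced", "advanced",
                 "advanced", "advanced"))
  expect_true(is.na(stage_group("unknown")))
})
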