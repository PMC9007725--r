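# Clinical value parsing, descriptive statistics, group tests, cohort
# summary on the packaged 21-patient table.

test_that("clinical values parse into numeric/censored/missing states", {
  p <- parse_clinical_value(c("22.5", "<1", "NA", "", "3", "1,200"))
  expect_equal(p$state, c("NUMERIC", "CENSORED_LT", "MISSING", "MISSING",
                          "NUMERIC", "NUMERIC"))
  expect_equal(p$value, c(22.5, 1, NA, NA, 3, 1200))
  expect_error(parse_clinical_value("abc", where = "ki67"), "ki67")
  expect_error(parse_clinical_value("<x"), "unparseable")
})

test_that("descriptive stats use standard median and n-1 SD", {
  p <- parse_clinical_value(c("1", "2", "3"))
  st <- descriptive_stats(p)
  expect_equal(st$median, 2)
  expect_equal(st$sample_sd, 1)
  # order invariance and agreement with a sort-based median oracle
  set.seed(6)
  vals <- round(runif(11, 0, 50), 1)
  p1 <- parse_clinical_value(as.character(vals))
  p2 <- parse_clinical_value(as.character(rev(vals)))
  s1 <- descriptive_stats(p1); s2 <- descriptive_stats(p2)
  expect_equal(s1, s2)
  srt <- sort(vals)
  expect_equal(s1$median, srt[(length(srt) + 1) / 2])
  expect_equal(s1$sample_sd^2,
               sum((vals - mean(vals))^2) / (length(vals) - 1),
               tolerance = 1e-12)
  # censoring policies
  pc <- parse_clinical_value(c("<1", "2", "4", "NA"))
  expect_equal(descriptive_stats(pc, "exclude")$n_used, 2)
  sub <- descriptive_stats(pc, "substitute")
  expect_equal(sub$n_used, 3)
  expect_equal(sub$median, 2)
  # nothing retained
  expect_equal(descriptive_stats(parse_clinical_value(c("NA", "NA")))$n_used,
               0)
})

test_that("cohort age statistics reproduce the printed values", {
  tab <- cohort_table1()
  gh <- parse_clinical_value(tab$age[tab$group == "GH"])
  nf <- parse_clinical_value(tab$age[tab$group == "NFPA"])
  s_gh <- descriptive_stats(gh)
  s_nf <- descriptive_stats(nf)
  expect_equal(s_gh$n_used, 10)
  expect_equal(s_gh$median, 47)
  expect_equal(round(s_gh$sample_sd, 2), 17.69)
  expect_equal(s_nf$n_used, 9)
  expect_equal(s_nf$median, 46)
  expect_equal(round(s_nf$sample_sd, 2), 13.94)
  expect_equal(round(compare_continuous(gh, nf)$p, 2), 0.36)
})

test_that("welch comparison matches a hand-computed 5v5 case", {
  a <- c(10, 12, 14, 16, 18)
  b <- c(11, 15, 19, 23, 27)
  pa <- parse_clinical_value(as.character(a))
  pb <- parse_clinical_value(as.character(b))
  se2 <- var(a) / 5 + var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(compare_continuous(pa, pb)$p, 2 * pt(-abs(t_hand), df_hand))
  # identical groups -> p = 1
  expect_equal(compare_continuous(pa, pa)$p, 1)
  expect_error(compare_continuous(parse_clinical_value("1"), pb), ">= 2")
})

test_that("yates chi-square follows the corrected formula", {
  # invasion counts: 2/11 GH vs 4/10 NFPA
  res <- compare_categorical(2, 9, 4, 6)
  expect_equal(round(res$p, 2), 0.53)
  chi_hand <- 21 * (abs(2 * 6 - 9 * 4) - 21 / 2)^2 / (11 * 10 * 6 * 15)
  expect_equal(res$chi_sq, chi_hand)
  # identical proportions: chi2 = 0, p = 1
  same <- compare_categorical(3, 6, 3, 6)
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p, 1)
  # correction floored at zero when |ad-bc| < n/2 (the sex table)
  sex <- compare_categorical(4, 7, 4, 6)
  expect_equal(sex$chi_sq, 0)
  expect_equal(sex$p, 1)
  # random tables: textbook formula, non-negative, never above uncorrected
  set.seed(14)
  for (i in 1:25) {
    cells <- sample(1:12, 4, replace = TRUE)
    res <- compare_categorical(cells[1], cells[2], cells[3], cells[4])
    n <- sum(cells)
    r1 <- cells[1] + cells[2]; r2 <- cells[3] + cells[4]
    c1 <- cells[1] + cells[3]; c2 <- cells[2] + cells[4]
    hand <- n * max(0, abs(cells[1] * cells[4] - cells[2] * cells[3]) -
                      n / 2)^2 / (r1 * r2 * c1 * c2)
    expect_equal(res$chi_sq, hand)
    uncorr <- n * (cells[1] * cells[4] - cells[2] * cells[3])^2 /
      (r1 * r2 * c1 * c2)
    expect_gte(res$chi_sq, 0)
    expect_lte(res$chi_sq, uncorr + 1e-12)
    # cross-check against stats::chisq.test where R applies the same
    # (unfloored) correction
    if (abs(cells[1] * cells[4] - cells[2] * cells[3]) >= n / 2) {
      ref <- suppressWarnings(
        chisq.test(matrix(cells, 2, byrow = TRUE), correct = TRUE))
      expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    }
  }
  expect_warning(z <- compare_categorical(0, 0, 3, 4), "zero margin")
  expect_equal(z$p, 1)
})

test_that("the packaged cohort summary reproduces the reference table", {
  cs <- cohort_summary(cohort_table1())
  get <- function(v, g, f) cs$stats[[f]][cs$stats$variable == v &
                                           cs$stats$group == g]
  expect_equal(get("age", "GH", "median"), 47)
  expect_equal(round(get("age", "GH", "sample_sd"), 2), 17.69)
  expect_equal(get("age", "NFPA", "median"), 46)
  expect_equal(round(get("age", "NFPA", "sample_sd"), 2), 13.94)
  # Ki-67 with "<1" excluded: printed medians/SDs
  expect_equal(get("ki67", "GH", "n_used"), 7)
  expect_equal(get("ki67", "GH", "median"), 2)
  expect_equal(round(get("ki67", "GH", "sample_sd"), 2), 1.81)
  expect_equal(get("ki67", "NFPA", "median"), 2)
  expect_equal(round(get("ki67", "NFPA", "sample_sd"), 2), 0.84)
  # surgeries (the reference prints SD 0.31; the n-1 recomputation from
  # the per-patient values gives 0.30)
  expect_equal(get("n_surgeries", "GH", "median"), 1)
  expect_equal(round(get("n_surgeries", "GH", "sample_sd"), 2), 0.30)
  # NFPA diameter median
  expect_equal(get("dmax", "NFPA", "median"), 30)
  # tests
  p_of <- function(v) cs$tests$p[cs$tests$variable == v]
  expect_equal(round(p_of("age"), 2), 0.36)
  expect_equal(round(p_of("cavernous_invasion"), 2), 0.53)
  # invasion fractions: 2/11 (18.2%) vs 4/10 (40%)
  inv <- cs$invasion
  expect_equal(inv$yes[inv$group == "GH"], 2)
  expect_equal(round(inv$pct[inv$group == "GH"], 1), 18.2)
  expect_equal(inv$yes[inv$group == "NFPA"], 4)
  expect_equal(inv$pct[inv$group == "NFPA"], 40)
  # p53 is summarised but not tested
  expect_false("p53" %in% cs$tests$variable)
})

test_that("null cohorts keep the per-test false-positive rate at nominal level", {
  # 10 seeds x 6 tests; under the null the per-test significance rate
  # should stay near 5% (<= 0.10 is the Binomial(60, 0.05) 95% bound,
  # and the Yates tests are conservative)
  n_sig <- 0L
  n_tests <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, missing_rate = 0)
    tab <- generate_cohort_table(cfg, effects = FALSE)
    cs <- suppressWarnings(cohort_summary(tab))
    n_sig <- n_sig + sum(cs$tests$p < 0.05, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(cs$tests$p))
  }
  expect_lte(n_sig / n_tests, 0.10)
})
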