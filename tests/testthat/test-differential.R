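# Group means, log2 fold enrichment, t-tests, Bonferroni, DMR calling.

test_that("group mean beta averages the group's samples", {
  ss <- toy_samplesheet(2, 3)
  betas <- matrix(c(0.2, 0.4, 0.1, 0.3, 0.5, 0.1, 0.2, 0.3, 0.4, 0.5),
                  nrow = 2, dimnames = list(c("r1", "r2"), ss$sample_id))
  m <- group_mean_beta(betas, ss, "GH")
  expect_equal(unname(m["r1"]), mean(betas["r1", 1:2]))
  expect_error(group_mean_beta(betas, ss, "ACTH"), "absent")
  # brute force over 10 random samples
  ss10 <- data.frame(sample_id = paste0("s", 1:10), group = "NFPA")
  b10 <- matrix(runif(30), 3, 10,
                dimnames = list(paste0("r", 1:3), ss10$sample_id))
  expect_equal(unname(group_mean_beta(b10, ss10, "NFPA")),
               unname(apply(b10, 1, function(x) sum(x) / 10)))
  # single sample: identity
  ss1 <- data.frame(sample_id = "s1", group = "GH")
  b1 <- matrix(0.42, 1, 1, dimnames = list("r1", "s1"))
  expect_equal(unname(group_mean_beta(b1, ss1, "GH")), 0.42)
})

test_that("log2 fold enrichment matches its closed form", {
  expect_equal(log2_fold_enrichment(0.8, 0.2, epsilon = 0), 2)
  expect_equal(log2_fold_enrichment(0.37, 0.37), 0)
  expect_equal(log2_fold_enrichment(0, 0.5, epsilon = 1e-6),
               log2(1e-6 / 0.500001))
  expect_equal(round(log2_fold_enrichment(0, 0.5, epsilon = 1e-6), 2),
               -18.93)
  expect_error(log2_fold_enrichment(1.2, 0.5), "\\[0, 1\\]")
})

test_that("region t-test agrees with stats::t.test in both variants", {
  set.seed(99)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -1, 1))
    w <- region_t_test(a, b, "welch")
    ref_w <- t.test(a, b)
    expect_equal(w$t_stat, unname(ref_w$statistic), tolerance = 1e-12)
    expect_equal(w$p_raw, ref_w$p.value, tolerance = 1e-12)
    s <- region_t_test(a, b, "student")
    ref_s <- t.test(a, b, var.equal = TRUE)
    expect_equal(s$t_stat, unname(ref_s$statistic), tolerance = 1e-12)
    expect_equal(s$p_raw, ref_s$p.value, tolerance = 1e-12)
  }
})

test_that("welch t on the cohort ages reproduces the printed p-value", {
  gh_ages <- c(22, 27, 28, 35, 46, 48, 57, 57, 63, 76)
  nfpa_ages <- c(36, 40, 42, 46, 46, 55, 68, 70, 72)
  res <- region_t_test(nfpa_ages, gh_ages, "welch")
  expect_equal(round(res$p_raw, 2), 0.36)
})

test_that("degenerate variances are handled as specified", {
  expect_equal(region_t_test(c(0.5, 0.5), c(0.5, 0.5)),
               list(t_stat = 0, p_raw = 1))
  expect_warning(res <- region_t_test(c(0.8, 0.8), c(0.2, 0.2)),
                 "degenerate")
  expect_equal(res$p_raw, 0)
  expect_error(region_t_test(0.5, c(0.1, 0.2)), "at least 2")
})

test_that("welch statistic matches the textbook formula on a 3v3 toy", {
  a <- c(0.1, 0.2, 0.6)
  b <- c(0.4, 0.5, 0.9)
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  res <- region_t_test(a, b)
  expect_equal(res$t_stat, t_hand)
  expect_equal(res$p_raw, 2 * pt(-abs(t_hand), df_hand))
})

test_that("bonferroni adjustment is min(1, m*p) and matches p.adjust", {
  expect_equal(bonferroni_adjust(0.001, m = 10), 0.01)
  expect_equal(bonferroni_adjust(0.01, m = 184841), 1)
  expect_equal(bonferroni_adjust(0), 0)
  set.seed(4)
  p <- runif(50)
  expect_equal(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
  # dominates raw p and is monotone
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_true(all(diff(bonferroni_adjust(p)[order(p)]) >= 0))
})

make_sim_betas <- function(seed, n_regions = 400, group_shift = 0,
                           dmr_fraction = 0, ...) {
  cfg <- sim_config(n_regions = n_regions, group_shift = group_shift,
                    dmr_fraction = dmr_fraction, seed = seed, ...)
  gm <- build_genome_model(cfg)
  reg <- generate_target_regions(gm, cfg)
  ss <- make_samplesheet(cfg)
  sim <- simulate_meth_counts(reg, gm, ss, cfg)
  list(betas = compute_beta(suppressMessages(
    filter_covered_regions(sim$counts, ss))), ss = ss, truth = sim$truth)
}

test_that("the dual significance gate and magnitude classes are enforced", {
  x <- make_sim_betas(31, dmr_fraction = 0.1)
  dmrs <- suppressMessages(call_dmrs(x$betas, x$ss))
  expect_equal(dmrs$significant,
               dmrs$p_adj <= 0.05 & abs(dmrs$lfc) > 0.5)
  expect_true(all(dmrs$p_adj >= dmrs$p_raw & dmrs$p_adj <= 1))
  # H/L partition the significant set
  expect_true(all(dmrs$magnitude_class[dmrs$significant] %in%
                    c("H_DMR", "L_DMR")))
  expect_true(all(dmrs$magnitude_class[!dmrs$significant] == "NONE"))
  expect_equal(dmrs$magnitude_class == "H_DMR",
               dmrs$significant & abs(dmrs$lfc) > 2)
  expect_true(all(dmrs$direction[dmrs$significant & dmrs$lfc > 0] ==
                    "NFPA_HYPER"))
  # sorted by p_adj then |lfc| descending
  expect_true(!is.unsorted(dmrs$p_adj))
  # p_adj respects m = number of tested regions
  expect_equal(attr(dmrs, "dmr_params")$m, nrow(x$betas))
  expect_equal(dmrs$p_adj, pmin(1, nrow(x$betas) * dmrs$p_raw))
})

test_that("magnitude classification follows the H/L thresholds", {
  cfg <- dmr_config()
  expect_equal(classify_magnitude(TRUE, 2.5, cfg), "H_DMR")
  expect_equal(classify_magnitude(TRUE, -2.5, cfg), "H_DMR")
  expect_equal(classify_magnitude(TRUE, 1.0, cfg), "L_DMR")
  expect_equal(classify_magnitude(TRUE, 2.0, cfg), "L_DMR")  # strict cut
  expect_equal(classify_magnitude(FALSE, 3.0, cfg), "NONE")
})

test_that("label swap negates lfc/t and preserves p and the called set", {
  x <- make_sim_betas(17, group_shift = 0.4)
  swapped <- x$ss
  swapped$group[swapped$group == "GH"] <- "tmp"
  swapped$group[swapped$group == "NFPA"] <- "GH"
  swapped$group[swapped$group == "tmp"] <- "NFPA"
  d1 <- suppressMessages(call_dmrs(x$betas, x$ss))
  d2 <- suppressMessages(call_dmrs(x$betas, swapped))
  d2 <- d2[match(d1$region_id, d2$region_id), ]
  expect_equal(d2$t_stat, -d1$t_stat)
  expect_equal(d2$p_raw, d1$p_raw)
  # lfc antisymmetry is exact only up to the epsilon pseudocount
  expect_equal(d2$lfc, -d1$lfc, tolerance = 1e-4)
  expect_equal(d2$significant, d1$significant)
})

test_that("sample order within groups does not matter", {
  x <- make_sim_betas(23, group_shift = 0.3, dmr_fraction = 0.05)
  perm <- x$ss[sample(nrow(x$ss)), ]
  d1 <- suppressMessages(call_dmrs(x$betas, x$ss))
  d2 <- suppressMessages(call_dmrs(x$betas, perm))
  expect_equal(d1, d2, ignore_attr = TRUE)
})

test_that("caller validates group sizes and NA-free betas", {
  betas <- matrix(runif(12), 3, 4,
                  dimnames = list(paste0("r", 1:3), paste0("s", 1:4)))
  ss_bad <- data.frame(sample_id = paste0("s", 1:4),
                       group = c("GH", "GH", "GH", "NFPA"))
  expect_error(call_dmrs(betas, ss_bad), "2 samples per tested group")
  ss_ok <- data.frame(sample_id = paste0("s", 1:4),
                      group = c("GH", "GH", "NFPA", "NFPA"))
  betas[1, 1] <- NA
  expect_error(call_dmrs(betas, ss_ok), "undefined betas")
})
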