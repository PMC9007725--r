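# The DMR caller: group mean betas, log2 fold enrichment, per-region
# t-tests, Bonferroni correction, dual significance gates and H/L
# magnitude classes.

#' Per-region group mean beta
#'
#' Arithmetic mean of the beta values over a group's samples, per region.
#' Undefined betas (NA, only possible before coverage filtering) are
#' excluded sample-wise.
#'
#' @param betas beta matrix (regions x samples).
#' @param samplesheet data.frame `sample_id`, `group`.
#' @param group group label to average.
#' @return named numeric vector, one mean per region.
#' @export
group_mean_beta <- function(betas, samplesheet, group) {
  check_samplesheet(samplesheet)
  if (!group %in% samplesheet$group)
    stopf("group '%s' absent from samplesheet", group)
  cols <- intersect(colnames(betas),
                    samplesheet$sample_id[samplesheet$group == group])
  if (!length(cols))
    stopf("no '%s' samples among beta matrix columns", group)
  rowMeans(betas[, cols, drop = FALSE], na.rm = TRUE)
}

#' Log2 fold enrichment of NFPA over GH mean methylation
#'
#' `log2((mean_nfpa + epsilon) / (mean_gh + epsilon))`; positive values
#' mean NFPA-hypermethylated. The symmetric pseudocount guards zero
#' means.
#'
#' @param mean_nfpa,mean_gh group mean betas in \[0, 1\] (vectorised).
#' @param epsilon pseudocount (default 1e-6).
#' @return numeric vector of log2 fold enrichments.
#' @export
log2_fold_enrichment <- function(mean_nfpa, mean_gh, epsilon = 1e-6) {
  if (any(mean_nfpa < 0 | mean_nfpa > 1 | mean_gh < 0 | mean_gh > 1,
          na.rm = TRUE))
    stopf("group mean betas must lie in [0, 1]")
  log2((mean_nfpa + epsilon) / (mean_gh + epsilon))
}

# Closed-form two-sample t statistics from per-group means/vars/sizes.
# Returns list(t, df, p). Degenerate (zero pooled standard error): equal
# means -> t = 0, p = 1; unequal -> p = 0 with +/-Inf t.
t_from_moments <- function(m1, v1, n1, m2, v2, n2, variant) {
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep_len(n1 + n2 - 2, length(se2))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen, na.rm = TRUE)) {
    eq <- degen & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1
    ne <- degen & (m1 != m2)
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf
    p[ne] <- 0
  }
  list(t = t, df = df, p = p)
}

#' Two-sample t-test on per-region betas
#'
#' Two-sided test of NFPA versus GH beta values for one region. The
#' Welch variant (default) uses unequal variances with
#' Welch-Satterthwaite degrees of freedom; the Student variant pools the
#' variance. The statistic is oriented NFPA minus GH, matching the sign
#' of the log2 fold enrichment.
#'
#' @param betas_nfpa,betas_gh numeric vectors, each of length >= 2.
#' @param variant `"welch"` or `"student"`.
#' @return list with `t_stat` and `p_raw`. When both groups are constant:
#'   equal values give t = 0, p = 1; different values give p = 0 with a
#'   degenerate-variance warning.
#' @export
region_t_test <- function(betas_nfpa, betas_gh,
                          variant = c("welch", "student")) {
  variant <- match.arg(variant)
  betas_nfpa <- betas_nfpa[!is.na(betas_nfpa)]
  betas_gh <- betas_gh[!is.na(betas_gh)]
  if (length(betas_nfpa) < 2 || length(betas_gh) < 2)
    stopf("each group needs at least 2 observations")
  res <- t_from_moments(mean(betas_nfpa), stats::var(betas_nfpa),
                        length(betas_nfpa),
                        mean(betas_gh), stats::var(betas_gh),
                        length(betas_gh), variant)
  if (is.infinite(res$t))
    warnf("degenerate variance: both groups constant with different values")
  list(t_stat = res$t, p_raw = res$p)
}

#' Bonferroni multiple-testing correction
#'
#' `p_adj = min(1, m * p)` where `m` defaults to the number of tests
#' supplied (the regions actually tested after coverage filtering).
#'
#' @param p_values vector of raw p-values in \[0, 1\].
#' @param m number of tests.
#' @return adjusted p-values, clamped at 1.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' Classify significant regions into H- and L-DMRs
#'
#' Significant regions with |log2 fold enrichment| strictly above
#' `config$h_cut` are H_DMR (high differentially methylated regions),
#' the remaining significant ones L_DMR; non-significant regions are
#' NONE. H and L partition the significant set.
#'
#' @param significant logical vector.
#' @param lfc log2 fold enrichments.
#' @param config a [dmr_config()] object.
#' @return character vector in \{`H_DMR`, `L_DMR`, `NONE`\}.
#' @export
classify_magnitude <- function(significant, lfc, config = dmr_config()) {
  stopifnot(inherits(config, "dmr_config"))
  ifelse(!significant, "NONE",
         ifelse(abs(lfc) > config$h_cut, "H_DMR", "L_DMR"))
}

#' Call differentially methylated regions
#'
#' Per region: NFPA and GH group mean betas, log2 fold enrichment (with
#' pseudocount `config$epsilon`), a two-sided t-test across samples,
#' Bonferroni adjustment over the tested regions, and the dual gate: a
#' region is significant iff `p_adj <= alpha` and `|lfc| > lfc_cut`
#' (strict). Significant regions split into H_DMR/L_DMR at
#' `|lfc| > h_cut`. Results are sorted by adjusted p, then |lfc|
#' decreasing, then region id.
#'
#' @param betas beta matrix (regions x samples), coverage-filtered so no
#'   NA remains among GH/NFPA samples.
#' @param samplesheet data.frame `sample_id`, `group`; both `GH` and
#'   `NFPA` need at least 2 samples in the matrix.
#' @param config a [dmr_config()] object.
#' @return data.frame with one row per region: `region_id`,
#'   `mean_beta_nfpa`, `mean_beta_gh`, `lfc`, `t_stat`, `p_raw`, `p_adj`,
#'   `significant`, `magnitude_class`, `direction`. The number of tests
#'   `m` and the thresholds are attached as attribute `dmr_params`.
#' @export
call_dmrs <- function(betas, samplesheet, config = dmr_config()) {
  stopifnot(is.matrix(betas), inherits(config, "dmr_config"))
  check_samplesheet(samplesheet)
  cols_n <- intersect(colnames(betas),
                      samplesheet$sample_id[samplesheet$group == "NFPA"])
  cols_g <- intersect(colnames(betas),
                      samplesheet$sample_id[samplesheet$group == "GH"])
  if (length(cols_n) < 2 || length(cols_g) < 2)
    stopf("need >= 2 samples per tested group; found %d NFPA, %d GH",
          length(cols_n), length(cols_g))
  bn <- betas[, cols_n, drop = FALSE]
  bg <- betas[, cols_g, drop = FALSE]
  if (anyNA(bn) || anyNA(bg))
    stopf("undefined betas among tested samples; apply filter_covered_regions first")
  m_n <- rowMeans(bn); m_g <- rowMeans(bg)
  lfc <- log2_fold_enrichment(m_n, m_g, config$epsilon)
  tt <- t_from_moments(m_n, row_vars(bn), length(cols_n),
                       m_g, row_vars(bg), length(cols_g),
                       config$test_variant)
  n_degen <- sum(is.infinite(tt$t))
  if (n_degen > 0)
    warnf("degenerate variance in %d region(s): both groups constant with different values",
          n_degen)
  m <- nrow(betas)
  p_adj <- bonferroni_adjust(tt$p, m)
  significant <- p_adj <= config$alpha & abs(lfc) > config$lfc_cut
  res <- data.frame(
    region_id = rownames(betas),
    mean_beta_nfpa = m_n, mean_beta_gh = m_g,
    lfc = lfc, t_stat = tt$t, p_raw = tt$p, p_adj = p_adj,
    significant = significant,
    magnitude_class = classify_magnitude(significant, lfc, config),
    direction = ifelse(!significant, "NONE",
                       ifelse(lfc > 0, "NFPA_HYPER", "NFPA_HYPO")),
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_adj, -abs(res$lfc), res$region_id), , drop = FALSE]
  rownames(res) <- NULL
  log_msg("call_dmrs: %d of %d regions significant (%d H_DMR, %d L_DMR) at alpha=%g, |lfc|>%g",
          sum(res$significant), m, sum(res$magnitude_class == "H_DMR"),
          sum(res$magnitude_class == "L_DMR"), config$alpha, config$lfc_cut)
  attr(res, "dmr_params") <- list(m = m, alpha = config$alpha,
                                  lfc_cut = config$lfc_cut,
                                  h_cut = config$h_cut,
                                  epsilon = config$epsilon,
                                  test_variant = config$test_variant)
  res
}
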