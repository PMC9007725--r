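#' CpG context labels
#'
#' The six CpG-centric contexts used throughout the package, in priority
#' order: island first, then shores (2 kb flanks), shelves (next 2 kb),
#' then open sea. `N_` denotes the lower-coordinate flank of an island,
#' `S_` the higher-coordinate flank, independent of strand.
#'
#' @export
CPG_CONTEXTS <- c("ISLAND", "N_SHORE", "S_SHORE", "N_SHELF", "S_SHELF",
                  "OPEN_SEA")

#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-data
#' generator. Defaults describe a desk-scale version of a targeted
#' methyl-capture experiment on two pituitary adenoma groups (GH-secreting
#' and nonfunctioning, NFPA) plus normal pituitaries: region geometry with
#' mean length 245 bp (range 2-8,131 bp), 11 GH / 10 NFPA / 5 normal
#' samples, context-dependent baseline methylation (islands low, open sea
#' high), a global NFPA hypermethylation shift on the logit scale, and a
#' fraction of regions carrying a planted differential effect of a given
#' log2 fold enrichment.
#'
#' @param n_regions number of target regions (desk-scale default 5000; the
#'   full-scale 437,792 is supported but flagged in the log).
#' @param region_length_mean,region_length_min,region_length_max region
#'   length distribution in bp: truncated log-normal with this mean and
#'   range.
#' @param n_gh,n_nfpa,n_normal samples per group.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_islands CpG islands placed on the genome.
#' @param island_length island length in bp.
#' @param island_spacing minimum gap between islands in bp; the default
#'   8 kb keeps shores and shelves of adjacent islands from colliding.
#' @param n_genes,noncoding_fraction gene models placed on the genome and
#'   the fraction of them without a CDS.
#' @param baseline_beta_by_context named vector of mean methylation
#'   fraction per CpG context.
#' @param region_jitter_sd sd of the per-region logit-scale jitter around
#'   the context baseline.
#' @param group_shift logit-scale hypermethylation shift applied to every
#'   NFPA region mean; the default 0.8 is logit(0.68) - logit(0.48), the
#'   gap between typical NFPA and GH global medians.
#' @param dmr_fraction proportion of regions with a planted effect.
#' @param planted_lfc target log2 fold enrichment (NFPA over GH group
#'   mean) of planted regions.
#' @param dmr_hyper_fraction proportion of planted regions that are
#'   NFPA-hypermethylated (the rest are hypomethylated).
#' @param coverage_mean,coverage_size negative-binomial mean and size for
#'   per-region per-sample total read counts.
#' @param overdispersion beta-binomial concentration (precision) of the
#'   per-sample methylation fraction around the region mean; smaller is
#'   noisier.
#' @param censor_rate,missing_rate rates of censored ("<1") Ki-67 entries
#'   and of missing values in simulated cohort tables.
#' @param seed integer seed recorded in the config and used by generator
#'   functions.
#'
#' @return a list of class `sim_config`, validated.
#' @export
sim_config <- function(n_regions = 5000,
                       region_length_mean = 245,
                       region_length_min = 2,
                       region_length_max = 8131,
                       n_gh = 11, n_nfpa = 10, n_normal = 5,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_islands = 150,
                       island_length = 500,
                       island_spacing = 8000,
                       n_genes = 100,
                       noncoding_fraction = 0.3,
                       baseline_beta_by_context = c(
                         ISLAND = 0.04, N_SHORE = 0.45, S_SHORE = 0.45,
                         N_SHELF = 0.58, S_SHELF = 0.58, OPEN_SEA = 0.55),
                       region_jitter_sd = 0.3,
                       group_shift = 0.8,
                       dmr_fraction = 0.05,
                       planted_lfc = 2,
                       dmr_hyper_fraction = 0.9,
                       coverage_mean = 100,
                       coverage_size = 10,
                       overdispersion = 20,
                       censor_rate = 0.2,
                       missing_rate = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_regions = assert_count(n_regions, "n_regions"),
    region_length_mean = assert_number(region_length_mean,
                                       "region_length_mean", lo = 1),
    region_length_min = assert_number(region_length_min,
                                      "region_length_min", lo = 1),
    region_length_max = assert_number(region_length_max,
                                      "region_length_max", lo = 1),
    n_gh = assert_count(n_gh, "n_gh"),
    n_nfpa = assert_count(n_nfpa, "n_nfpa"),
    n_normal = assert_count(n_normal, "n_normal", min = 0),
    chrom_lengths = chrom_lengths,
    n_islands = assert_count(n_islands, "n_islands", min = 0),
    island_length = assert_count(island_length, "island_length"),
    island_spacing = assert_count(island_spacing, "island_spacing", min = 0),
    n_genes = assert_count(n_genes, "n_genes", min = 0),
    noncoding_fraction = assert_number(noncoding_fraction,
                                       "noncoding_fraction", 0, 1),
    baseline_beta_by_context = baseline_beta_by_context,
    region_jitter_sd = assert_number(region_jitter_sd, "region_jitter_sd",
                                     lo = 0),
    group_shift = assert_number(group_shift, "group_shift"),
    dmr_fraction = assert_number(dmr_fraction, "dmr_fraction", 0, 1),
    planted_lfc = assert_number(planted_lfc, "planted_lfc"),
    dmr_hyper_fraction = assert_number(dmr_hyper_fraction,
                                       "dmr_hyper_fraction", 0, 1),
    coverage_mean = assert_number(coverage_mean, "coverage_mean"),
    coverage_size = assert_number(coverage_size, "coverage_size", lo = 0.01),
    overdispersion = assert_number(overdispersion, "overdispersion",
                                   lo = 0.01),
    censor_rate = assert_number(censor_rate, "censor_rate", 0, 1),
    missing_rate = assert_number(missing_rate, "missing_rate", 0, 1),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (cfg$coverage_mean <= 0)
    stopf("'coverage_mean' must be positive")
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == ""))
    stopf("'chrom_lengths' must be a named vector")
  if (any(cfg$chrom_lengths < 1))
    stopf("chromosome lengths must be positive")
  if (!(cfg$region_length_min <= cfg$region_length_mean &&
        cfg$region_length_mean <= cfg$region_length_max))
    stopf("need region_length_min <= region_length_mean <= region_length_max")
  miss <- setdiff(CPG_CONTEXTS, names(cfg$baseline_beta_by_context))
  if (length(miss))
    stopf("baseline_beta_by_context lacks contexts: %s",
          paste(miss, collapse = ", "))
  bb <- cfg$baseline_beta_by_context
  if (any(bb <= 0 | bb >= 1))
    stopf("baseline betas must lie strictly in (0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' DMR-calling configuration
#'
#' Thresholds for the differential methylation caller. A region is a DMR
#' when its Bonferroni-adjusted P value is at most `alpha` and the
#' absolute log2 fold enrichment of the NFPA over the GH group mean beta
#' exceeds `lfc_cut` (strictly). Significant regions with |lfc| strictly
#' above `h_cut` are high-magnitude DMRs (H-DMRs), the remaining
#' significant ones low-magnitude (L-DMRs).
#'
#' @param alpha familywise significance level on adjusted P values.
#' @param lfc_cut absolute log2 fold-enrichment gate for significance.
#' @param h_cut absolute log2 fold-enrichment split between H- and L-DMRs.
#' @param epsilon pseudocount added symmetrically to both group means
#'   before the ratio, guarding zero means.
#' @param test_variant `"welch"` (unequal variances, default) or
#'   `"student"` (pooled variance).
#'
#' @return a list of class `dmr_config`.
#' @export
dmr_config <- function(alpha = 0.05, lfc_cut = 0.5, h_cut = 2,
                       epsilon = 1e-6, test_variant = c("welch", "student")) {
  test_variant <- match.arg(test_variant)
  assert_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  assert_number(lfc_cut, "lfc_cut", lo = 1e-12)
  assert_number(h_cut, "h_cut")
  assert_number(epsilon, "epsilon", lo = 0)
  if (!(lfc_cut < h_cut)) stopf("need 0 < lfc_cut < h_cut")
  structure(list(alpha = alpha, lfc_cut = lfc_cut, h_cut = h_cut,
                 epsilon = epsilon, test_variant = test_variant),
            class = "dmr_config")
}
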