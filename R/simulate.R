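# Beta-binomial methylome simulator with planted differential effects,
# and cohort-table generation.

#' Simulate region-level methylation counts
#'
#' For every region and sample, draws a total read count from a negative
#' binomial with mean `coverage_mean`, then a methylated count from a
#' beta-binomial around the region's group mean. Region means are the
#' CpG-context baseline (islands low, open sea high) jittered on the
#' logit scale. NFPA samples receive a global logit-scale
#' hypermethylation shift (`group_shift`); a `dmr_fraction` of regions
#' additionally carries a planted effect sized so that the NFPA/GH mean
#' ratio is `2^planted_lfc` (clamped into (0.005, 0.995) before the
#' shift). Normal-pituitary samples are generated at baseline and are
#' excluded from differential testing by default.
#'
#' @param regions data.frame of target regions
#'   (`chrom`, `start`, `end`, `region_id`).
#' @param genome a [build_genome_model()] result (supplies CpG islands
#'   for context assignment).
#' @param samplesheet data.frame `sample_id`, `group`; every sample must
#'   carry a group label.
#' @param config a [sim_config()] object.
#' @return list with elements `counts` (a [meth_counts()] object) and
#'   `truth` (data.frame `region_id`, `is_planted_dmr`, `true_lfc`,
#'   `direction` in \{`NFPA_HYPER`, `NFPA_HYPO`, `NONE`\}, plus the
#'   generating means `mu_gh`, `mu_nfpa` and the CpG `context`).
#' @export
simulate_meth_counts <- function(regions, genome, samplesheet, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  check_samplesheet(samplesheet)
  if (anyNA(samplesheet$group) || any(samplesheet$group == ""))
    stopf("every sample in the samplesheet needs a group label")
  if (config$coverage_mean <= 0) stopf("'coverage_mean' must be positive")
  n <- nrow(regions)
  cmap <- build_context_map(genome$islands,
                            stats::setNames(genome$chromosomes$length,
                                            genome$chromosomes$name))
  context <- annotate_cpg_context(regions, cmap)
  base <- config$baseline_beta_by_context[context]

  with_seed(config$seed + 303L, {
    mu_gh <- inv_logit(logit(base) +
                         stats::rnorm(n, 0, config$region_jitter_sd))
    n_planted <- round(config$dmr_fraction * n)
    planted <- logical(n)
    sgn <- numeric(n)
    if (n_planted > 0) {
      idx <- sample.int(n, n_planted)
      planted[idx] <- TRUE
      sgn[idx] <- ifelse(
        stats::runif(n_planted) < config$dmr_hyper_fraction, 1, -1)
    }
    target <- mu_gh
    target[planted] <- clamp(
      mu_gh[planted] * 2^(sgn[planted] * abs(config$planted_lfc)),
      0.005, 0.995)
    mu_nfpa <- inv_logit(logit(target) + config$group_shift)
    mu_norm <- base

    bad <- setdiff(unique(samplesheet$group), c("GH", "NFPA", "NORMAL"))
    if (length(bad))
      stopf("unknown sample group(s): %s", paste(bad, collapse = ", "))
    mu_by_group <- list(GH = mu_gh, NFPA = mu_nfpa, NORMAL = mu_norm)
    s <- nrow(samplesheet)
    mu_mat <- vapply(samplesheet$group,
                     function(g) mu_by_group[[g]], numeric(n))
    theta <- config$overdispersion
    total <- matrix(stats::rnbinom(n * s, mu = config$coverage_mean,
                                   size = config$coverage_size),
                    nrow = n, ncol = s)
    p <- matrix(stats::rbeta(n * s, mu_mat * theta, (1 - mu_mat) * theta),
                nrow = n, ncol = s)
    meth <- matrix(stats::rbinom(n * s, size = total, prob = p),
                   nrow = n, ncol = s)
    dimnames(meth) <- dimnames(total) <-
      list(regions$region_id, samplesheet$sample_id)

    truth <- data.frame(
      region_id = regions$region_id,
      is_planted_dmr = planted,
      true_lfc = ifelse(planted, log2(mu_nfpa / mu_gh), 0),
      direction = ifelse(!planted, "NONE",
                         ifelse(mu_nfpa > mu_gh, "NFPA_HYPER", "NFPA_HYPO")),
      mu_gh = mu_gh, mu_nfpa = mu_nfpa, context = context,
      stringsAsFactors = FALSE)
    list(counts = meth_counts(meth, total), truth = truth)
  })
}

#' Simulate cytosine-level counts under known region means
#'
#' Explodes each region into individual cytosines and draws per-cytosine
#' methylated/total counts from the region's per-sample methylation mean,
#' so that collapsing back to regions recovers the means within binomial
#' error. Used to exercise the quantification stage.
#'
#' @param regions data.frame of target regions.
#' @param mu numeric matrix of methylation means, regions x samples, with
#'   dimnames.
#' @param config a [sim_config()] object (`coverage_mean`/`coverage_size`
#'   give the per-cytosine depth distribution; `seed` fixes the draw).
#' @param cytosines_per_region integer; default one per 50 bp, at least
#'   one.
#' @return long data.frame `chrom`, `pos`, `sample_id`, `meth`, `total`
#'   (0-based positions).
#' @export
simulate_cytosine_counts <- function(regions, mu, config,
                                     cytosines_per_region = NULL) {
  stopifnot(is.matrix(mu), nrow(mu) == nrow(regions))
  with_seed(config$seed + 404L, {
    k <- cytosines_per_region %||%
      pmax(1L, round((regions$end - regions$start) / 50))
    k <- pmin(rep_len(k, nrow(regions)), regions$end - regions$start)
    off <- unlist(lapply(seq_len(nrow(regions)), function(i) {
      len <- regions$end[i] - regions$start[i]
      sort(sample.int(len, k[i]) - 1L)
    }))
    ridx <- rep.int(seq_len(nrow(regions)), k)
    pos <- regions$start[ridx] + off
    nc <- length(pos)
    samples <- colnames(mu)
    out <- vector("list", length(samples))
    for (j in seq_along(samples)) {
      tot <- stats::rnbinom(nc, mu = config$coverage_mean,
                            size = config$coverage_size)
      met <- stats::rbinom(nc, size = tot, prob = mu[ridx, j])
      out[[j]] <- data.frame(chrom = regions$chrom[ridx], pos = pos,
                             sample_id = samples[j], meth = met,
                             total = tot, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate a clinical cohort table
#'
#' Either simulates a per-patient clinical table with the schema of a
#' pituitary-adenoma surgical cohort (sex, age, micro/macro, maximum
#' diameter, cavernous sinus invasion, Ki-67 with censored "<1" entries,
#' p53, number of surgeries) or, with `mode = "table1"`, returns the
#' packaged 21-patient reference cohort verbatim.
#'
#' All value columns are character so that censored (`"<1"`) and missing
#' (`"NA"`) entries survive round-trips; parse with
#' [parse_clinical_value()] / summarise with [cohort_summary()].
#'
#' @param config a [sim_config()] object (`n_gh`/`n_nfpa` group sizes,
#'   `censor_rate` for Ki-67, `missing_rate`, `seed`).
#' @param mode `"simulate"` (default) or `"table1"` for the packaged
#'   fixture.
#' @param effects with the default `TRUE`, NFPAs are simulated larger
#'   (maximum diameter) and more invasive than GH-omas, as in surgical
#'   cohorts; `FALSE` draws both groups from identical distributions
#'   (null cohort).
#' @return data.frame with columns `id`, `group`, `sex`,
#'   `high_risk_area`, `age`, `macro`, `dmax_mm`, `cavernous_invasion`,
#'   `ki67_pct`, `p53_pct`, `n_surgeries`, `aip_mutation`.
#' @export
generate_cohort_table <- function(config, mode = c("simulate", "table1"),
                                  effects = TRUE) {
  mode <- match.arg(mode)
  if (mode == "table1") return(cohort_table1())
  stopifnot(inherits(config, "sim_config"))
  n_gh <- config$n_gh
  n_nf <- config$n_nfpa
  n <- n_gh + n_nf
  group <- c(rep("GH", n_gh), rep("NFPA", n_nf))
  with_seed(config$seed + 505L, {
    age <- round(clamp(stats::rnorm(n, 50, 15), 18, 85))
    sex <- ifelse(stats::runif(n) < 0.4, "M", "F")
    hra <- ifelse(stats::runif(n) < 0.15, "Yes", "No")
    macro <- stats::runif(n) < 0.9
    # NFPAs present larger: typical max diameters ~27 vs ~16 mm
    dmax <- round(stats::rlnorm(n, meanlog = if (effects)
      ifelse(group == "GH", log(16), log(27)) else log(16),
      sdlog = 0.35), 1)
    dmax[!macro] <- round(stats::runif(sum(!macro), 3, 9), 1)
    inv_p <- if (effects) ifelse(group == "GH", 0.18, 0.40) else 0.18
    invasion <- ifelse(stats::runif(n) < inv_p, "Yes", "No")
    ki_raw <- sample(1:5, n, replace = TRUE,
                     prob = c(0.35, 0.3, 0.15, 0.1, 0.1))
    ki <- ifelse(stats::runif(n) < config$censor_rate, "<1",
                 as.character(ki_raw))
    p53 <- as.character(sample(0:3, n, replace = TRUE,
                               prob = c(0.5, 0.25, 0.15, 0.1)))
    surg <- as.character(sample(1:3, n, replace = TRUE,
                                prob = c(0.85, 0.1, 0.05)))
    aip <- ifelse(stats::runif(n) < 0.05, "Yes", "No")
    tab <- data.frame(
      id = c(sprintf("GH%d", seq_len(n_gh)),
             sprintf("NFPA%d", seq_len(n_nf))),
      group = group, sex = sex, high_risk_area = hra,
      age = as.character(age),
      macro = ifelse(macro, "Macro", "Micro"),
      dmax_mm = as.character(dmax),
      cavernous_invasion = invasion,
      ki67_pct = ki, p53_pct = p53, n_surgeries = surg,
      aip_mutation = aip, stringsAsFactors = FALSE)
    if (config$missing_rate > 0) {
      for (col in c("age", "dmax_mm", "ki67_pct", "p53_pct")) {
        hit <- stats::runif(n) < config$missing_rate
        tab[[col]][hit] <- "NA"
      }
    }
    tab
  })
}

#' The packaged 21-patient reference cohort
#'
#' Loads the literal demographic/radiological/clinicopathological table
#' of the 11 GH-oma + 10 NFPA surgical cohort shipped with the package
#' (`inst/extdata/table1_cohort.csv`): the worked example for
#' [cohort_summary()].
#'
#' @return data.frame with the [generate_cohort_table()] column contract.
#' @export
cohort_table1 <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "methdmr",
                      mustWork = TRUE)
  read_cohort(path)
}
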