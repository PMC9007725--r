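# Distribution contrasts between sample groups: global, per CpG
# context, and per DMR stratum, via two-sided Mann-Whitney tests.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The U statistic for the first sample is
#' computed from midranks; the p-value uses the exact distribution when
#' `n_a * n_b <= 400` and there are no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @return list with `u_stat` (U for `values_a`) and `p`.
#' @export
mann_whitney_u <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a == 0 || n_b == 0) stopf("both samples must be non-empty")
  r <- rank(c(values_a, values_b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- n_a * n_b <= 400 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact,
                       correct = TRUE)$p.value)
  list(u_stat = u_a, p = min(1, p))
}

comparison_row <- function(stratum, x_nfpa, x_gh) {
  mw <- mann_whitney_u(x_nfpa, x_gh)
  data.frame(stratum = stratum,
             median_nfpa = stats::median(x_nfpa),
             median_gh = stats::median(x_gh),
             u_stat = mw$u_stat, p = mw$p,
             n_nfpa = length(x_nfpa), n_gh = length(x_gh),
             stringsAsFactors = FALSE)
}

pool_group_betas <- function(betas, samplesheet, group) {
  cols <- intersect(colnames(betas),
                    samplesheet$sample_id[samplesheet$group == group])
  if (!length(cols)) stopf("no '%s' samples in beta matrix", group)
  v <- as.vector(betas[, cols, drop = FALSE])
  v[!is.na(v)]
}

#' Global methylation contrast between NFPA and GH samples
#'
#' Pools every defined per-region per-sample beta within each group and
#' compares the two pooled distributions (medians plus Mann-Whitney p).
#'
#' @param betas beta matrix (regions x samples).
#' @param samplesheet data.frame `sample_id`, `group`.
#' @return one-row data.frame: `stratum` (`GLOBAL`), `median_nfpa`,
#'   `median_gh`, `u_stat`, `p`, `n_nfpa`, `n_gh`.
#' @export
compare_global <- function(betas, samplesheet) {
  check_samplesheet(samplesheet)
  comparison_row("GLOBAL",
                 pool_group_betas(betas, samplesheet, "NFPA"),
                 pool_group_betas(betas, samplesheet, "GH"))
}

#' Methylation contrast stratified by CpG context
#'
#' One [compare_global()]-style comparison per CpG context, pooling the
#' betas of the regions annotated with that context. Contexts without
#' regions are omitted with a warning.
#'
#' @param betas beta matrix.
#' @param samplesheet data.frame `sample_id`, `group`.
#' @param contexts character vector of CpG contexts, one per row of
#'   `betas`.
#' @return data.frame with one row per populated context.
#' @export
compare_by_context <- function(betas, samplesheet, contexts) {
  stopifnot(length(contexts) == nrow(betas))
  check_samplesheet(samplesheet)
  missing_ctx <- setdiff(CPG_CONTEXTS, unique(contexts))
  if (length(missing_ctx))
    warnf("compare_by_context: no regions in context(s) %s; omitted",
          paste(missing_ctx, collapse = ", "))
  out <- lapply(intersect(CPG_CONTEXTS, unique(contexts)), function(ctx) {
    sub <- betas[contexts == ctx, , drop = FALSE]
    comparison_row(ctx,
                   pool_group_betas(sub, samplesheet, "NFPA"),
                   pool_group_betas(sub, samplesheet, "GH"))
  })
  do.call(rbind, out)
}

#' Methylation contrast across DMR strata
#'
#' Restricted to a set of DMR records, compares the per-region NFPA and
#' GH group mean betas within each stratum (e.g. coding/noncoding or CpG
#' context). Empty strata are skipped with a warning.
#'
#' @param dmrs data.frame of DMR records ([call_dmrs()] output rows,
#'   typically the significant subset), with `mean_beta_nfpa` and
#'   `mean_beta_gh` columns.
#' @param stratifier character vector of stratum labels, one per row of
#'   `dmrs`.
#' @return data.frame with one row per populated stratum.
#' @export
compare_dmr_strata <- function(dmrs, stratifier) {
  if (!nrow(dmrs)) stopf("no DMR records supplied")
  stopifnot(length(stratifier) == nrow(dmrs))
  out <- lapply(unique(stratifier), function(s) {
    idx <- which(stratifier == s)
    if (!length(idx)) {
      warnf("compare_dmr_strata: empty stratum '%s' skipped", s)
      return(NULL)
    }
    comparison_row(s, dmrs$mean_beta_nfpa[idx], dmrs$mean_beta_gh[idx])
  })
  do.call(rbind, out)
}
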