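# Region-level quantification: collapse cytosine counts to regions,
# beta values, all-sample coverage filter.

check_samplesheet <- function(samplesheet) {
  if (!is.data.frame(samplesheet) ||
      !all(c("sample_id", "group") %in% names(samplesheet)))
    stopf("samplesheet needs columns 'sample_id' and 'group'")
  if (anyDuplicated(samplesheet$sample_id))
    stopf("duplicate sample_id in samplesheet")
  invisible(samplesheet)
}

check_regions <- function(regions, require_disjoint = TRUE) {
  need <- c("chrom", "start", "end", "region_id")
  if (!is.data.frame(regions) || !all(need %in% names(regions)))
    stopf("regions need columns %s", paste(need, collapse = ", "))
  if (any(regions$end <= regions$start))
    stopf("empty or inverted region interval (end <= start)")
  if (any(regions$start < 0)) stopf("negative region start")
  if (anyDuplicated(regions$region_id)) stopf("duplicate region_id")
  if (require_disjoint) {
    ord <- order(regions$chrom, regions$start, regions$end)
    r <- regions[ord, ]
    same <- r$chrom[-1] == r$chrom[-nrow(r)]
    if (nrow(r) > 1 && any(same & r$start[-1] < r$end[-nrow(r)]))
      stopf("regions overlap; pass allow_overlaps = TRUE to permit this")
  }
  invisible(regions)
}

#' Collapse cytosine-level counts to target regions
#'
#' Sums methylated and total read counts of all cytosines falling inside
#' each target region (0-based half-open: a cytosine at position `p`
#' belongs to `[start, end)` iff `start <= p < end`), per sample.
#' Regions without any cytosine get (0, 0). Cytosines on chromosomes not
#' present in the region set are skipped with a warning reporting how
#' many were dropped.
#'
#' @param cytosines data.frame `chrom`, `pos`, `sample_id`, `meth`,
#'   `total` (one row per cytosine and sample).
#' @param regions data.frame of target regions; must be non-overlapping
#'   unless `allow_overlaps = TRUE`, in which case a cytosine contributes
#'   to every region containing it.
#' @param allow_overlaps permit overlapping regions.
#' @return a [meth_counts()] object, rows in the order of `regions`,
#'   columns the sorted unique sample ids.
#' @export
collapse_to_regions <- function(cytosines, regions, allow_overlaps = FALSE) {
  need <- c("chrom", "pos", "sample_id", "meth", "total")
  if (!all(need %in% names(cytosines)))
    stopf("cytosines need columns %s", paste(need, collapse = ", "))
  if (any(cytosines$meth < 0 | cytosines$total < 0 |
          cytosines$meth > cytosines$total))
    stopf("cytosine counts violate 0 <= meth <= total")
  check_regions(regions, require_disjoint = !allow_overlaps)

  samples <- sort(unique(cytosines$sample_id))
  n <- nrow(regions)
  s <- length(samples)
  meth <- total <- matrix(0, n, s,
                          dimnames = list(regions$region_id, samples))

  unknown <- !(cytosines$chrom %in% regions$chrom)
  if (any(unknown)) {
    warnf("collapse_to_regions: skipped %d cytosine records on chromosomes absent from the region set",
          sum(unknown))
    cytosines <- cytosines[!unknown, , drop = FALSE]
  }
  if (nrow(cytosines) == 0) return(meth_counts(meth, total))
  jj <- match(cytosines$sample_id, samples)

  if (!allow_overlaps) {
    ii <- rep(NA_integer_, nrow(cytosines))
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      ord <- ri[order(regions$start[ri])]
      ci <- which(cytosines$chrom == ch)
      if (!length(ci)) next
      slot <- findInterval(cytosines$pos[ci], regions$start[ord])
      hit <- slot >= 1 & cytosines$pos[ci] < regions$end[ord][pmax(slot, 1)]
      ii[ci[hit]] <- ord[slot[hit]]
    }
    keep <- !is.na(ii)
    acc <- rowsum(cbind(cytosines$meth[keep], cytosines$total[keep]),
                  group = (jj[keep] - 1) * n + ii[keep])
    lin <- as.integer(rownames(acc))
    meth[lin] <- acc[, 1]
    total[lin] <- acc[, 2]
  } else {
    for (r in seq_len(n)) {
      inr <- cytosines$chrom == regions$chrom[r] &
        cytosines$pos >= regions$start[r] & cytosines$pos < regions$end[r]
      if (!any(inr)) next
      acc <- rowsum(cbind(cytosines$meth[inr], cytosines$total[inr]),
                    group = jj[inr])
      cols <- as.integer(rownames(acc))
      meth[r, cols] <- acc[, 1]
      total[r, cols] <- acc[, 2]
    }
  }
  meth_counts(meth, total)
}

#' Compute methylation fractions (beta values)
#'
#' beta = methylated / total aligned reads per region and sample, ranging
#' 0 (unmethylated) to 1 (fully methylated). Cells with zero total
#' coverage are undefined and returned as `NA`, never 0.
#'
#' @param counts a [meth_counts()] object.
#' @return numeric matrix of betas with the counts' dimnames.
#' @export
compute_beta <- function(counts) {
  stopifnot(inherits(counts, "meth_counts"))
  beta <- counts$meth / counts$total
  beta[counts$total == 0] <- NA_real_
  beta
}

#' Keep regions covered in every sample of the tested groups
#'
#' Retains exactly the regions whose total read count is at least
#' `min_total` in every sample belonging to the named groups (the
#' all-sample coverage rule used before differential testing). Region
#' order is preserved; retained/discarded counts are logged.
#'
#' @param counts a [meth_counts()] object.
#' @param samplesheet data.frame `sample_id`, `group`.
#' @param groups group labels whose samples must all be covered
#'   (default the two tumour groups).
#' @param min_total minimum total reads defining "covered" (default 1).
#' @return the filtered [meth_counts()] object.
#' @export
filter_covered_regions <- function(counts, samplesheet,
                                   groups = c("GH", "NFPA"),
                                   min_total = 1) {
  stopifnot(inherits(counts, "meth_counts"))
  check_samplesheet(samplesheet)
  assert_count(min_total, "min_total")
  bad <- setdiff(groups, unique(samplesheet$group))
  if (length(bad))
    stopf("groups absent from samplesheet: %s", paste(bad, collapse = ", "))
  want <- samplesheet$sample_id[samplesheet$group %in% groups]
  cols <- intersect(colnames(counts$total), want)
  if (!length(cols))
    stopf("no samples of groups [%s] found among count matrix columns",
          paste(groups, collapse = ", "))
  keep <- rowSums(counts$total[, cols, drop = FALSE] >= min_total) ==
    length(cols)
  log_msg("filter_covered_regions: retained %d of %d regions (discarded %d) at min_total=%d in %d samples",
          sum(keep), length(keep), sum(!keep), min_total, length(cols))
  counts[keep, ]
}
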