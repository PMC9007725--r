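# Fixture builders used across test files. All randomized fixtures take
# an explicit seed.

`%||%` <- function(x, y) if (is.null(x)) y else x

# islands with arbitrary (possibly < 8 kb) gaps to exercise flank
# collisions; non-overlapping and sorted
rand_islands <- function(n, L, seed, len_range = c(200, 800)) {
  set.seed(seed)
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  for (. in 1:50) {
    start <- sort(sample.int(L - max(len), n))
    ok <- n < 2 || all(start[-1] > (start + len)[-n])
    if (ok) break
  }
  keep <- c(TRUE, if (n > 1) start[-1] > (start + len)[-n])
  data.frame(chrom = "chrT", start = start[keep], end = (start + len)[keep],
             stringsAsFactors = FALSE)
}

# regions that may overlap each other (annotation does not require
# disjointness)
rand_regions <- function(n, L, seed, max_len = 500) {
  set.seed(seed)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(L - l, 1), 0L)
  data.frame(chrom = "chrT", start = start, end = start + len,
             region_id = sprintf("r%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# hand-rolled gene models (mix of coding and noncoding, both strands)
rand_genes <- function(n, L, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(g) {
    len <- sample(3000:15000, 1)
    start <- sample.int(L - len, 1)
    n_ex <- sample(2:5, 1)
    bp <- sort(sample.int(len - 1, 2 * n_ex - 2))
    ex_s <- start + c(0, bp[seq(2, length(bp), by = 2)])
    ex_e <- start + c(bp[seq(1, length(bp), by = 2)], len)
    coding <- runif(1) > 0.3
    if (coding) {
      i <- sample.int(n_ex, 1); j <- sample(i:n_ex, 1)
      ts <- ex_s[i] + sample.int(ex_e[i] - ex_s[i], 1) - 1
      te <- ex_s[j] + sample.int(ex_e[j] - ex_s[j], 1)
      if (te <= ts) { ts <- ex_s[i]; te <- ex_e[j] }
    } else ts <- te <- start
    list(gene_id = sprintf("g%03d", g), chrom = "chrT", start = start,
         end = start + len, strand = sample(c("+", "-"), 1),
         thick_start = ts, thick_end = te,
         exon_starts = ex_s, exon_ends = ex_e)
  })
  genes <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = "chrT",
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    thick_start = vapply(rows, `[[`, 0, "thick_start"),
    thick_end = vapply(rows, `[[`, 0, "thick_end"),
    stringsAsFactors = FALSE)
  genes$exon_starts <- lapply(rows, `[[`, "exon_starts")
  genes$exon_ends <- lapply(rows, `[[`, "exon_ends")
  genes
}

# small beta matrix with named groups for caller tests
toy_samplesheet <- function(n_gh = 4, n_nfpa = 4) {
  data.frame(sample_id = c(sprintf("GH%d", seq_len(n_gh)),
                           sprintf("NF%d", seq_len(n_nfpa))),
             group = c(rep("GH", n_gh), rep("NFPA", n_nfpa)),
             stringsAsFactors = FALSE)
}
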