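# Synthetic genome backgrounds: chromosomes, CpG islands, gene models,
# target regions. All generators restore the caller's RNG state and are
# bit-reproducible for a fixed config seed.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a synthetic genome model
#'
#' Places non-overlapping CpG islands (separated by at least
#' `island_spacing` bp so that shore/shelf flanks of adjacent islands do
#' not collide) and simple gene models (transcript, exons, optional CDS
#' span) on a set of chromosomes. Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `genome_model` with elements `chromosomes`
#'   (data.frame `name`, `length`), `islands` (BED-like data.frame
#'   `chrom`, `start`, `end`, `name`; 0-based half-open, sorted,
#'   non-overlapping) and `genes` (data.frame of gene models, see
#'   [read_genes()] for the column contract).
#' @export
build_genome_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- data.frame(name = names(config$chrom_lengths),
                       length = as.numeric(config$chrom_lengths),
                       stringsAsFactors = FALSE)
  with_seed(config$seed + 101L, {
    islands <- place_islands(chroms, config$n_islands,
                             config$island_length, config$island_spacing)
    genes <- place_genes(chroms, config$n_genes, config$noncoding_fraction)
  })
  structure(list(chromosomes = chroms, islands = islands, genes = genes),
            class = "genome_model")
}

place_islands <- function(chroms, n_islands, island_length, spacing) {
  if (n_islands == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  # split islands across chromosomes proportionally to length
  w <- chroms$length / sum(chroms$length)
  k <- floor(w * n_islands)
  rem <- n_islands - sum(k)
  if (rem > 0) {
    ord <- order(w * n_islands - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  out <- vector("list", nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    ki <- k[i]
    if (ki == 0) next
    L <- chroms$length[i]
    need <- ki * island_length + (ki - 1) * spacing
    if (need > L)
      stopf("cannot place %d islands of %d bp with %d bp spacing on %s (%d bp)",
            ki, island_length, spacing, chroms$name[i], L)
    slack <- L - need
    g <- stats::runif(ki + 1)
    g <- floor(g / sum(g) * slack)
    starts <- cumsum(g[seq_len(ki)]) +
      (seq_len(ki) - 1) * (island_length + spacing)
    out[[i]] <- data.frame(chrom = chroms$name[i], start = starts,
                           end = starts + island_length,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, chroms$name), res$start), , drop = FALSE]
  res$name <- sprintf("cgi_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

place_genes <- function(chroms, n_genes, noncoding_fraction) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), thick_start = numeric(),
                      thick_end = numeric(), stringsAsFactors = FALSE)
  empty$exon_starts <- list()
  empty$exon_ends <- list()
  if (n_genes == 0) return(empty)
  w <- chroms$length / sum(chroms$length)
  chrom_idx <- sample.int(nrow(chroms), n_genes, replace = TRUE, prob = w)
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    L <- chroms$length[chrom_idx[g]]
    len <- round(stats::rlnorm(1, meanlog = log(20000), sdlog = 0.6))
    len <- clamp(len, 2000, max(2000, floor(L / 5)))
    start <- floor(stats::runif(1, 0, L - len))
    end <- start + len
    n_ex <- sample(2:8, 1)
    # interior breakpoints delimit alternating exon/intron segments,
    # starting and ending with an exon
    bp <- sort(sample.int(len - 1, 2 * n_ex - 2))
    ex_s <- start + c(0, bp[seq(2, length(bp), by = 2)])
    ex_e <- start + c(bp[seq(1, length(bp), by = 2)], len)
    coding <- stats::runif(1) > noncoding_fraction
    if (coding) {
      i <- sample.int(n_ex, 1)
      j <- sample(i:n_ex, 1)
      ts <- ex_s[i] + sample.int(max(1, ex_e[i] - ex_s[i]), 1) - 1
      te <- ex_s[j] + sample.int(max(1, ex_e[j] - ex_s[j]), 1)
      if (te <= ts) { ts <- ex_s[i]; te <- ex_e[j] }
    } else {
      ts <- start; te <- start
    }
    rows[[g]] <- list(chrom = chroms$name[chrom_idx[g]], start = start,
                      end = end,
                      strand = sample(c("+", "-"), 1),
                      thick_start = ts, thick_end = te,
                      exon_starts = ex_s, exon_ends = ex_e)
  }
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    thick_start = vapply(rows, `[[`, 0, "thick_start"),
    thick_end = vapply(rows, `[[`, 0, "thick_end"),
    stringsAsFactors = FALSE)
  genes$exon_starts <- lapply(rows, `[[`, "exon_starts")
  genes$exon_ends <- lapply(rows, `[[`, "exon_ends")
  ord <- order(match(genes$chrom, chroms$name), genes$start)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

# Mean of a log-normal truncated to [lo, hi], sdlog fixed.
truncated_lnorm_mean <- function(meanlog, sdlog, lo, hi) {
  z <- stats::pnorm((log(hi) - meanlog) / sdlog) -
    stats::pnorm((log(lo) - meanlog) / sdlog)
  num <- exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm((log(hi) - meanlog - sdlog^2) / sdlog) -
       stats::pnorm((log(lo) - meanlog - sdlog^2) / sdlog))
  num / z
}

#' Generate target regions
#'
#' Draws `n_regions` non-overlapping capture-style target regions on the
#' genome. Lengths follow a log-normal distribution truncated to
#' `[region_length_min, region_length_max]` with the truncated mean
#' calibrated to `region_length_mean`; regions are sorted by coordinate
#' and carry unique ids.
#'
#' @param genome a [build_genome_model()] result.
#' @param config a [sim_config()] object.
#' @return data.frame with columns `chrom`, `start`, `end`, `region_id`
#'   (0-based half-open intervals).
#' @export
generate_target_regions <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  n <- config$n_regions
  if (n > 100000L)
    log_msg("generate_target_regions: n_regions=%d is above desk scale", n)
  lo <- config$region_length_min
  hi <- config$region_length_max
  sdlog <- if (lo == hi) 0 else 1
  chroms <- genome$chromosomes
  with_seed(config$seed + 202L, {
    lens <- if (lo == hi) rep(lo, n) else {
      meanlog <- stats::uniroot(
        function(m) truncated_lnorm_mean(m, sdlog, lo, hi) -
          config$region_length_mean,
        lower = log(lo), upper = log(hi), tol = 1e-8)$root
      u <- stats::runif(n,
                        stats::plnorm(lo, meanlog, sdlog),
                        stats::plnorm(hi, meanlog, sdlog))
      clamp(round(stats::qlnorm(u, meanlog, sdlog)), lo, hi)
    }
    w <- chroms$length / sum(chroms$length)
    kept <- NULL
    todo <- n
    for (iter in seq_len(200)) {
      ci <- sample.int(nrow(chroms), todo, replace = TRUE, prob = w)
      pend <- lens[seq.int(n - todo + 1L, n)]
      starts <- floor(stats::runif(todo) * (chroms$length[ci] - pend))
      cand <- data.frame(chrom = chroms$name[ci], start = starts,
                         end = starts + pend, stringsAsFactors = FALSE)
      all <- rbind(kept, cand)
      all <- all[order(match(all$chrom, chroms$name), all$start, all$end), ,
                 drop = FALSE]
      same <- c(FALSE, all$chrom[-1] == all$chrom[-nrow(all)])
      prev_end <- c(-Inf, all$end[-nrow(all)])
      keep <- !(same & all$start < cummax_by(prev_end, same))
      kept <- all[keep, , drop = FALSE]
      todo <- n - nrow(kept)
      if (todo == 0) break
    }
    if (todo > 0)
      stopf("could not place %d non-overlapping regions (%d short)", n, todo)
    kept$region_id <- sprintf("region_%06d", seq_len(nrow(kept)))
    rownames(kept) <- NULL
    kept[, c("chrom", "start", "end", "region_id")]
  })
}

# running max of `x` reset wherever `same` is FALSE (chromosome change)
cummax_by <- function(x, same) {
  out <- x
  for (i in seq_along(x)[-1]) if (same[i]) out[i] <- max(out[i - 1], x[i])
  out
}

#' Build the default sample sheet for a simulation
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `sample_id`, `group` where group is
#'   one of `GH`, `NFPA`, `NORMAL`.
#' @export
make_samplesheet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(
    sample_id = c(sprintf("GH%02d", seq_len(config$n_gh)),
                  sprintf("NFPA%02d", seq_len(config$n_nfpa)),
                  if (config$n_normal > 0)
                    sprintf("NORM%02d", seq_len(config$n_normal))),
    group = c(rep("GH", config$n_gh), rep("NFPA", config$n_nfpa),
              rep("NORMAL", config$n_normal)),
    stringsAsFactors = FALSE)
}
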