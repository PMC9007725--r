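# CpG-centric and genic annotation of target regions.
#
# Distance convention: a base b and an island [s, e) are at distance
# s - b when b < s and b - e + 1 when b >= e, so the base immediately
# flanking an island is at distance 1. Shores cover distances 1-2000,
# shelves 2001-4000; everything farther is open sea. N is the
# lower-coordinate flank, S the higher-coordinate flank, regardless of
# strand.

GENIC_CATEGORIES <- c("EXONIC", "UTR5", "UTR3", "NCRNA_EXONIC", "INTRONIC",
                      "NCRNA_INTRONIC", "UPSTREAM", "DOWNSTREAM",
                      "INTERGENIC")
GENIC_TIER <- c(EXONIC = 1, UTR5 = 2, UTR3 = 2, NCRNA_EXONIC = 3,
                INTRONIC = 4, NCRNA_INTRONIC = 4, UPSTREAM = 5,
                DOWNSTREAM = 5, INTERGENIC = 6)

SHORE_BP <- 2000L
SHELF_BP <- 2000L

#' Build a CpG-context partition of the genome
#'
#' Partitions every chromosome into ISLAND, N_SHORE/S_SHORE (up to 2 kb
#' on the lower/higher-coordinate flank of each island), N_SHELF/S_SHELF
#' (the next 2 kb) and OPEN_SEA. Where flanks of adjacent islands would
#' collide, each base is assigned to the context of the nearer island
#' (ties go to the lower-coordinate island).
#'
#' @param islands BED-like data.frame `chrom`, `start`, `end` of CpG
#'   islands; must be non-overlapping and within chromosome bounds.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @return an object of class `context_map`: per chromosome a partition
#'   data.frame (`start`, `end`, `context`) covering `[0, length)`.
#' @export
build_context_map <- function(islands, chrom_lengths) {
  if (is.null(names(chrom_lengths)))
    stopf("'chrom_lengths' must be named")
  bad <- setdiff(unique(islands$chrom), names(chrom_lengths))
  if (length(bad))
    stopf("islands on unknown chromosomes: %s", paste(bad, collapse = ", "))
  map <- lapply(names(chrom_lengths), function(ch) {
    L <- as.numeric(chrom_lengths[[ch]])
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    isl <- isl[order(isl$start), , drop = FALSE]
    if (nrow(isl) > 1 && any(isl$start[-1] < isl$end[-nrow(isl)]))
      stopf("overlapping islands on %s", ch)
    if (nrow(isl) && (any(isl$start < 0) || any(isl$end > L)))
      stopf("island outside chromosome bounds on %s", ch)
    if (nrow(isl) == 0)
      return(data.frame(start = 0, end = L, context = "OPEN_SEA",
                        stringsAsFactors = FALSE))
    k <- nrow(isl)
    # territory limits: midpoint split between adjacent islands, ties to
    # the lower-coordinate island
    splits <- if (k > 1)
      floor((isl$end[-k] + isl$start[-1] - 1) / 2) + 1 else numeric(0)
    left_lim <- c(0, splits)
    right_lim <- c(splits, L)
    segs <- vector("list", k)
    for (i in seq_len(k)) {
      s <- isl$start[i]; e <- isl$end[i]
      n_sh_s <- clamp(s - SHORE_BP, left_lim[i], s)
      n_sf_s <- clamp(s - SHORE_BP - SHELF_BP, left_lim[i], s)
      s_sh_e <- clamp(e + SHORE_BP, e, right_lim[i])
      s_sf_e <- clamp(e + SHORE_BP + SHELF_BP, e, right_lim[i])
      segs[[i]] <- data.frame(
        start = c(left_lim[i], n_sf_s, n_sh_s, s, e, s_sh_e, s_sf_e),
        end = c(n_sf_s, n_sh_s, s, e, s_sh_e, s_sf_e, right_lim[i]),
        context = c("OPEN_SEA", "N_SHELF", "N_SHORE", "ISLAND",
                    "S_SHORE", "S_SHELF", "OPEN_SEA"),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, segs)
    out <- out[out$end > out$start, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(map) <- names(chrom_lengths)
  structure(list(chrom_lengths = chrom_lengths, map = map),
            class = "context_map")
}

#' Assign one CpG context per region
#'
#' A region may span several contexts; a single label is chosen by
#' priority ISLAND > shores > shelves > OPEN_SEA among the contexts it
#' overlaps. Among candidates of equal priority the larger base-pair
#' overlap wins; remaining ties go N before S.
#'
#' @param regions data.frame of target regions (`chrom`, `start`, `end`).
#' @param context_map a [build_context_map()] result.
#' @return character vector of contexts, one per region.
#' @export
annotate_cpg_context <- function(regions, context_map) {
  stopifnot(inherits(context_map, "context_map"))
  bad <- setdiff(unique(regions$chrom), names(context_map$map))
  if (length(bad))
    stopf("regions on chromosomes absent from context map: %s",
          paste(bad, collapse = ", "))
  priority <- c(ISLAND = 1, N_SHORE = 2, S_SHORE = 2, N_SHELF = 3,
                S_SHELF = 3, OPEN_SEA = 4)
  out <- character(nrow(regions))
  for (ch in unique(regions$chrom)) {
    m <- context_map$map[[ch]]
    ri <- which(regions$chrom == ch)
    lo <- findInterval(regions$start[ri], m$start)
    hi <- findInterval(regions$end[ri] - 1, m$start)
    for (k in seq_along(ri)) {
      idx <- seq.int(lo[k], hi[k])
      ov <- pmin(regions$end[ri[k]], m$end[idx]) -
        pmax(regions$start[ri[k]], m$start[idx])
      ov <- tapply(ov, m$context[idx], sum)
      cand <- names(ov)[priority[names(ov)] == min(priority[names(ov)])]
      cand <- cand[ov[cand] == max(ov[cand])]
      out[ri[k]] <- CPG_CONTEXTS[min(match(cand, CPG_CONTEXTS))]
    }
  }
  out
}

# interval set helpers (matrix with columns start, end)
iv_overlap_any <- function(s, e, starts, ends) {
  length(starts) > 0 && any(pmin(e, ends) > pmax(s, starts))
}

# gaps of [start,end) not covered by the (sorted, disjoint) exons
intron_intervals <- function(ex_s, ex_e) {
  if (length(ex_s) < 2) return(cbind(numeric(0), numeric(0)))
  cbind(ex_e[-length(ex_e)], ex_s[-1])
}

# pieces of exons strictly below/above a coordinate cutpoint
exon_parts <- function(ex_s, ex_e, lo, hi) {
  s <- pmax(ex_s, lo); e <- pmin(ex_e, hi)
  keep <- e > s
  cbind(s[keep], e[keep])
}

#' Annotate regions with genic context
#'
#' Simplified gene-model annotation: each region gets one category by the
#' precedence EXONIC (CDS overlap) > UTR5/UTR3 > NCRNA_EXONIC >
#' INTRONIC/NCRNA_INTRONIC > UPSTREAM/DOWNSTREAM (within
#' `upstream_window` bp of the transcript ends, strand-aware) >
#' INTERGENIC, together with the nearest gene and its distance (0 when
#' the region overlaps the gene). Overlap with any part of a category's
#' intervals suffices; ties across genes resolve to the smaller distance,
#' then the lexicographically smaller gene id.
#'
#' @param regions data.frame of target regions.
#' @param genes gene-model data.frame (see [build_genome_model()]).
#' @param upstream_window bp window defining UPSTREAM/DOWNSTREAM.
#' @return data.frame `region_id`, `category`, `nearest_gene`,
#'   `distance`. With an empty gene set every region is INTERGENIC with
#'   `NA` distance (flagged by a warning).
#' @export
annotate_genic <- function(regions, genes, upstream_window = 1000) {
  n <- nrow(regions)
  out <- data.frame(region_id = regions$region_id,
                    category = rep("INTERGENIC", n),
                    nearest_gene = NA_character_,
                    distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (is.null(genes) || nrow(genes) == 0) {
    warnf("annotate_genic: empty gene set; all regions INTERGENIC with undefined distance")
    return(out)
  }
  for (r in seq_len(n)) {
    gs <- genes[genes$chrom == regions$chrom[r], , drop = FALSE]
    if (nrow(gs) == 0) next
    s <- regions$start[r]; e <- regions$end[r]
    best_cat <- "INTERGENIC"; best_dist <- Inf; best_gene <- NA_character_
    for (g in seq_len(nrow(gs))) {
      ex_s <- gs$exon_starts[[g]]; ex_e <- gs$exon_ends[[g]]
      coding <- gs$thick_end[g] > gs$thick_start[g]
      plus <- gs$strand[g] == "+"
      cat_g <- NA_character_
      if (coding && iv_overlap_any(s, e,
                                   pmax(ex_s, gs$thick_start[g]),
                                   pmin(ex_e, gs$thick_end[g]))) {
        cat_g <- "EXONIC"
      } else if (coding) {
        lo_utr <- exon_parts(ex_s, ex_e, gs$start[g], gs$thick_start[g])
        hi_utr <- exon_parts(ex_s, ex_e, gs$thick_end[g], gs$end[g])
        utr5 <- if (plus) lo_utr else hi_utr
        utr3 <- if (plus) hi_utr else lo_utr
        if (iv_overlap_any(s, e, utr5[, 1], utr5[, 2])) cat_g <- "UTR5"
        else if (iv_overlap_any(s, e, utr3[, 1], utr3[, 2])) cat_g <- "UTR3"
      }
      if (is.na(cat_g) && !coding &&
          iv_overlap_any(s, e, ex_s, ex_e)) cat_g <- "NCRNA_EXONIC"
      if (is.na(cat_g)) {
        ivs <- intron_intervals(ex_s, ex_e)
        if (iv_overlap_any(s, e, ivs[, 1], ivs[, 2]))
          cat_g <- if (coding) "INTRONIC" else "NCRNA_INTRONIC"
      }
      dist_g <- 0
      if (is.na(cat_g)) {
        # no overlap with the transcript body; check the flank windows
        up <- if (plus) c(gs$start[g] - upstream_window, gs$start[g])
              else c(gs$end[g], gs$end[g] + upstream_window)
        dn <- if (plus) c(gs$end[g], gs$end[g] + upstream_window)
              else c(gs$start[g] - upstream_window, gs$start[g])
        dist_g <- if (e <= gs$start[g]) gs$start[g] - e + 1
                  else if (s >= gs$end[g]) s - gs$end[g] + 1
                  else 0
        if (iv_overlap_any(s, e, up[1], up[2])) cat_g <- "UPSTREAM"
        else if (iv_overlap_any(s, e, dn[1], dn[2])) cat_g <- "DOWNSTREAM"
        else cat_g <- "INTERGENIC"
      }
      better <- GENIC_TIER[cat_g] < GENIC_TIER[best_cat] ||
        (GENIC_TIER[cat_g] == GENIC_TIER[best_cat] &&
           (dist_g < best_dist ||
              (dist_g == best_dist &&
                 (is.na(best_gene) || gs$gene_id[g] < best_gene))))
      if (better) {
        best_cat <- cat_g; best_dist <- dist_g; best_gene <- gs$gene_id[g]
      }
    }
    out$category[r] <- best_cat
    out$nearest_gene[r] <- best_gene
    out$distance[r] <- best_dist
  }
  out
}

#' Collapse genic categories to coding vs noncoding
#'
#' CODING iff the region overlaps a CDS exon (category EXONIC); every
#' other category, including UTRs and introns, is NONCODING.
#'
#' @param categories character vector of genic categories.
#' @return character vector of `"CODING"`/`"NONCODING"`.
#' @export
classify_coding <- function(categories) {
  bad <- setdiff(unique(categories), GENIC_CATEGORIES)
  if (length(bad))
    stopf("unknown genic categories: %s", paste(bad, collapse = ", "))
  ifelse(categories == "EXONIC", "CODING", "NONCODING")
}

#' Tabulate annotation proportions
#'
#' @param annotations character vector (e.g. CpG contexts or genic
#'   categories).
#' @return data.frame `category`, `n`, `pct` sorted by decreasing count;
#'   percentages sum to 100 up to rounding.
#' @export
summarize_annotation <- function(annotations) {
  if (!length(annotations)) stopf("no annotations to summarize")
  tab <- sort(table(annotations), decreasing = TRUE)
  data.frame(category = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / length(annotations),
             stringsAsFactors = FALSE, row.names = NULL)
}
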