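# Brute-force oracles, written independently of the implementation
# paths they check.

# Per-base CpG context from the sorted island list of one chromosome.
# A base at distance d from the nearest island edge (d = 1 for the
# immediately flanking base) is shore for d <= 2000, shelf for
# d <= 4000, open sea beyond; ties between islands go to the
# lower-coordinate island.
oracle_base_context <- function(pos, isl) {
  n <- length(pos)
  k <- nrow(isl)
  if (k == 0) return(rep("OPEN_SEA", n))
  S <- matrix(isl$start, n, k, byrow = TRUE)
  E <- matrix(isl$end, n, k, byrow = TRUE)
  B <- matrix(pos, n, k)
  D <- ifelse(B < S, S - B, B - E + 1)
  D[S <= B & B < E] <- 0
  i <- max.col(-D, ties.method = "first")
  d <- D[cbind(seq_len(n), i)]
  side <- ifelse(pos < isl$start[i], "N_", "S_")
  ifelse(d == 0, "ISLAND",
         ifelse(d <= 2000, paste0(side, "SHORE"),
                ifelse(d <= 4000, paste0(side, "SHELF"), "OPEN_SEA")))
}

# Region-level context: per-base majority within the priority class.
oracle_region_context <- function(start, end, isl) {
  ctx <- oracle_base_context(seq(start, end - 1), isl)
  tab <- table(ctx)
  priority <- c(ISLAND = 1, N_SHORE = 2, S_SHORE = 2, N_SHELF = 3,
                S_SHELF = 3, OPEN_SEA = 4)
  cand <- names(tab)[priority[names(tab)] == min(priority[names(tab)])]
  cand <- cand[tab[cand] == max(tab[cand])]
  CPG_CONTEXTS[min(match(cand, CPG_CONTEXTS))]
}

# Exhaustive per-category genic scan for one region.
oracle_genic <- function(s, e, genes, window = 1000) {
  tiers <- c(EXONIC = 1, UTR5 = 2, UTR3 = 2, NCRNA_EXONIC = 3,
             INTRONIC = 4, NCRNA_INTRONIC = 4, UPSTREAM = 5,
             DOWNSTREAM = 5, INTERGENIC = 6)
  hit_any <- function(m) !is.null(m) && nrow(m) > 0 &&
    any(pmin(e, m[, 2]) > pmax(s, m[, 1]))
  trim <- function(m) m[m[, 2] > m[, 1], , drop = FALSE]
  best <- list(cat = "INTERGENIC", dist = Inf, gene = NA_character_)
  for (g in seq_len(nrow(genes))) {
    ex <- cbind(genes$exon_starts[[g]], genes$exon_ends[[g]])
    coding <- genes$thick_end[g] > genes$thick_start[g]
    plus <- genes$strand[g] == "+"
    ivs <- list()
    if (coding) {
      ivs$EXONIC <- trim(cbind(pmax(ex[, 1], genes$thick_start[g]),
                               pmin(ex[, 2], genes$thick_end[g])))
      lo <- trim(cbind(ex[, 1], pmin(ex[, 2], genes$thick_start[g])))
      hi <- trim(cbind(pmax(ex[, 1], genes$thick_end[g]), ex[, 2]))
      ivs$UTR5 <- if (plus) lo else hi
      ivs$UTR3 <- if (plus) hi else lo
      if (nrow(ex) > 1)
        ivs$INTRONIC <- cbind(ex[-nrow(ex), 2], ex[-1, 1])
    } else {
      ivs$NCRNA_EXONIC <- ex
      if (nrow(ex) > 1)
        ivs$NCRNA_INTRONIC <- cbind(ex[-nrow(ex), 2], ex[-1, 1])
    }
    body_overlap <- pmin(e, genes$end[g]) > pmax(s, genes$start[g])
    if (!body_overlap) {
      up <- if (plus) c(genes$start[g] - window, genes$start[g])
            else c(genes$end[g], genes$end[g] + window)
      dn <- if (plus) c(genes$end[g], genes$end[g] + window)
            else c(genes$start[g] - window, genes$start[g])
      ivs$UPSTREAM <- matrix(up, 1)
      ivs$DOWNSTREAM <- matrix(dn, 1)
    }
    cat_g <- "INTERGENIC"
    for (cat in names(tiers)) {
      if (cat == "INTERGENIC") break
      if (hit_any(ivs[[cat]])) { cat_g <- cat; break }
    }
    dist_g <- if (body_overlap) 0
              else if (e <= genes$start[g]) genes$start[g] - e + 1
              else s - genes$end[g] + 1
    better <- tiers[[cat_g]] < tiers[[best$cat]] ||
      (tiers[[cat_g]] == tiers[[best$cat]] &&
         (dist_g < best$dist ||
            (dist_g == best$dist &&
               (is.na(best$gene) || genes$gene_id[g] < best$gene))))
    if (better) best <- list(cat = cat_g, dist = dist_g,
                             gene = genes$gene_id[g])
  }
  best
}

# Exhaustive permutation two-sided Mann-Whitney p for small samples:
# all choose(n_a + n_b, n_a) reassignments of the pooled values, U from
# midranks, p = share of assignments at least as far from the null mean
# as the observed U.
oracle_mw_perm <- function(a, b) {
  pool <- c(a, b)
  n_a <- length(a)
  n <- length(pool)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  mid <- n_a * (n - n_a) / 2
  combos <- utils::combn(n, n_a)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# O(n * m) membership scan for region collapse.
oracle_collapse <- function(cyt, regions) {
  samples <- sort(unique(cyt$sample_id))
  meth <- total <- matrix(0, nrow(regions), length(samples),
                          dimnames = list(regions$region_id, samples))
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(cyt))) {
      if (cyt$chrom[j] == regions$chrom[i] &&
          cyt$pos[j] >= regions$start[i] && cyt$pos[j] < regions$end[i]) {
        k <- match(cyt$sample_id[j], samples)
        meth[i, k] <- meth[i, k] + cyt$meth[j]
        total[i, k] <- total[i, k] + cyt$total[j]
      }
    }
  }
  list(meth = meth, total = total)
}
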