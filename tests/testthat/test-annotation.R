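# CpG context map, region context, genic annotation, summaries.

test_that("context map reproduces the direct flank geometry", {
  isl <- data.frame(chrom = "chrT", start = 10000, end = 10500,
                    stringsAsFactors = FALSE)
  cm <- build_context_map(isl, c(chrT = 100000))
  m <- cm$map$chrT
  expect_equal(m$start, c(0, 6000, 8000, 10000, 10500, 12500, 14500))
  expect_equal(m$end, c(6000, 8000, 10000, 10500, 12500, 14500, 100000))
  expect_equal(m$context, c("OPEN_SEA", "N_SHELF", "N_SHORE", "ISLAND",
                            "S_SHORE", "S_SHELF", "OPEN_SEA"))
  # true partition of [0, L)
  expect_equal(m$start[-1], m$end[-nrow(m)])
  expect_equal(m$start[1], 0)
  expect_equal(m$end[nrow(m)], 100000)
})

test_that("colliding flanks split at the midpoint, ties to the lower island", {
  isl <- data.frame(chrom = "chrT", start = c(10000, 13500),
                    end = c(10500, 14000), stringsAsFactors = FALSE)
  cm <- build_context_map(isl, c(chrT = 50000))
  m <- cm$map$chrT
  # the 3 kb gap [10500, 13500) splits 1500/1500: S_SHORE then N_SHORE
  expect_true(any(m$context == "S_SHORE" & m$start == 10500 &
                    m$end == 12000))
  expect_true(any(m$context == "N_SHORE" & m$start == 12000 &
                    m$end == 13500))
  # per-base brute force over the whole gap agrees
  pos <- 10500:13499
  seg <- findInterval(pos, m$start)
  expect_equal(m$context[seg], oracle_base_context(pos, isl))
})

test_that("no islands means the whole genome is open sea", {
  cm <- build_context_map(
    data.frame(chrom = character(), start = numeric(), end = numeric()),
    c(chrT = 1e5))
  expect_equal(cm$map$chrT$context, "OPEN_SEA")
  expect_error(
    build_context_map(data.frame(chrom = "chrT", start = c(0, 50),
                                 end = c(100, 150)), c(chrT = 1e3)),
    "overlapping islands")
})

test_that("region context follows the priority and overlap rules", {
  isl <- data.frame(chrom = "chrT", start = 10000, end = 10500,
                    stringsAsFactors = FALSE)
  cm <- build_context_map(isl, c(chrT = 100000))
  reg <- data.frame(
    chrom = "chrT",
    start = c(10100, 10200, 50000, 9000, 11000),
    end = c(10400, 10700, 50200, 10100, 13000),
    region_id = paste0("r", 1:5), stringsAsFactors = FALSE)
  ctx <- annotate_cpg_context(reg, cm)
  expect_equal(ctx[1], "ISLAND")         # fully inside
  expect_equal(ctx[2], "ISLAND")         # straddles edge: priority wins
  expect_equal(ctx[3], "OPEN_SEA")       # 5 kb+ away
  expect_equal(ctx[4], "ISLAND")         # mostly shore, but island priority
  expect_equal(ctx[5], "S_SHORE")        # shore beats shelf by priority
  expect_error(
    annotate_cpg_context(data.frame(chrom = "chrX", start = 1, end = 2,
                                    region_id = "x"), cm),
    "absent from context map")
})

test_that("region context matches the per-base oracle on random genomes", {
  for (seed in 1:4) {
    isl <- rand_islands(8, 1e5, seed)
    cm <- build_context_map(isl, c(chrT = 1e5))
    reg <- rand_regions(120, 1e5, seed + 100)
    got <- annotate_cpg_context(reg, cm)
    want <- vapply(seq_len(nrow(reg)), function(i)
      oracle_region_context(reg$start[i], reg$end[i], isl), "")
    expect_identical(got, want, label = sprintf("seed %d", seed))
  }
})

test_that("priority monotonicity: enlarging a region never demotes it", {
  isl <- rand_islands(6, 1e5, 77)
  cm <- build_context_map(isl, c(chrT = 1e5))
  reg <- rand_regions(100, 99000, 78)
  big <- reg
  big$start <- pmax(0, reg$start - 500)
  big$end <- reg$end + 500
  pr <- c(ISLAND = 1, N_SHORE = 2, S_SHORE = 2, N_SHELF = 3, S_SHELF = 3,
          OPEN_SEA = 4)
  expect_true(all(pr[annotate_cpg_context(big, cm)] <=
                    pr[annotate_cpg_context(reg, cm)]))
})

test_that("genic annotation handles the canonical cases", {
  # one coding plus-strand gene: exons [1000,1200) [2000,2300) [3000,3500),
  # CDS [2100, 3100)
  gene <- data.frame(gene_id = "gA", chrom = "chrT", start = 1000,
                     end = 3500, strand = "+", thick_start = 2100,
                     thick_end = 3100, stringsAsFactors = FALSE)
  gene$exon_starts <- list(c(1000, 2000, 3000))
  gene$exon_ends <- list(c(1200, 2300, 3500))
  # one minus-strand noncoding gene far away
  nc <- data.frame(gene_id = "gB", chrom = "chrT", start = 20000,
                   end = 24000, strand = "-", thick_start = 20000,
                   thick_end = 20000, stringsAsFactors = FALSE)
  nc$exon_starts <- list(c(20000, 23000))
  nc$exon_ends <- list(c(21000, 24000))
  genes <- rbind(gene, nc)
  reg <- data.frame(
    chrom = "chrT",
    start = c(1500, 2150, 1100, 3200, 500, 24500, 21500, 20500, 8000),
    end = c(1600, 2250, 2200, 3300, 600, 24600, 21600, 20600, 8100),
    region_id = paste0("r", 1:9), stringsAsFactors = FALSE)
  ann <- annotate_genic(reg, genes)
  expect_equal(ann$category,
               c("INTRONIC",       # inside intron 1
                 "EXONIC",         # CDS part of exon 2
                 "EXONIC",         # spans exon 1 (UTR5) and CDS: precedence
                 "UTR3",           # exon 3 past CDS end on + strand
                 "UPSTREAM",       # 500 bp 5' of + gene
                 "UPSTREAM",       # higher coords, 5' of the minus gene
                 "NCRNA_INTRONIC", # intron of the noncoding gene
                 "NCRNA_EXONIC",   # exon of the noncoding gene
                 "INTERGENIC"))
  expect_equal(ann$distance[c(1, 2, 7)], c(0, 0, 0))
  expect_true(all(ann$distance[c(5, 6, 9)] > 0))
  expect_equal(ann$nearest_gene[9], "gA")  # nearer than gB
})

test_that("empty gene set yields flagged intergenic annotations", {
  reg <- data.frame(chrom = "chrT", start = 1, end = 100, region_id = "r1")
  expect_warning(ann <- annotate_genic(reg, NULL), "empty gene set")
  expect_equal(ann$category, "INTERGENIC")
  expect_true(is.na(ann$distance))
})

test_that("genic annotation matches the exhaustive category scan", {
  for (seed in 1:4) {
    genes <- rand_genes(12, 1e5, seed)
    reg <- rand_regions(120, 1e5, seed + 200)
    got <- annotate_genic(reg, genes)
    for (i in seq_len(nrow(reg))) {
      want <- oracle_genic(reg$start[i], reg$end[i], genes)
      expect_equal(got$category[i], want$cat,
                   label = sprintf("seed %d region %d category", seed, i))
      expect_equal(got$nearest_gene[i], want$gene,
                   label = sprintf("seed %d region %d gene", seed, i))
      expect_equal(got$distance[i], unname(want$dist),
                   label = sprintf("seed %d region %d distance", seed, i))
    }
  }
})

test_that("coding classification and proportion summaries are exact", {
  expect_equal(classify_coding(c("EXONIC", "INTRONIC", "INTERGENIC",
                                 "UTR5", "NCRNA_EXONIC")),
               c("CODING", "NONCODING", "NONCODING", "NONCODING",
                 "NONCODING"))
  expect_error(classify_coding("EXON"), "unknown genic categories")
  s <- summarize_annotation(c(rep("NONCODING", 92), rep("CODING", 8)))
  expect_equal(s$pct[s$category == "NONCODING"], 92)
  s2 <- summarize_annotation(c("A", "B", "C", "C"))
  expect_equal(s2$pct[order(s2$category)], c(25, 25, 50))
  expect_equal(sum(s2$pct), 100)
  # planted mix bookkeeping
  mix <- sample(rep(c("X", "Y"), c(30, 70)))
  s3 <- summarize_annotation(mix)
  expect_equal(s3$n[s3$category == "X"], 30)
  expect_equal(s3$pct[s3$category == "Y"], 70)
})
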