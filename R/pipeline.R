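# End-to-end orchestration: simulate-or-load -> quantify/filter -> DMR
# calling -> annotation -> group comparisons, with a JSON run manifest.

#' Run the full differential-methylation pipeline
#'
#' Chains the pipeline stages: obtain region-level counts (either by
#' simulation or from files), apply the all-sample coverage filter over
#' the tested groups, compute betas, call DMRs, annotate regions with
#' CpG and genic context, run the group-level distribution contrasts,
#' and write all outputs plus a JSON manifest recording the effective
#' configuration, seed and the region funnel (input, post-filter,
#' significant, H, L).
#'
#' @param out_dir output directory (created if needed). `NULL` skips all
#'   file output.
#' @param sim a [sim_config()] object; used to simulate when `inputs` is
#'   NULL.
#' @param dmr a [dmr_config()] object.
#' @param inputs optional named list of file paths to load instead of
#'   simulating: `regions` (BED), `islands` (BED), `genes` (BED12/GTF),
#'   `counts` (TSV), `samplesheet` (TSV), and `chrom_lengths` (named
#'   vector, required with file inputs).
#' @param min_total coverage threshold for [filter_covered_regions()].
#' @return invisibly, a list with `regions`, `counts`, `filtered`,
#'   `betas`, `dmrs` (annotated table), `comparisons`, `truth` (NULL for
#'   file inputs), `manifest`.
#' @export
run_pipeline <- function(out_dir = NULL, sim = sim_config(),
                         dmr = dmr_config(), inputs = NULL, min_total = 1) {
  t0 <- Sys.time()
  if (is.null(inputs)) {
    log_msg("run_pipeline: simulating (seed=%d)", sim$seed)
    genome <- build_genome_model(sim)
    regions <- generate_target_regions(genome, sim)
    samplesheet <- make_samplesheet(sim)
    simres <- simulate_meth_counts(regions, genome, samplesheet, sim)
    counts <- simres$counts
    truth <- simres$truth
    islands <- genome$islands
    genes <- genome$genes
    chrom_lengths <- stats::setNames(genome$chromosomes$length,
                                     genome$chromosomes$name)
  } else {
    for (f in c("regions", "counts", "samplesheet")) {
      if (is.null(inputs[[f]])) stopf("inputs$%s is required", f)
      if (!file.exists(inputs[[f]])) stopf("input file not found: %s",
                                           inputs[[f]])
    }
    regions <- read_bed(inputs$regions)
    counts <- read_counts(inputs$counts)
    samplesheet <- read_samplesheet(inputs$samplesheet)
    islands <- if (!is.null(inputs$islands)) read_bed(inputs$islands)[,
      c("chrom", "start", "end")] else NULL
    genes <- if (!is.null(inputs$genes)) read_genes(inputs$genes) else NULL
    chrom_lengths <- inputs$chrom_lengths
    if (is.null(chrom_lengths))
      chrom_lengths <- tapply(regions$end, regions$chrom, max)
    truth <- NULL
  }
  n_input <- nrow(counts$meth)

  filtered <- filter_covered_regions(counts, samplesheet,
                                     groups = c("GH", "NFPA"),
                                     min_total = min_total)
  betas <- compute_beta(filtered)
  dmrs <- call_dmrs(betas, samplesheet, dmr)

  kept <- regions[match(rownames(betas), regions$region_id), , drop = FALSE]
  ann <- data.frame(region_id = kept$region_id,
                    cpg_context = NA_character_,
                    genic_category = NA_character_,
                    nearest_gene = NA_character_,
                    distance = NA_real_,
                    coding_class = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(islands) && nrow(islands)) {
    cmap <- build_context_map(islands, chrom_lengths)
    ann$cpg_context <- annotate_cpg_context(kept, cmap)
  }
  if (!is.null(genes) && nrow(genes)) {
    gen <- annotate_genic(kept, genes)
    ann$genic_category <- gen$category
    ann$nearest_gene <- gen$nearest_gene
    ann$distance <- gen$distance
    ann$coding_class <- classify_coding(gen$category)
  }
  dmrs <- merge(dmrs, cbind(kept[, c("chrom", "start", "end")],
                            ann[, -1, drop = FALSE],
                            region_id = ann$region_id),
                by = "region_id", sort = FALSE)
  dmrs <- dmrs[order(dmrs$p_adj, -abs(dmrs$lfc), dmrs$region_id), ,
               drop = FALSE]
  rownames(dmrs) <- NULL

  comparisons <- list(global = compare_global(betas, samplesheet))
  if (!all(is.na(ann$cpg_context)))
    comparisons$by_context <- compare_by_context(betas, samplesheet,
                                                 ann$cpg_context)
  sig <- dmrs[dmrs$significant, , drop = FALSE]
  if (nrow(sig) && !all(is.na(sig$coding_class)))
    comparisons$dmr_coding <- compare_dmr_strata(sig, sig$coding_class)
  if (nrow(sig) && !all(is.na(sig$cpg_context)))
    comparisons$dmr_context <- compare_dmr_strata(sig, sig$cpg_context)

  n_sig <- sum(dmrs$significant)
  n_h <- sum(dmrs$magnitude_class == "H_DMR")
  n_l <- sum(dmrs$magnitude_class == "L_DMR")
  stopifnot(n_sig == n_h + n_l, nrow(dmrs) <= n_input)
  manifest <- list(
    version = as.character(utils::packageVersion("methdmr")),
    seed = if (is.null(inputs)) sim$seed else NA,
    config = list(
      sim = if (is.null(inputs)) unclass(sim) else NULL,
      dmr = unclass(dmr), min_total = min_total,
      inputs = if (!is.null(inputs))
        lapply(inputs, function(x) if (is.character(x)) x else unclass(x))),
    funnel = list(input_regions = n_input, post_filter = nrow(dmrs),
                  significant = n_sig, h_dmr = n_h, l_dmr = n_l),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_bed(regions, p("regions.bed"))
    if (!is.null(islands) && nrow(islands)) {
      isl <- islands
      isl$region_id <- if (!is.null(isl$name)) isl$name else
        sprintf("cgi_%04d", seq_len(nrow(isl)))
      write_bed(isl, p("islands.bed"))
    }
    if (!is.null(genes) && nrow(genes)) write_bed12(genes, p("genes.bed12"))
    write_counts(counts, p("counts.tsv"))
    write_samplesheet(samplesheet, p("samplesheet.tsv"))
    if (!is.null(truth)) write_tsv(truth, p("truth.tsv"))
    write_tsv(dmrs, p("dmrs.tsv"))
    write_tsv(ann, p("annotation.tsv"))
    for (nm in names(comparisons))
      write_tsv(comparisons[[nm]], p(sprintf("comparison_%s.tsv", nm)))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    log_msg("run_pipeline: outputs written to %s", out_dir)
  }
  invisible(list(regions = regions, counts = counts, filtered = filtered,
                 betas = betas, dmrs = dmrs, annotation = ann,
                 comparisons = comparisons, truth = truth,
                 samplesheet = samplesheet, manifest = manifest))
}
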