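# Standard-format I/O. All coordinates are 0-based half-open (BED
# convention); 1-based formats (GTF) are converted at this boundary.
# All files are UTF-8, LF, tab-delimited except the cohort CSV.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read / write regions as BED3+name
#'
#' BED with columns chrom, start, end and an optional name (region id);
#' strictly 0-based half-open. Malformed lines are reported with their
#' line numbers; empty intervals (end <= start) and duplicate ids are
#' errors.
#'
#' @param path file path.
#' @param regions data.frame `chrom`, `start`, `end`, `region_id`.
#' @return `read_bed`: the regions data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stopf("%s: line %d has %d field(s); BED needs at least 3",
          path, which(nf < 3)[1], min(nf))
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stopf("%s: non-numeric coordinates on line %d", path, bad[1])
  bad <- which(end <= start)
  if (length(bad))
    stopf("%s: empty interval (end <= start) on line %d", path, bad[1])
  name <- vapply(seq_along(parts), function(i)
    if (nf[i] >= 4) parts[[i]][4] else sprintf("region_%d", i), "")
  if (anyDuplicated(name))
    stopf("%s: duplicate region id '%s'", path, name[anyDuplicated(name)])
  data.frame(chrom = chrom, start = start, end = end, region_id = name,
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  check_regions(regions, require_disjoint = FALSE)
  df <- regions[, c("chrom", "start", "end", "region_id")]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write gene models as BED12
#'
#' BED12 with thickStart/thickEnd as the CDS span (thickStart ==
#' thickEnd marks a noncoding gene) and blocks as exons.
#'
#' @param path file path.
#' @param genes gene-model data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `thick_start`, `thick_end` and
#'   list-columns `exon_starts`, `exon_ends`.
#' @return `read_bed12`: the gene-model data.frame.
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12))
    stopf("%s: line %d has %d field(s); BED12 needs 12",
          path, which(nf < 12)[1], min(nf))
  f <- function(i) vapply(parts, `[`, "", i)
  num <- function(i) as.numeric(f(i))
  start <- num(2)
  genes <- data.frame(gene_id = f(4), chrom = f(1), start = start,
                      end = num(3), strand = f(6), thick_start = num(7),
                      thick_end = num(8), stringsAsFactors = FALSE)
  sizes <- lapply(strsplit(f(11), ","), as.numeric)
  offs <- lapply(strsplit(f(12), ","), as.numeric)
  genes$exon_starts <- mapply(function(s, o) s + o, start, offs,
                              SIMPLIFY = FALSE)
  genes$exon_ends <- mapply(function(es, sz) es + sz, genes$exon_starts,
                            sizes, SIMPLIFY = FALSE)
  if (any(genes$end <= genes$start))
    stopf("%s: empty transcript interval", path)
  if (anyDuplicated(genes$gene_id)) stopf("%s: duplicate gene_id", path)
  genes
}

#' @rdname read_bed12
#' @export
write_bed12 <- function(genes, path) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    paste(genes$chrom[i], format(genes$start[i], scientific = FALSE),
          format(genes$end[i], scientific = FALSE), genes$gene_id[i], 0,
          genes$strand[i], format(genes$thick_start[i], scientific = FALSE),
          format(genes$thick_end[i], scientific = FALSE), 0, length(es),
          paste0(paste(format(ee - es, scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          paste0(paste(format(es - genes$start[i], scientific = FALSE,
                              trim = TRUE), collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Read gene models from BED12 or a minimal GTF dialect
#'
#' GTF files (extension .gtf) are parsed for `exon` and `CDS` features
#' with a `gene_id` attribute; 1-based inclusive coordinates are
#' converted to 0-based half-open. Anything else is read as BED12.
#'
#' @param path file path.
#' @return gene-model data.frame (see [read_bed12()]).
#' @export
read_genes <- function(path) {
  if (!grepl("\\.gtf$", path, ignore.case = TRUE))
    return(read_bed12(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9))
    stopf("%s: line %d is not a 9-field GTF record",
          path, which(lengths(parts) < 9)[1])
  feat <- vapply(parts, `[`, "", 3)
  keep <- feat %in% c("exon", "CDS")
  parts <- parts[keep]; feat <- feat[keep]
  gid <- vapply(parts, function(p) {
    m <- regmatches(p[9], regexec('gene_id[ =]+"?([^";]+)"?', p[9]))[[1]]
    if (length(m) < 2) stopf("%s: GTF record lacks gene_id", path)
    m[2]
  }, "")
  chrom <- vapply(parts, `[`, "", 1)
  start <- as.numeric(vapply(parts, `[`, "", 4)) - 1  # to 0-based
  end <- as.numeric(vapply(parts, `[`, "", 5))
  strand <- vapply(parts, `[`, "", 7)
  out <- lapply(unique(gid), function(g) {
    i <- which(gid == g)
    ex <- i[feat[i] == "exon"]
    cds <- i[feat[i] == "CDS"]
    if (!length(ex)) stopf("%s: gene '%s' has no exon records", path, g)
    data.frame(gene_id = g, chrom = chrom[i[1]], start = min(start[ex]),
               end = max(end[ex]), strand = strand[i[1]],
               thick_start = if (length(cds)) min(start[cds]) else
                 min(start[ex]),
               thick_end = if (length(cds)) max(end[cds]) else
                 min(start[ex]),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, out)
  genes$exon_starts <- lapply(unique(gid), function(g) {
    i <- which(gid == g & feat == "exon"); sort(start[i])
  })
  genes$exon_ends <- lapply(unique(gid), function(g) {
    i <- which(gid == g & feat == "exon"); sort(end[i])
  })
  genes
}

#' Read / write region-by-sample methylation counts as TSV
#'
#' Wide format: a `region_id` column followed by `<sample>_meth` and
#' `<sample>_total` column pairs. Cells violating `meth <= total` are
#' reported by region and sample.
#'
#' @param path file path.
#' @param counts a [meth_counts()] object.
#' @return `read_counts`: a [meth_counts()] object.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "region_id") stopf("%s: first column must be region_id",
                                         path)
  if (anyDuplicated(df$region_id))
    stopf("%s: duplicate region_id '%s'", path,
          df$region_id[anyDuplicated(df$region_id)])
  cn <- names(df)[-1]
  meth_cols <- grep("_meth$", cn, value = TRUE)
  samples <- sub("_meth$", "", meth_cols)
  total_cols <- paste0(samples, "_total")
  if (!all(total_cols %in% cn))
    stopf("%s: missing *_total column(s) for sample(s) %s", path,
          paste(samples[!total_cols %in% cn], collapse = ", "))
  meth <- as.matrix(df[, meth_cols, drop = FALSE])
  total <- as.matrix(df[, total_cols, drop = FALSE])
  dimnames(meth) <- dimnames(total) <- list(df$region_id, samples)
  bad <- which(meth > total)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(meth))
    stopf("%s: meth > total at region '%s', sample '%s'", path,
          rownames(meth)[i[1]], colnames(meth)[i[2]])
  }
  meth_counts(meth, total)
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "meth_counts"))
  samples <- colnames(counts$meth)
  df <- data.frame(region_id = rownames(counts$meth),
                   stringsAsFactors = FALSE)
  for (s in samples) {
    df[[paste0(s, "_meth")]] <- counts$meth[, s]
    df[[paste0(s, "_total")]] <- counts$total[, s]
  }
  write_tsv(df, path)
}

#' Read a cytosine-level count table
#'
#' Long TSV with columns `chrom`, `pos` (0-based), `sample_id`, `meth`,
#' `total`.
#'
#' @param path file path.
#' @return data.frame for [collapse_to_regions()].
#' @export
read_cytosines <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "pos", "sample_id", "meth", "total")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  bad <- which(df$meth > df$total | df$meth < 0)
  if (length(bad))
    stopf("%s: invalid counts at line %d (meth=%s total=%s)", path,
          bad[1] + 1, df$meth[bad[1]], df$total[bad[1]])
  df
}

#' Read / write a sample sheet
#'
#' TSV with columns `sample_id`, `group`.
#'
#' @param path file path.
#' @param samplesheet data.frame `sample_id`, `group`.
#' @return `read_samplesheet`: the data.frame.
#' @export
read_samplesheet <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  check_samplesheet(df)
  df
}

#' @rdname read_samplesheet
#' @export
write_samplesheet <- function(samplesheet, path) {
  check_samplesheet(samplesheet)
  write_tsv(samplesheet[, c("sample_id", "group")], path)
}

#' Read / write a clinical cohort table as CSV
#'
#' All value columns are kept as character so that censored ("<1") and
#' missing ("NA") entries are preserved verbatim.
#'
#' @param path file path.
#' @param table cohort data.frame.
#' @return `read_cohort`: the data.frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, colClasses = "character",
                  na.strings = character(0), check.names = FALSE)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
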