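#' Region-by-sample methylation count matrix
#'
#' Container pairing two integer matrices of identical shape: methylated
#' read counts and total aligned read counts, rows indexed by region id
#' and columns by sample id. The invariant `0 <= meth <= total` holds for
#' every cell.
#'
#' @param meth,total numeric matrices with matching dimnames.
#' @return an object of class `meth_counts`.
#' @export
meth_counts <- function(meth, total) {
  if (!is.matrix(meth) || !is.matrix(total))
    stopf("'meth' and 'total' must be matrices")
  if (!identical(dim(meth), dim(total)))
    stopf("'meth' and 'total' must have identical dimensions")
  if (is.null(rownames(meth)) || is.null(colnames(meth)))
    stopf("count matrices need region_id rownames and sample colnames")
  if (!identical(dimnames(meth), dimnames(total)))
    stopf("'meth' and 'total' must have identical dimnames")
  if (anyNA(meth) || anyNA(total))
    stopf("count matrices must not contain NA")
  bad <- which(meth < 0 | total < 0 | meth > total)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(meth))
    stopf("invalid counts at region '%s', sample '%s': meth=%s total=%s",
          rownames(meth)[i[1]], colnames(meth)[i[2]],
          meth[bad[1]], total[bad[1]])
  }
  structure(list(meth = meth, total = total), class = "meth_counts")
}

#' @export
print.meth_counts <- function(x, ...) {
  cat(sprintf("meth_counts: %d regions x %d samples\n",
              nrow(x$meth), ncol(x$meth)))
  cat(sprintf("  total coverage: median %.0f reads/region/sample\n",
              stats::median(x$total)))
  invisible(x)
}

#' @export
dim.meth_counts <- function(x) dim(x$meth)

#' Subset a meth_counts object by region and/or sample
#'
#' @param x a [meth_counts()] object.
#' @param i,j region and sample indices (any matrix index form).
#' @param ... ignored.
#' @export
`[.meth_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$meth))
  if (missing(j)) j <- seq_len(ncol(x$meth))
  meth_counts(x$meth[i, j, drop = FALSE], x$total[i, j, drop = FALSE])
}
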