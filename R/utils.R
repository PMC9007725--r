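#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# Row variances with the n-1 denominator; NA cells excluded per row.
row_vars <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Stage-level progress notes go to stderr so they never pollute stdout output.
log_msg <- function(fmt, ...) message(sprintf(fmt, ...))

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stopf("'%s' must be an integer >= %s", name, min)
  invisible(as.integer(x))
}

assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("'%s' must be a number in [%s, %s]", name, lo, hi)
  invisible(as.numeric(x))
}
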