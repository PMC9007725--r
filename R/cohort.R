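# Clinical cohort descriptive statistics with censored ("<1") and
# missing ("NA") value handling, Welch t and Yates chi-square group
# comparisons.

#' Parse clinical values
#'
#' Turns raw table cells into typed clinical values: `"NA"` or empty
#' means MISSING, `"<x"` means censored below the bound x
#' (CENSORED_LT), and numeric text is NUMERIC. Decimal points are
#' accepted; thousands commas in integers are stripped.
#'
#' @param raw character vector of raw cell contents.
#' @param where label used in error messages (e.g. a column name).
#' @return data.frame with columns `state` (`NUMERIC`, `CENSORED_LT`,
#'   `MISSING`) and `value` (the number for NUMERIC, the bound for
#'   CENSORED_LT, NA for MISSING).
#' @export
parse_clinical_value <- function(raw, where = "value") {
  raw <- trimws(as.character(raw))
  state <- character(length(raw))
  value <- rep(NA_real_, length(raw))
  for (i in seq_along(raw)) {
    x <- raw[i]
    if (is.na(x) || x == "" || toupper(x) == "NA") {
      state[i] <- "MISSING"
    } else if (startsWith(x, "<")) {
      bound <- suppressWarnings(as.numeric(gsub(",", "", substring(x, 2))))
      if (is.na(bound) || bound <= 0)
        stopf("unparseable censored entry '%s' in %s (row %d)", x, where, i)
      state[i] <- "CENSORED_LT"
      value[i] <- bound
    } else {
      num <- suppressWarnings(as.numeric(gsub(",", "", x)))
      if (is.na(num))
        stopf("unparseable entry '%s' in %s (row %d)", x, where, i)
      state[i] <- "NUMERIC"
      value[i] <- num
    }
  }
  data.frame(state = state, value = value, stringsAsFactors = FALSE)
}

retained_values <- function(parsed, policy) {
  if (policy == "exclude") parsed$value[parsed$state == "NUMERIC"]
  else c(parsed$value[parsed$state == "NUMERIC"],
         parsed$value[parsed$state == "CENSORED_LT"] / 2)
}

#' Median and sample SD of clinical values
#'
#' Standard even/odd-n median and the n-1 denominator standard
#' deviation of the retained values. Under the default `exclude` policy
#' both MISSING and censored entries are dropped; under `substitute`
#' censored entries enter as half their bound.
#'
#' @param parsed a [parse_clinical_value()] data.frame.
#' @param policy `"exclude"` or `"substitute"`.
#' @return list `n_used`, `median`, `sample_sd` (NA when nothing is
#'   retained).
#' @export
descriptive_stats <- function(parsed, policy = c("exclude", "substitute")) {
  policy <- match.arg(policy)
  v <- retained_values(parsed, policy)
  if (!length(v))
    return(list(n_used = 0L, median = NA_real_, sample_sd = NA_real_))
  list(n_used = length(v), median = stats::median(v),
       sample_sd = if (length(v) > 1) stats::sd(v) else NA_real_)
}

#' Two-group comparison of a continuous clinical variable
#'
#' Two-sided Welch t-test on the retained values of both groups.
#'
#' @param parsed_a,parsed_b [parse_clinical_value()] data.frames.
#' @param policy censoring policy, as in [descriptive_stats()].
#' @return list `p`, `test_name`.
#' @export
compare_continuous <- function(parsed_a, parsed_b,
                               policy = c("exclude", "substitute")) {
  policy <- match.arg(policy)
  a <- retained_values(parsed_a, policy)
  b <- retained_values(parsed_b, policy)
  if (length(a) < 2 || length(b) < 2)
    stopf("need >= 2 retained values per group (have %d and %d)",
          length(a), length(b))
  res <- t_from_moments(mean(a), stats::var(a), length(a),
                        mean(b), stats::var(b), length(b), "welch")
  list(p = res$p, test_name = "welch_t")
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' `chi2 = n * (max(0, |ad - bc| - n/2))^2 / (r1 r2 c1 c2)` with 1
#' degree of freedom, two-sided; the continuity correction is floored so
#' that `|ad - bc| < n/2` gives chi2 = 0 and p = 1. A zero margin yields
#' p = 1 with a warning.
#'
#' @param a_yes,a_no,b_yes,b_no the 2x2 cell counts (group A/B by
#'   yes/no).
#' @return list `chi_sq`, `p`, `test_name`.
#' @export
compare_categorical <- function(a_yes, a_no, b_yes, b_no) {
  cells <- c(a_yes, a_no, b_yes, b_no)
  if (any(cells < 0)) stopf("cell counts must be non-negative")
  n <- sum(cells)
  if (n == 0) stopf("empty 2x2 table")
  r1 <- a_yes + a_no; r2 <- b_yes + b_no
  c1 <- a_yes + b_yes; c2 <- a_no + b_no
  if (any(c(r1, r2, c1, c2) == 0)) {
    warnf("zero margin in 2x2 table; p set to 1")
    return(list(chi_sq = 0, p = 1, test_name = "chisq_yates"))
  }
  num <- max(0, abs(a_yes * b_no - a_no * b_yes) - n / 2)
  chi_sq <- n * num^2 / (r1 * r2 * c1 * c2)
  list(chi_sq = chi_sq, p = stats::pchisq(chi_sq, df = 1, lower.tail = FALSE),
       test_name = "chisq_yates")
}

#' Summarise a clinical cohort table
#'
#' Per group (GH, NFPA): n, median and sample SD of age, maximum
#' diameter, Ki-67, p53 and number of surgeries; Welch t comparisons of
#' the continuous variables (p53 is summarised descriptively only);
#' Yates chi-square comparisons of sex and cavernous sinus invasion; and
#' invasion fractions per group (missing invasion entries count as
#' non-invasive, so fractions are yes/group-size).
#'
#' @param table cohort data.frame with the [generate_cohort_table()]
#'   column contract.
#' @param policy censoring policy for Ki-67-style "<1" entries; the
#'   default `exclude` drops them from medians/SDs.
#' @return object of class `cohort_summary`: list with `stats` (one row
#'   per variable and group), `tests` (one row per compared variable)
#'   and `invasion` (per-group counts and percentages).
#' @export
cohort_summary <- function(table, policy = c("exclude", "substitute")) {
  policy <- match.arg(policy)
  need <- c("id", "group", "sex", "age", "dmax_mm", "cavernous_invasion",
            "ki67_pct", "p53_pct", "n_surgeries")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stopf("cohort table lacks columns: %s", paste(miss, collapse = ", "))
  groups <- c("GH", "NFPA")
  if (!all(groups %in% table$group))
    stopf("cohort table must contain both GH and NFPA patients")

  vars <- c(age = "age", dmax = "dmax_mm", ki67 = "ki67_pct",
            p53 = "p53_pct", n_surgeries = "n_surgeries")
  parsed <- lapply(groups, function(g) {
    rows <- table[table$group == g, , drop = FALSE]
    lapply(vars, function(col) parse_clinical_value(rows[[col]], col))
  })
  names(parsed) <- groups

  stats_df <- do.call(rbind, lapply(names(vars), function(v) {
    do.call(rbind, lapply(groups, function(g) {
      st <- descriptive_stats(parsed[[g]][[v]], policy)
      data.frame(variable = v, group = g, n_used = st$n_used,
                 median = st$median, sample_sd = st$sample_sd,
                 stringsAsFactors = FALSE)
    }))
  }))

  tested <- setdiff(names(vars), "p53")
  tests_df <- do.call(rbind, lapply(tested, function(v) {
    ct <- compare_continuous(parsed$GH[[v]], parsed$NFPA[[v]], policy)
    data.frame(variable = v, p = ct$p, test_name = ct$test_name,
               stringsAsFactors = FALSE)
  }))

  n_by_group <- vapply(groups, function(g) sum(table$group == g), 0L)
  sex_m <- vapply(groups,
                  function(g) sum(table$sex[table$group == g] == "M"), 0L)
  sex_test <- compare_categorical(sex_m["GH"], n_by_group["GH"] - sex_m["GH"],
                                  sex_m["NFPA"],
                                  n_by_group["NFPA"] - sex_m["NFPA"])
  inv_yes <- vapply(groups, function(g)
    sum(table$cavernous_invasion[table$group == g] == "Yes", na.rm = TRUE),
    0L)
  inv_test <- compare_categorical(inv_yes["GH"],
                                  n_by_group["GH"] - inv_yes["GH"],
                                  inv_yes["NFPA"],
                                  n_by_group["NFPA"] - inv_yes["NFPA"])
  tests_df <- rbind(tests_df,
                    data.frame(variable = c("sex", "cavernous_invasion"),
                               p = c(sex_test$p, inv_test$p),
                               test_name = c(sex_test$test_name,
                                             inv_test$test_name),
                               stringsAsFactors = FALSE))

  invasion <- data.frame(group = groups, yes = as.integer(inv_yes),
                         n = as.integer(n_by_group),
                         fraction = as.numeric(inv_yes / n_by_group),
                         pct = as.numeric(100 * inv_yes / n_by_group),
                         stringsAsFactors = FALSE, row.names = NULL)

  structure(list(stats = stats_df, tests = tests_df, invasion = invasion,
                 n_by_group = n_by_group, policy = policy),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (%d GH, %d NFPA; censoring policy: %s)\n",
              x$n_by_group["GH"], x$n_by_group["NFPA"], x$policy))
  st <- x$stats
  st$median <- round(st$median, 2)
  st$sample_sd <- round(st$sample_sd, 2)
  print(st, row.names = FALSE)
  cat("\nGroup comparisons:\n")
  tst <- x$tests
  tst$p <- round(tst$p, 2)
  print(tst, row.names = FALSE)
  cat("\nCavernous sinus invasion:\n")
  inv <- x$invasion
  inv$pct <- round(inv$pct, 1)
  print(inv[, c("group", "yes", "n", "pct")], row.names = FALSE)
  invisible(x)
}
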