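as_contingency <- function(observed) {
  m <- as.matrix(observed)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("contingency table must be at least 2x2")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("observed counts must be non-negative integers")
  }
  if (sum(m) <= 0) stop("contingency table total must be positive")
  storage.mode(m) <- "double"
  m
}

#' Expected counts under independence
#'
#' `E[i,j] = rowsum_i * colsum_j / total`; expected margins equal observed
#' margins by construction.
#'
#' @param observed matrix of non-negative integer counts (at least 2x2).
#' @return Numeric matrix of expected counts.
#' @export
expected_counts <- function(observed) {
  m <- as_contingency(observed)
  outer(rowSums(m), colSums(m)) / sum(m)
}

#' Chi-square applicability check
#'
#' Two-tier rule on the expected counts: `invalid` when any expected count is
#' below 1 (the approximation is not usable and no test should be reported),
#' `valid_with_warning` when all are at least 1 but some are below 5, `valid`
#' otherwise. A table with an all-zero row or column is `invalid` outright.
#' The verdict depends only on the expected counts, so it is invariant under
#' row/column permutation.
#'
#' @param observed count matrix.
#' @return A `chisq_conditions`: list with `validity`, `reason`,
#'   `min_expected`.
#' @export
check_conditions <- function(observed) {
  m <- as_contingency(observed)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(structure(list(validity = "invalid",
                          reason = "table has an all-zero row or column",
                          min_expected = 0),
                     class = "chisq_conditions"))
  }
  e <- expected_counts(m)
  mn <- min(e)
  res <- if (mn < 1) {
    list(validity = "invalid",
         reason = sprintf("smallest expected count %.3g < 1; the data does not meet the conditions of the chi-square test", mn))
  } else if (mn < 5) {
    list(validity = "valid_with_warning",
         reason = sprintf("smallest expected count %.3g < 5; interpret with caution", mn))
  } else {
    list(validity = "valid", reason = "all expected counts >= 5")
  }
  structure(c(res, list(min_expected = mn)), class = "chisq_conditions")
}

new_contingency_result <- function(observed, statistic, df, yates, cond) {
  p <- if (is.na(statistic)) NA_real_ else stats::pchisq(statistic, df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = df, p_value = p,
                 yates_applied = yates,
                 observed = observed,
                 expected = if (cond$validity == "invalid" && cond$min_expected == 0)
                   NULL else expected_counts(observed),
                 validity = cond$validity, validity_reason = cond$reason,
                 min_expected = cond$min_expected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> X2 = %s, df = %d, p = %s%s [%s]\n",
              format(x$statistic), x$df, format(x$p_value),
              if (x$yates_applied) " (Yates' correction)" else "",
              x$validity))
  if (x$validity != "valid") cat("  ", x$validity_reason, "\n")
  invisible(x)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Continuity-corrected Pearson statistic
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` with 1 degree of freedom; the correction
#' is clamped at zero so near-null tables cannot have their statistic inflated.
#' The applicability verdict from [check_conditions()] is attached; the
#' statistic is still computed under `valid_with_warning`, but omitted when
#' the table is `invalid`.
#'
#' @param observed 2x2 count matrix.
#' @return A `contingency_result`.
#' @export
yates_chi2_2x2 <- function(observed) {
  m <- as_contingency(observed)
  if (!all(dim(m) == c(2L, 2L))) stop("Yates' correction applies to 2x2 tables only")
  cond <- check_conditions(m)
  stat <- if (cond$validity == "invalid") NA_real_ else {
    e <- expected_counts(m)
    sum(pmax(abs(m - e) - 0.5, 0)^2 / e)
  }
  new_contingency_result(m, stat, 1L, TRUE, cond)
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' `(r - 1)(c - 1)` degrees of freedom, used when comparing whole profile
#' distributions across conditions. No continuity correction is applied for
#' df > 1. Degenerate tables (all-zero row/column) or tables failing the
#' expected-count conditions get an `invalid` verdict with the statistic
#' omitted.
#'
#' @param observed r x c count matrix.
#' @return A `contingency_result`.
#' @export
contingency_chi2 <- function(observed) {
  m <- as_contingency(observed)
  cond <- check_conditions(m)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  stat <- if (cond$validity == "invalid") NA_real_ else {
    e <- expected_counts(m)
    sum((m - e)^2 / e)
  }
  new_contingency_result(m, stat, df, FALSE, cond)
}

#' Reconstruct a count from a printed percentage
#'
#' Published reports often print only a percentage and a group size;
#' `round(percent / 100 * n)` recovers the underlying count so contingency
#' tables can be rebuilt.
#'
#' @param percent percentage in `[0, 100]`.
#' @param n positive group size.
#' @return Integer count, with attributes `percent` and `n` recording the
#'   reconstruction inputs.
#' @export
proportions_from_percentages <- function(percent, n) {
  stopifnot(n > 0)
  if (any(percent < 0 | percent > 100)) stop("percent must lie in [0, 100]")
  structure(as.integer(round(percent / 100 * n)), percent = percent, n = n)
}

#' 2x2 enrichment table from two printed percentages
#'
#' Convenience wrapper: rows are the two groups, columns are
#' (with profile, without profile).
#'
#' @param percent_a,n_a percentage and size of the first group.
#' @param percent_b,n_b percentage and size of the second group.
#' @return 2x2 integer matrix.
#' @export
two_group_table <- function(percent_a, n_a, percent_b, n_b) {
  a <- proportions_from_percentages(percent_a, n_a)
  b <- proportions_from_percentages(percent_b, n_b)
  matrix(c(a, n_a - a, b, n_b - b), nrow = 2, byrow = TRUE,
         dimnames = list(c("group_a", "group_b"), c("with", "without")))
}
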