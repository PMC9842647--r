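# Cohort-level clinical statistics: 2x2 tests, IHC H-score, ROC.

as_2x2 <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (is.numeric(table) && length(table) == 4 && is.null(dim(table))) {
    table <- matrix(table, 2, 2)
  }
  if (!is.matrix(table) || !all(dim(table) == c(2, 2))) {
    abort("Expected a 2x2 table (matrix, data frame or length-4 vector).")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(table) == 0) abort("Table total must be positive.")
  table
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p by summation of hypergeometric point probabilities (with
#' fixed margins) not exceeding that of the observed table — the common
#' software convention, as implemented in [stats::fisher.test()]. A zero
#' margin gives p = 1.
#'
#' @param table 2x2 counts (matrix, data frame or length-4 vector read
#'   column-wise).
#' @return Two-sided p-value in \[0, 1\].
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  min(fisher.test(m)$p.value, 1)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Plain Pearson chi-square (no continuity correction by default) with
#' the 1-df upper-tail p. Zero expected counts are rejected with a
#' pointer to the Fisher test.
#'
#' @param table 2x2 counts.
#' @param yates Apply the Yates continuity correction.
#' @return List with `chi2` and `p_value`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  m <- as_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    abort("Zero expected count; use fisher_exact_2x2() instead.")
  }
  res <- suppressWarnings(chisq.test(m, correct = yates))
  list(chi2 = unname(res$statistic), p_value = unname(res$p.value))
}

#' IHC H-score from four staining-class percentages
#'
#' `H = 0 * negative + 1 * low_positive + 2 * positive +
#' 3 * high_positive`, on percentages summing to 100; the score ranges
#' from 0 to 300.
#'
#' @param fractions Length-4 numeric vector
#'   `(negative, low_positive, positive, high_positive)` in percent, or a
#'   data frame with those four columns (one score per row).
#' @param tol Allowed deviation of the percentage sum from 100.
#' @return Numeric H-score(s) in \[0, 300\].
#' @export
h_score <- function(fractions, tol = 0.01) {
  cls <- c("negative", "low_positive", "positive", "high_positive")
  if (is.data.frame(fractions)) {
    if (!all(cls %in% names(fractions))) {
      abort(sprintf("Data frame needs columns: %s.", paste(cls, collapse = ", ")))
    }
    m <- as.matrix(fractions[cls])
  } else {
    if (length(fractions) != 4) abort("`fractions` must have 4 entries.")
    m <- matrix(as.numeric(fractions), 1, 4)
  }
  if (any(m < 0) || any(m > 100)) {
    abort("Each class percentage must lie in [0, 100].")
  }
  sums <- rowSums(m)
  if (any(abs(sums - 100) > tol)) {
    abort(sprintf("Class percentages must sum to 100 (got %s).",
                  paste(signif(sums[abs(sums - 100) > tol], 6), collapse = ", ")))
  }
  as.numeric(m %*% c(0, 1, 2, 3))
}

#' ROC analysis: AUC and the Youden-optimal cutoff
#'
#' AUC by the rank (Mann-Whitney) statistic with midrank tie handling.
#' Candidate cutoffs are midpoints between adjacent distinct scores
#' (plus open ends); the reported cutoff maximizes Youden's
#' J = sensitivity + specificity - 1, ties resolved to the lowest
#' cutoff. A score counts as test-positive when it exceeds the cutoff.
#'
#' @param scores Numeric scores (e.g. H-scores).
#' @param outcome Binary outcome; 0/1, logical, or 2-level factor (the
#'   second level is the positive class).
#' @return A `roc_result`: list with `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `n_pos`, `n_neg` and the full `curve` tibble.
#' @export
roc_cutoff <- function(scores, outcome) {
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  outcome <- as.integer(as.logical(outcome))
  if (length(scores) != length(outcome)) {
    abort("`scores` and `outcome` lengths differ.")
  }
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both outcome classes must be present.")
  }
  r <- rank(scores)
  auc <- (sum(r[outcome == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  u <- sort(unique(scores))
  cuts <- if (length(u) > 1) {
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2)
  } else {
    u - 1
  }
  curve <- purrr::map_dfr(cuts, function(cc) {
    tibble(cutoff = cc,
           sensitivity = mean(scores[outcome == 1] > cc),
           specificity = mean(scores[outcome == 0] <= cc))
  })
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))[1]  # cuts ascending -> lowest cutoff wins ties
  structure(
    list(auc = auc, cutoff = curve$cutoff[best],
         sensitivity = curve$sensitivity[best],
         specificity = curve$specificity[best],
         n_pos = n_pos, n_neg = n_neg, curve = curve),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; cutoff = %g (sens %.3f, spec %.3f)\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Tabulate a cohort and test the 2x2 association
#'
#' Builds the 2x2 contingency table of a two-level clinical category
#' against a two-level grouping (e.g. marker high/low) and applies
#' the Fisher exact test when any expected count is below 5, otherwise
#' the plain Pearson chi-square — the conventional selection rule.
#'
#' @param records Data frame of per-subject records.
#' @param category_column,group_column Column names; both must be
#'   two-level after any prior binning (more levels are rejected).
#' @return A `cohort_test`: list with `table` (2x2 matrix), `test`
#'   (`"fisher"` or `"chi-square"`), `statistic` (chi2 or `NA`) and
#'   `p_value`.
#' @export
cohort_table <- function(records, category_column, group_column) {
  for (col in c(category_column, group_column)) {
    if (!col %in% names(records)) abort(sprintf("Column `%s` not found.", col))
    if (length(unique(records[[col]])) != 2) {
      abort(sprintf("Column `%s` must have exactly 2 levels; pre-bin it.", col))
    }
  }
  tab <- table(records[[category_column]], records[[group_column]])
  m <- matrix(as.numeric(tab), 2, 2, dimnames = dimnames(tab))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    structure(list(table = m, test = "fisher", statistic = NA_real_,
                   p_value = fisher_exact_2x2(m)), class = "cohort_test")
  } else {
    cs <- chi_square_2x2(m)
    structure(list(table = m, test = "chi-square", statistic = cs$chi2,
                   p_value = cs$p_value), class = "cohort_test")
  }
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("2x2 cohort test (%s): p = %.4f\n", x$test, x$p_value))
  print(x$table)
  invisible(x)
}
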