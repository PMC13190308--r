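# Contingency and correlation statistics used throughout the seeding
# analyses, with definitions fixed so that p-values recomputed from printed
# count tables reproduce the printed values.

as_table2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("expected a 2x2 table", call. = FALSE)
  if (any(m < 0) || sum(m) < 1) stop("invalid 2x2 table", call. = FALSE)
  m
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of
#' tables at most as probable as the one observed (the standard "small-p"
#' definition, as in [stats::fisher.test()]).
#'
#' @param table 2x2 matrix (rows = group, cols = outcome).
#' @return two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(32, 89, 19, 118), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  m <- as_table2x2(table)
  stats::fisher.test(m)$p.value
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Yates continuity correction is applied by default (df = 1).
#'
#' @param table 2x2 matrix.
#' @param yates apply the continuity correction.
#' @return p-value, or `NA` with a warning when an expected cell is 0.
#' @export
chi_squared <- function(table, yates = TRUE) {
  m <- as_table2x2(table)
  exp_cells <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_cells == 0)) {
    warning("expected cell count of 0; chi-squared undefined",
            call. = FALSE)
    return(NA_real_)
  }
  suppressWarnings(stats::chisq.test(m, correct = yates)$p.value)
}

#' Rank-based two-sample tests
#'
#' Paired = Wilcoxon signed-rank, unpaired = Mann–Whitney U. Exact
#' distributions are used up to n = 25 (without ties/zeros), the normal
#' approximation with tie correction beyond.
#'
#' @param x,y numeric vectors (equal length when `paired`).
#' @param paired paired test.
#' @param exact_max largest n for which the exact distribution is used.
#' @param alternative passed to [stats::wilcox.test()].
#' @return p-value; `NA` when all paired differences are tied at zero.
#' @export
rank_tests <- function(x, y, paired = FALSE, exact_max = 25L,
                       alternative = "two.sided") {
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    d <- d[!is.na(d)]
    if (!length(d) || all(d == 0)) return(NA_real_)
    n <- sum(d != 0)
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) return(NA_real_)
    n <- max(length(x), length(y))
  }
  suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = n <= exact_max,
                       correct = TRUE, alternative = alternative)$p.value
  )
}

#' Correlation with significance test
#'
#' @param x,y numeric vectors (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` and `p`; both `NA` when either input has zero
#'   variance.
#' @export
correlation_report <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value)
}
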