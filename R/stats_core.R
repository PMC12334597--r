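#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks. Symmetric in its arguments and
#' invariant under strictly monotone transforms of either one.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

mh_test <- function(statistic, p_value, df = NA_real_, method = "") {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 method = method), class = "mh_test")
}

#' @export
print.mh_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, format(x$df), x$p_value))
  invisible(x)
}

#' Two-sample t-test
#'
#' Two-sided two-sample t-test, pooled-variance (Student) by default, Welch
#' optionally. Degenerate input where both groups have zero variance and equal
#' means returns p = 1 by convention (no evidence of a difference); zero
#' pooled variance with unequal means is an error.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant \code{"student"} (pooled variance, default) or
#'   \code{"welch"}.
#' @return An \code{mh_test} with fields \code{statistic}, \code{df},
#'   \code{p_value}.
#' @export
t_test <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(mh_test(0, 1, length(a) + length(b) - 2, "t-test (degenerate)"))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  mh_test(unname(ht$statistic), ht$p.value, unname(ht$parameter),
          paste0(variant, " t-test"))
}

# Exact permutation distribution of the rank sum of group a. Ties get average
# ranks; enumeration is over all choose(n, n_a) assignments of the observed
# rank multiset, so ties are handled exactly.
wilcoxon_exact_p <- function(r, n_a) {
  idx <- utils::combn(length(r), n_a)
  sums <- colSums(matrix(r[idx], nrow = n_a))
  w <- sum(r[seq_len(n_a)])  # caller arranges a first
  lo <- mean(sums <= w + 1e-9)
  hi <- mean(sums >= w - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test. With a combined sample size of at most 12 the
#' p-value is exact, computed by enumerating every assignment of the observed
#' (average-tie) ranks to the two groups; larger samples use the normal
#' approximation with tie-corrected variance and continuity correction. All
#' values tied across both groups gives p = 1.
#'
#' @param a,b Non-empty numeric vectors.
#' @return An \code{mh_test}; the statistic is the rank sum of \code{a}.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  if (length(unique(c(a, b))) == 1L)
    return(mh_test(w, 1, method = "Wilcoxon rank-sum (all tied)"))
  if (n <= 12L)
    return(mh_test(w, wilcoxon_exact_p(r, n_a), method = "Wilcoxon rank-sum (exact)"))
  e_w <- n_a * (n + 1) / 2
  ties <- table(r)
  v <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(w - e_w) - 0.5) / sqrt(v)
  z <- max(z, 0)
  mh_test(w, 2 * stats::pnorm(-abs(z)), method = "Wilcoxon rank-sum (normal approx.)")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): rejecting all hypotheses with
#' q <= alpha reproduces the classical BH step-up rejection set at level
#' alpha. Output order matches input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

contingency_result <- function(table, test_name, statistic, df, p_value) {
  structure(list(table = table, test_name = test_name, statistic = statistic,
                 df = df, p_value = p_value), class = "mh_contingency")
}

#' @export
print.mh_contingency <- function(x, ...) {
  cat(sprintf("%s: p = %.4g", x$test_name, x$p_value))
  if (!is.na(x$statistic)) cat(sprintf(" (statistic = %.4g, df = %d)",
                                       x$statistic, x$df))
  cat("\n")
  invisible(x)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table. With \code{yates = TRUE}
#' (2x2 tables only) each |O - E| is reduced by min(0.5, |O - E|) before
#' squaring, so the corrected statistic is clamped at zero and cannot
#' overshoot.
#'
#' @param tab Integer matrix of non-negative counts with positive row and
#'   column sums.
#' @param yates Apply the continuity correction (2x2 only)?
#' @return An \code{mh_contingency} result.
#' @export
chi_square_test <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  if (yates && !all(dim(tab) == c(2L, 2L)))
    stop("Yates correction applies to 2x2 tables only")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  contingency_result(tab, if (yates) "chi_square_yates" else "chi_square",
                     unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of hypergeometric
#' point probabilities (over all tables with the observed margins) that do not
#' exceed the probability of the observed table. A zero margin gives p = 1 by
#' convention.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return An \code{mh_contingency} result (no statistic or df).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("fisher_exact requires a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(contingency_result(tab, "fisher_exact", NA_real_, NA_integer_, 1))
  p <- stats::fisher.test(tab)$p.value
  contingency_result(tab, "fisher_exact", NA_real_, NA_integer_, min(1, p))
}
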