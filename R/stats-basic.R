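#' Basic inferential tests with a uniform tidy interface
#'
#' Thin wrappers over the standard tests used throughout the analyses:
#' unpaired Student's t, two-sample Kolmogorov-Smirnov, 2x2 chi-square
#' (no continuity correction by default), exact binomial, and Pearson
#' correlation with a two-sided p-value. Each returns a one-row-style list
#' with `statistic`, `df` (where defined) and `p`.
#'
#' @name basic_tests
NULL

#' @rdname basic_tests
#' @param x,y Numeric samples.
#' @param var_equal Assume equal variances (classical unpaired t-test).
#' @export
unpaired_t_test <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("t-test undefined: both samples have zero variance")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' @rdname basic_tests
#' @export
ks_test_2s <- function(x, y) {
  ht <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @rdname basic_tests
#' @param tab 2x2 contingency matrix.
#' @param correct Apply Yates continuity correction.
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  stopifnot(all(dim(tab) == c(2, 2)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("chi-square undefined: expected cell count 0")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' @rdname basic_tests
#' @param successes,n Successes and trials.
#' @param p0 Null success probability.
#' @export
binom_test_exact <- function(successes, n, p0 = 0.5) {
  ht <- stats::binom.test(successes, n, p = p0)
  list(statistic = successes, p = ht$p.value)
}

#' @rdname basic_tests
#' @export
pearson_cor_test <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined: zero-variance input")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(statistic = unname(ht$estimate), df = unname(ht$parameter),
       p = ht$p.value)
}
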