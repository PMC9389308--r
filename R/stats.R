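# Thin, contract-checked wrappers around the standard tests the comparison
# uses. Kept as named operations so the pipeline's statistical choices (no
# continuity correction by default, mid-rank ties, U = min(U_a, U_b)) are
# explicit and testable against brute-force oracles.

#' Round half away from zero
#'
#' Display rounding for percentages: 26.5 rounds to 27, unlike base
#' `round()`'s round-half-even. Full precision is always retained
#' internally; this is applied only at report time.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expected counts from the
#' row/column margins, `df = (r-1)(c-1)`, p-value from the upper tail of
#' the chi-squared distribution. No continuity correction by default
#' (`correct = TRUE` enables Yates' correction for 2x2 tables).
#'
#' @param contingency matrix of non-negative integer counts.
#' @param correct apply Yates' continuity correction (2x2 only).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(contingency, correct = FALSE) {
  m <- as.matrix(contingency)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("contingency table must contain non-negative integers")
  }
  if (sum(m) <= 0) stop("contingency table has zero grand total")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero row/column margin: collapse the empty categories before testing")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho, or `NA` with a warning when either vector is constant
#'   (the correlation is undefined).
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman correlation undefined for a constant vector")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. `U` is reported as
#' `min(U_a, U_b)` with mid-rank handling of ties. The p-value is exact
#' (from the null U distribution) when both samples have at most 20
#' observations and no ties are present; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b non-empty numeric vectors.
#' @return list with `U` (the smaller of the two U statistics), `U_a`
#'   (wins of `a` over `b`), `p_value` (two-sided), and `method`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_b <- n1 * n2 - u_a
  u <- min(u_a, u_b)
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (max(n1, n2) <= 20 && !has_ties) {
    method <- "exact"
    p <- min(1, 2 * stats::pwilcox(u, n1, n2))
  } else {
    method <- "normal approximation with tie correction"
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {  # all observations identical
      p <- 1
    } else {
      zstat <- (u - mu + 0.5) / sqrt(sigma2)  # u <= mu, continuity-corrected
      p <- min(1, 2 * stats::pnorm(zstat))
    }
  }
  list(U = u, U_a = u_a, p_value = p, method = method)
}
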