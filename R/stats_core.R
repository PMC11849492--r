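#' Spearman rank correlation with t-approximation p-value
#'
#' Computes the Spearman correlation coefficient (SCC) as the Pearson
#' correlation of midranks, with a two-sided p-value from the
#' t-approximation on n - 2 degrees of freedom. This is the rank statistic
#' used throughout the diversity and module association stages.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return A list with elements `rho`, `p_value`, `n`.
#' @examples
#' spearman_rho(1:10, (1:10)^3)$rho  # 1: invariant to monotone transforms
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("zero rank variance")
  rho <- stats::cor(rx, ry)
  list(rho = rho, p_value = .t_pvalue(rho, df = n - 2), n = n)
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Partial Spearman correlation: all three vectors are midrank-transformed,
#' then the partial Pearson correlation of the x and y ranks controlling the
#' covariate ranks is computed. Two-sided p from the t-approximation on
#' n - 3 degrees of freedom. Used for the "age adjusted" associations of
#' alpha diversity and KO abundances with SIPs.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param covariate Numeric covariate to adjust for (typically age).
#' @return A list with elements `rho`, `p_value`, `n`.
#' @export
adjusted_spearman <- function(x, y, covariate) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(covariate)
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("all inputs must have equal length")
  if (n < 4) stop("need at least 4 observations for a covariate-adjusted correlation")
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("missing values not allowed")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0)
    stop("zero rank variance")
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= .Machine$double.eps)
    stop("covariate ranks are collinear with x or y ranks")
  rho <- (rxy - rxz * ryz) / sqrt(den)
  rho <- max(-1, min(1, rho))
  list(rho = rho, p_value = .t_pvalue(rho, df = n - 3), n = n)
}

.t_pvalue <- function(rho, df) {
  if (df < 1) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = df)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for a difference between two independent groups. The exact
#' null distribution is used whenever n1 + n2 <= 16 and there are no ties;
#' otherwise a tie-corrected normal approximation with continuity correction.
#' The U statistic is the number of (a, b) pairs with a > b (ties counted
#' half), so U = 0 when every value of `a` is below every value of `b`.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param alternative Only `"two_sided"` is supported.
#' @return A list with `u_statistic`, `p_value`, `n1`, `n2`, `method`
#'   (`"exact"` or `"normal_tie_corrected"`).
#' @export
mann_whitney_u <- function(a, b, alternative = "two_sided") {
  alternative <- match.arg(alternative, "two_sided")
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  n1 <- length(a); n2 <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (n1 + n2 <= 16) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(u_statistic = unname(wt$statistic),
       p_value = min(1, wt$p.value),
       n1 = n1, n2 = n2,
       method = if (use_exact) "exact" else "normal_tie_corrected")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control. Rejecting all tests with q < t is
#' equivalent to the BH step-up procedure at level t.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]; no missing values.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' 75th percentile with linear interpolation
#'
#' The per-sample summary statistic of a co-abundance gene group: the 75th
#' percentile across member genes, using linear interpolation at index
#' h = (n - 1) * 0.75 between adjacent order statistics.
#'
#' @param values Non-empty numeric vector.
#' @return The interpolated 75th percentile.
#' @export
percentile_75 <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0) stop("cannot take a percentile of an empty vector")
  if (anyNA(v)) stop("missing values not allowed")
  unname(stats::quantile(v, probs = 0.75, type = 7))
}
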