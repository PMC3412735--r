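#' Group summary: n, mean, sample SD
#'
#' Mean and sample standard deviation (n - 1 denominator), the form used
#' for the per-meal transit-time summaries.
#'
#' @param values Numeric vector, length >= 2.
#' @return An object of class `group_summary` with fields `n`, `mean`,
#'   `sd`.
#' @examples
#' group_summary(c(119, 100, 83, 91, 92, 112))
#' @export
group_summary <- function(values) {
  values <- as.double(values)
  if (length(values) < 2) stop("group_summary needs n >= 2")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite")
  n <- length(values)
  m <- sum(values) / n
  s <- sqrt(sum((values - m)^2) / (n - 1))
  structure(list(n = n, mean = m, sd = s), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, sd = %.4g\n", x$n, x$mean, x$sd))
  invisible(x)
}

# --- Student t distribution via the regularized incomplete beta ----------
# Implemented from the continued-fraction expansion (modified Lentz) so the
# p-value does not depend on the host's statistical runtime; stats::pt is
# used only as an independent cross-check in the tests.

beta_cf <- function(x, a, b, max_iter = 300, eps = 1e-15) {
  tiny <- 1e-300
  qab <- a + b; qap <- a + 1; qam <- a - 1
  c_ <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < tiny) d <- tiny
  d <- 1 / d
  h <- d
  for (m in seq_len(max_iter)) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
    c_ <- 1 + aa / c_; if (abs(c_) < tiny) c_ <- tiny
    d <- 1 / d
    h <- h * d * c_
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
    c_ <- 1 + aa / c_; if (abs(c_) < tiny) c_ <- tiny
    d <- 1 / d
    del <- d * c_
    h <- h * del
    if (abs(del - 1) < eps) return(h)
  }
  stop("incomplete beta continued fraction failed to converge")
}

# regularized incomplete beta I_x(a, b)
reg_inc_beta <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  bt <- exp(a * log(x) + b * log1p(-x) - lbeta(a, b))
  if (x < (a + 1) / (a + b + 2)) bt * beta_cf(x, a, b) / a
  else 1 - bt * beta_cf(1 - x, b, a) / b
}

#' Student t cumulative distribution function
#'
#' `P(T <= q)` for `T ~ t(df)`, evaluated through the regularized
#' incomplete beta function (continued-fraction expansion).
#'
#' @param q Quantile(s).
#' @param df Degrees of freedom (> 0).
#' @return Cumulative probabilities.
#' @export
t_cdf <- function(q, df) {
  if (df <= 0) stop("df must be positive")
  vapply(q, function(qi) {
    if (!is.finite(qi)) return(if (qi > 0) 1 else 0)
    tail <- 0.5 * reg_inc_beta(df / (df + qi^2), df / 2, 0.5)
    if (qi >= 0) 1 - tail else tail
  }, numeric(1))
}

#' Paired Student t test
#'
#' Two-sided paired t test on elementwise differences `a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, with the p-value
#' computed from [t_cdf()].  Two-sided because "significant difference"
#' carries no stated direction.
#'
#' @param a,b Paired numeric vectors of equal length `n >= 2`.
#' @return An object of class `paired_t_test` with `t_statistic`, `df`,
#'   `p_value`, `mean_difference`, `n`.
#' @examples
#' tab <- gi_table1()
#' paired_t_test(tab$solid_mget, tab$liquid_mget)
#' @export
paired_t_test <- function(a, b) {
  a <- as.double(a); b <- as.double(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("paired t test needs n >= 2")
  d <- a - b
  md <- mean(d)
  sdd <- sqrt(sum((d - md)^2) / (n - 1))
  if (sdd == 0) stop("degenerate paired differences: all differences equal")
  tstat <- md / (sdd / sqrt(n))
  df <- n - 1
  p <- reg_inc_beta(df / (df + tstat^2), df / 2, 0.5)  # = 2 * upper tail
  structure(list(t_statistic = tstat, df = df, p_value = p,
                 mean_difference = md, n = n),
            class = "paired_t_test")
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat(sprintf("Paired t test: t = %.4g, df = %d, two-sided p = %.4g (mean difference %.4g, n = %d)\n",
              x$t_statistic, x$df, x$p_value, x$mean_difference, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' `r = sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))` with `dx`, `dy` the
#' centered vectors.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both nonconstant.
#' @return r in `[-1, 1]`.
#' @examples
#' pearson_correlation(1:10, 2 * (1:10) + 1)
#' @export
pearson_correlation <- function(x, y) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("pearson_correlation needs n >= 3")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("pearson_correlation is undefined for constant input")
  sum(dx * dy) / sqrt(sxx * syy)
}

#' Repeatability coefficient of variation
#'
#' `100 * sd / mean` across repeated same-animal sessions, the figure
#' used to express session-to-session biological variability of the
#' transit times.
#'
#' @param repeats Numeric vector of repeated measurements, `n >= 2`,
#'   positive mean.
#' @return CV in percent.
#' @examples
#' repeatability_cv(c(90, 100, 110))
#' @export
repeatability_cv <- function(repeats) {
  g <- group_summary(repeats)
  if (g$mean <= 0) stop("repeatability_cv needs a positive mean")
  100 * g$sd / g$mean
}
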