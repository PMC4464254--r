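# Group-level inferential statistics: Pearson and partial correlation,
# Sobel mediation, Bonferroni thresholds.

.cor_report <- function(r, p, n, alpha, m_tests) {
  adj <- bonferroni_alpha(alpha, m_tests)
  structure(list(r = r, p = p, n = n, alpha = alpha, m_tests = m_tests,
                 adjusted_alpha = adj, significant = p < adj),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.4g (n = %d, adjusted alpha = %.4g)%s\n",
              x$r, x$p, x$n, x$adjusted_alpha,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pearson correlation report
#'
#' Product-moment correlation with a two-tailed t-based p-value, annotated
#' with the Bonferroni-adjusted alpha for its test family.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @param alpha family-wise alpha level (default 0.05).
#' @param m_tests number of tests in the Bonferroni family (default 1).
#' @return A `correlation_report`: `r`, `p`, `n`, `adjusted_alpha`,
#'   `significant`.
#' @export
pearson <- function(x, y, alpha = 0.05, m_tests = 1L) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must be equal-length vectors with n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y)
  .cor_report(unname(ct$estimate), ct$p.value, length(x), alpha, m_tests)
}

#' Partial correlation controlling for one covariate
#'
#' First-order partial correlation
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
#' with a two-tailed t-based p on n - 3 degrees of freedom. Equivalent to
#' the Pearson correlation of the two covariate-residualized vectors.
#'
#' @param x,y numeric vectors.
#' @param z covariate vector.
#' @inheritParams pearson
#' @return A `correlation_report`.
#' @export
partial_correlation <- function(x, y, z, alpha = 0.05, m_tests = 1L) {
  n <- length(x)
  if (n < 4L || length(y) != n || length(z) != n)
    stop("x, y, z must be equal-length vectors with n >= 4")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate covariate: z is collinear with x or y")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  df <- n - 3
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  .cor_report(r, p, n, alpha, m_tests)
}

#' Sobel test of mediation
#'
#' Fits the Baron-Kenny chain: path `a` from regressing the mediator `m` on
#' `x`, path `b` from regressing `y` on `m` and `x`. The indirect effect is
#' a*b and the Sobel statistic is
#' z = a*b / sqrt(b^2 SEa^2 + a^2 SEb^2), with a two-tailed normal p.
#'
#' @param x independent variable.
#' @param m mediator.
#' @param y outcome.
#' @return An object of class `mediation_report`: `a`, `se_a`, `b`, `se_b`,
#'   `indirect` (= a*b), `sobel_z`, `p`, `n`.
#' @export
sobel_mediation <- function(x, m, y) {
  n <- length(x)
  if (n < 5L || length(m) != n || length(y) != n)
    stop("x, m, y must be equal-length vectors with n >= 5")
  fa <- stats::lm(m ~ x)
  fb <- stats::lm(y ~ m + x)
  if (any(!is.finite(coef(fa))) || any(!is.finite(coef(fb))))
    stop("mediation regressions are not estimable (collinearity)")
  sa <- summary(fa)$coefficients
  sb <- summary(fb)$coefficients
  a <- sa["x", "Estimate"];  se_a <- sa["x", "Std. Error"]
  b <- sb["m", "Estimate"];  se_b <- sb["m", "Std. Error"]
  zz <- (a * b) / sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  if (!is.finite(zz)) zz <- 0          # a = b = 0 exactly: no indirect effect
  structure(list(a = a, se_a = se_a, b = b, se_b = se_b, indirect = a * b,
                 sobel_z = zz, p = 2 * stats::pnorm(-abs(zz)), n = n),
            class = "mediation_report")
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf("Sobel mediation: a = %.3f (SE %.3f), b = %.3f (SE %.3f)\n",
              x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  indirect = %.4f, Sobel z = %.3f, p = %.4g (n = %d)\n",
              x$indirect, x$sobel_z, x$p, x$n))
  invisible(x)
}

#' Bonferroni-adjusted alpha level
#'
#' @param alpha family-wise alpha.
#' @param m number of tests in the family (>= 1).
#' @return alpha / m.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("number of tests must be >= 1")
  alpha / m
}
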