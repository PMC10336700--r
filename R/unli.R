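#' One-dimensional unit normal loss integral
#'
#' E(max(Y, 0)) for Y ~ N(mu, sigma^2):
#' `mu * (1 - Phi(-mu/sigma)) + sigma * phi(-mu/sigma)`. For two-strategy
#' decision problems with incremental net benefit Y, the EVPI is
#' `unli_1d(p) - max(mu, 0)`.
#'
#' @param mu Mean, or a [gaussian_params()] object.
#' @param sigma Standard deviation (> 0); ignored when `mu` is a
#'   `gaussian_params` object.
#' @return E(max(Y, 0)), a positive scalar bounded below by max(mu, 0).
#' @examples
#' unli_1d(0, 1)                  # 1/sqrt(2*pi)
#' unli_1d(gaussian_params(1, 2))
#' @export
unli_1d <- function(mu, sigma = NULL) {
  p <- if (inherits(mu, "gaussian_params")) mu else gaussian_params(mu, sigma)
  z <- p$mu / p$sigma
  p$mu * pnorm(z) + p$sigma * dnorm(z)
}

# Tolerance under which sigma_i - rho*sigma_j counts as the exact-zero
# (degenerate) branch of the closed form. Either branch agrees far below
# this scale (the total is continuous in rho), so the cutoff is not
# delicate; it only decides which decomposition is reported.
.degenerate_tol <- function(si, sj) 1e-12 * max(si, sj)

# Closed-form terms for one ordered pair (i, j):
#   r + q = E[ Y_i * 1{Y_i > 0, Y_i > Y_j} ].
# Derivation: condition on the joint event {Y_i > 0, Y_i - Y_j > 0}. With
# tau^2 = Var(Y_i - Y_j), the correlation between Y_i and Y_i - Y_j is
# r = (sigma_i - rho*sigma_j)/tau, whose sign is the branch indicator
# delta. The expectation of a standard normal over an upper bivariate
# orthant is phi(h)*Phi((r*h-k)/sqrt(1-r^2)) + r*phi(k)*Phi((r*k-h)/sqrt(1-r^2)),
# which yields the non-degenerate r/q split below; when r = 0 the event
# factorises and the pair contributes Phi(c1) times the 1-D loss integral.
.pair_terms <- function(mui, muj, si, sj, rho) {
  dif <- si - rho * sj
  s1mr2 <- sqrt((1 - rho) * (1 + rho))
  if (abs(dif) <= .degenerate_tol(si, sj)) {
    c1 <- (rho * sj * mui - si * muj) / (si * sj * s1mr2)
    r_term <- pnorm(c1) * unli_1d(gaussian_params(mui, si))
    return(list(delta = 0L, r = r_term, q = 0, degenerate = TRUE))
  }
  delta <- if (dif > 0) 1L else -1L
  tau <- sqrt(si^2 + sj^2 - 2 * rho * si * sj)
  a <- mui / si
  b <- (mui - muj) / tau
  r <- dif / tau
  s1r <- sqrt((1 - r) * (1 + r))          # = sj * sqrt(1 - rho^2) / tau
  c1 <- (b - r * a) / s1r                 # = (rho*sj*mui - si*muj)/(si*sj*sqrt(1-rho^2))
  c2 <- (a - r * b) / s1r
  r_term <- mui * (delta > 0) + pnorm(c1) * (si * dnorm(a) - mui * pnorm(-a))
  q_term <- mui * (bvn_cdf(a, b, r) - (delta > 0) + pnorm(-a) * pnorm(c1)) +
    si * r * dnorm(b) * pnorm(c2)
  list(delta = delta, r = r_term, q = q_term, degenerate = FALSE)
}

#' Term decomposition of the two-dimensional unit normal loss integral
#'
#' Evaluates, for each ordered pair (i, j) in \{(1,2), (2,1)\}, the branch
#' indicator delta = sign(sigma_i - rho*sigma_j) and the two closed-form
#' terms r and q whose four-way sum is E(max(Y1, Y2, 0)). The pair (i, j)
#' contributes E\[Y_i 1\{Y_i > 0, Y_i > Y_j\}\] = r + q. When
#' sigma_i - rho*sigma_j is numerically zero (within `1e-12 * max(sigma)`)
#' the degenerate branch is taken: the whole contribution moves into r,
#' q is zero and delta is reported as 0.
#'
#' @param p A [bvn_params()] object.
#' @return A data frame with one row per ordered pair and columns `i`, `j`,
#'   `delta`, `r`, `q`, `degenerate`; attribute `"value"` holds the total
#'   E(max(Y1, Y2, 0)) (the exact sum of the four terms).
#' @export
unli_2d_terms <- function(p) {
  p <- as_bvn_params(p)
  t12 <- .pair_terms(p$mu1, p$mu2, p$sigma1, p$sigma2, p$rho)
  t21 <- .pair_terms(p$mu2, p$mu1, p$sigma2, p$sigma1, p$rho)
  out <- data.frame(
    i = c(1L, 2L),
    j = c(2L, 1L),
    delta = c(t12$delta, t21$delta),
    r = c(t12$r, t21$r),
    q = c(t12$q, t21$q),
    degenerate = c(t12$degenerate, t21$degenerate)
  )
  attr(out, "value") <- sum(out$r) + sum(out$q)
  class(out) <- c("unli_terms", "data.frame")
  out
}

#' @export
print.unli_terms <- function(x, ...) {
  cat("2-D UNLI term decomposition (E(max(Y1, Y2, 0)) = sum of r and q)\n")
  print.data.frame(x, row.names = FALSE, digits = 10)
  cat(sprintf("total: %.10g\n", attr(x, "value")))
  invisible(x)
}

#' Two-dimensional unit normal loss integral
#'
#' Closed-form E(max(Y1, Y2, 0)) for bivariate normal (Y1, Y2): the sum of
#' the four terms of [unli_2d_terms()]. Symmetric under swapping the two
#' components, bounded below by max(0, mu1, mu2) and by each marginal
#' [unli_1d()], and non-decreasing in each mean.
#'
#' @param p A [bvn_params()] object.
#' @return E(max(Y1, Y2, 0)), a scalar.
#' @examples
#' unli_2d(bvn_params(0, 0, 1, 1, 0))    # 2-D analogue of 1/sqrt(2*pi)
#' @export
unli_2d <- function(p) {
  attr(unli_2d_terms(p), "value")
}

#' Expected value of perfect information from bivariate-normal parameters
#'
#' For a three-strategy decision problem whose two incremental net benefits
#' (against the common reference) are bivariate normal, the expected net
#' benefit under perfect information is E(max(Y1, Y2, 0)) while deciding on
#' current evidence yields max(mu1, mu2, 0); the EVPI is their difference.
#'
#' @param p A [bvn_params()] object describing the incremental net benefits.
#' @return EVPI, a non-negative scalar in the units of the net benefits.
#' @examples
#' # Three inhaler strategies, pooled parameters at WTP $50,000/QALY:
#' evpi_from_bvn(bvn_params(-4734, -2668, 4678, 4645, 0.50))  # ~1019
#' @export
evpi_from_bvn <- function(p) {
  p <- as_bvn_params(p)
  max(unli_2d(p) - max(p$mu1, p$mu2, 0), 0)
}
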