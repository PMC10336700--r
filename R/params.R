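#' Normal parameter containers
#'
#' `gaussian_params()` describes one (incremental) net benefit as
#' N(mu, sigma^2); `bvn_params()` describes the pair of incremental net
#' benefits of two alternative strategies against a common reference as a
#' bivariate normal with means `mu1`, `mu2`, standard deviations `sigma1`,
#' `sigma2` and correlation `rho`. Units are opaque (typically currency).
#'
#' Standard deviations must be strictly positive and `|rho| < 1` strictly:
#' the closed form divides by `sqrt(1 - rho^2)` and the perfectly
#' correlated / degenerate cases are rejected rather than taken as limits.
#'
#' @param mu,mu1,mu2 Means.
#' @param sigma,sigma1,sigma2 Standard deviations (> 0).
#' @param rho Correlation in the open interval (-1, 1).
#' @return An object of class `"gaussian_params"` or `"bvn_params"`.
#' @examples
#' bvn_params(-4734, -2668, 4678, 4645, 0.50)
#' @export
gaussian_params <- function(mu, sigma) {
  structure(
    list(mu = check_number(mu, "mu"), sigma = check_positive(sigma, "sigma")),
    class = "gaussian_params"
  )
}

#' @rdname gaussian_params
#' @export
bvn_params <- function(mu1, mu2, sigma1, sigma2, rho) {
  rho <- check_number(rho, "rho")
  if (abs(rho) >= 1)
    fail_validation("rho must lie strictly inside (-1, 1), got ", rho)
  structure(
    list(
      mu1 = check_number(mu1, "mu1"),
      mu2 = check_number(mu2, "mu2"),
      sigma1 = check_positive(sigma1, "sigma1"),
      sigma2 = check_positive(sigma2, "sigma2"),
      rho = rho
    ),
    class = "bvn_params"
  )
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat(sprintf("Normal net-benefit parameters: mu = %g, sigma = %g\n",
              x$mu, x$sigma))
  invisible(x)
}

#' @export
print.bvn_params <- function(x, ...) {
  cat("Bivariate-normal incremental net benefits\n")
  cat(sprintf("  mu    = (%g, %g)\n", x$mu1, x$mu2))
  cat(sprintf("  sigma = (%g, %g)\n", x$sigma1, x$sigma2))
  cat(sprintf("  rho   = %g\n", x$rho))
  invisible(x)
}

as_bvn_params <- function(x) {
  if (inherits(x, "bvn_params")) return(x)
  fail_validation("expected a 'bvn_params' object")
}
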