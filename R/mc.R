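#' Monte-Carlo estimate of E(max(Y1, Y2, 0))
#'
#' Independent verification oracle for the closed form: draws `n` bivariate
#' normal pairs via the lower-triangular (Cholesky) factor of the
#' covariance, `Y = mu + L Z`, and averages max(Y1, Y2, 0). The random
#' stream is seeded explicitly per call and the caller's RNG state is left
#' untouched, so results are bit-reproducible.
#'
#' @param p A [bvn_params()] object.
#' @param n Number of draws (>= 2).
#' @param seed Integer seed for this call's private stream.
#' @param keep_draws Keep the n x 2 matrix of draws (for diagnostics)?
#' @return An object of class `"mc_estimate"`: list with `mean`, `se`
#'   (sample standard deviation of the positive-part maxima divided by
#'   sqrt(n)), `n` and `seed`, plus `draws` if requested.
#' @examples
#' mc_max_expectation(bvn_params(0, 0, 1, 1, 0), n = 1e4, seed = 1)
#' @export
mc_max_expectation <- function(p, n, seed, keep_draws = FALSE) {
  p <- as_bvn_params(p)
  n <- check_count(n, "n", min = 2L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  z <- withr::with_seed(seed, matrix(rnorm(2 * n), ncol = 2))
  y1 <- p$mu1 + p$sigma1 * z[, 1]
  y2 <- p$mu2 + p$sigma2 * (p$rho * z[, 1] + sqrt(1 - p$rho^2) * z[, 2])
  m <- pmax(y1, y2, 0)
  out <- list(mean = mean(m), se = sd(m) / sqrt(n), n = n, seed = seed)
  if (keep_draws) out$draws <- cbind(y1 = y1, y2 = y2)
  structure(out, class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("MC estimate of E(max(Y,0)): %.6g (SE %.3g, n = %d, seed = %d)\n",
              x$mean, x$se, x$n, x$seed))
  invisible(x)
}
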