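#' Factorial verification grid
#'
#' The 252-setting factorial design used to verify the closed form against
#' Monte Carlo: means in \{-2, 0, 2\}, variances in \{1, 3\} and
#' correlations in \{-0.75, -0.50, ..., 0.50, 0.75\}
#' (3 x 3 x 2 x 2 x 7 = 252). Rows are ordered lexicographically by
#' (mu1, mu2, var1, var2, rho).
#'
#' @return A 252-row data frame with columns `mu1`, `mu2`, `var1`, `var2`,
#'   `rho`.
#' @export
build_grid <- function() {
  g <- expand.grid(
    rho = c(-0.75, -0.50, -0.25, 0, 0.25, 0.50, 0.75),
    var2 = c(1, 3),
    var1 = c(1, 3),
    mu2 = c(-2, 0, 2),
    mu1 = c(-2, 0, 2),
    KEEP.OUT.ATTRS = FALSE
  )
  g <- g[, c("mu1", "mu2", "var1", "var2", "rho")]
  rownames(g) <- NULL
  g
}

#' Run the closed-form vs Monte-Carlo verification study
#'
#' Evaluates the closed-form 2-D UNLI and a seeded Monte-Carlo estimate at
#' every setting of [build_grid()] and reports the standardised discrepancy
#' z = (closed_form - mc_mean) / mc_se. The seed for setting k is
#' `base_seed + k`, giving independent, individually reproducible streams.
#' At N = 100,000 the full grid takes on the order of ten seconds.
#'
#' Statistical reading: if the closed form is exact, the z values behave
#' like standard normal draws; with 252 comparisons, |z| <= 4 everywhere
#' and at most a couple of exceedances of 3 is the expected picture.
#'
#' @param n Monte-Carlo draws per setting (>= 1000).
#' @param base_seed Integer base seed.
#' @return A data frame of class `"unli_verification"` with columns `mu1`,
#'   `mu2`, `var1`, `var2`, `rho`, `closed_form`, `mc_mean`, `mc_se`, `z`;
#'   attributes `n` and `base_seed`.
#' @export
run_verification <- function(n = 100000, base_seed = 1) {
  n <- check_count(n, "n", min = 1000L)
  base_seed <- check_count(base_seed, "base_seed", min = -.Machine$integer.max)
  g <- build_grid()
  cf <- mc_mean <- mc_se <- numeric(nrow(g))
  for (k in seq_len(nrow(g))) {
    p <- bvn_params(g$mu1[k], g$mu2[k],
                    sqrt(g$var1[k]), sqrt(g$var2[k]), g$rho[k])
    cf[k] <- unli_2d(p)
    est <- mc_max_expectation(p, n, seed = base_seed + k)
    mc_mean[k] <- est$mean
    mc_se[k] <- est$se
  }
  out <- cbind(g, closed_form = cf, mc_mean = mc_mean, mc_se = mc_se,
               z = (cf - mc_mean) / mc_se)
  attr(out, "n") <- n
  attr(out, "base_seed") <- base_seed
  class(out) <- c("unli_verification", "data.frame")
  out
}

#' @export
summary.unli_verification <- function(object, ...) {
  z <- object$z
  res <- list(
    settings = nrow(object),
    n = attr(object, "n"),
    base_seed = attr(object, "base_seed"),
    max_abs_z = max(abs(z)),
    n_gt3 = sum(abs(z) > 3),
    pass = max(abs(z)) <= 4 && sum(abs(z) > 3) <= 2
  )
  class(res) <- "summary.unli_verification"
  res
}

#' @export
print.summary.unli_verification <- function(x, ...) {
  cat(sprintf(
    "Verification over %d settings (N = %d, base seed = %d)\n",
    x$settings, x$n, x$base_seed))
  cat(sprintf("  max |z|      : %.3f\n", x$max_abs_z))
  cat(sprintf("  count |z| > 3: %d\n", x$n_gt3))
  cat(sprintf("  band (all |z| <= 4, at most 2 > 3): %s\n",
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Write a verification report as CSV
#'
#' Stable column order (`mu1, mu2, var1, var2, rho, closed_form, mc_mean,
#' mc_se, z`) for regression testing.
#'
#' @param v Result of [run_verification()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_verification_csv <- function(v, path) {
  cols <- c("mu1", "mu2", "var1", "var2", "rho",
            "closed_form", "mc_mean", "mc_se", "z")
  if (!all(cols %in% names(v)))
    fail_validation("v does not look like a verification report")
  write.csv(as.data.frame(v)[, cols], path, row.names = FALSE)
  invisible(path)
}
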