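# Independent oracles (pure stats::integrate quadrature) and shared
# fixture configurations. The quadrature routines deliberately share no
# code with the package's closed form.

# P(X <= x1, Y <= x2) for standard BVN, by conditioning on X.
quad_bvn <- function(x1, x2, rho) {
  f <- function(x) dnorm(x) * pnorm((x2 - rho * x) / sqrt(1 - rho^2))
  integrate(f, -Inf, x1, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# E[Y_i 1{Y_i > 0, Y_i > Y_j}] by conditioning on Y_i.
quad_pair <- function(mui, muj, si, sj, rho) {
  f <- function(y) {
    mcond <- muj + rho * sj / si * (y - mui)
    y * dnorm(y, mui, si) * pnorm((y - mcond) / (sj * sqrt(1 - rho^2)))
  }
  integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# E(max(Y1, Y2, 0)) as the sum of the two ordered-pair integrals.
quad_emax <- function(p) {
  quad_pair(p$mu1, p$mu2, p$sigma1, p$sigma2, p$rho) +
    quad_pair(p$mu2, p$mu1, p$sigma2, p$sigma1, p$rho)
}

# EVPI for three strategies with independent arm-mean NBs (m, v) taking
# arm `ref` as reference; used for reference-invariance properties.
evpi_with_reference <- function(m, v, ref) {
  alt <- setdiff(seq_along(m), ref)
  s1 <- sqrt(v[alt[1]] + v[ref])
  s2 <- sqrt(v[alt[2]] + v[ref])
  evpi_from_bvn(bvn_params(m[alt[1]] - m[ref], m[alt[2]] - m[ref],
                           s1, s2, v[ref] / (s1 * s2)))
}

# Mild-tailed generator configuration with genuine decision uncertainty:
# used for parameter recovery and cross-method consistency. QALY sd is
# small enough that clipping to [0, 1.2] is negligible, and the cost cv
# keeps all moments well behaved.
recovery_config <- function(n = 1e5, seed = 7) {
  synth_config(
    n_per_arm = rep(n, 3),
    arms = c("A", "B", "C"),
    reference = "A",
    mean_cost = c(3000, 3300, 3200),
    sd_cost = c(2000, 2200, 2100),
    mean_qaly = c(0.700, 0.690, 0.715),
    sd_qaly = c(0.12, 0.12, 0.12),
    cost_qaly_cor = -0.1,
    missingness = 0,
    seed = seed
  )
}

# Delta-method standard errors for the estimated incremental-NB
# parameters (mu1, mu2, sigma1, sigma2, rho) of a complete dataset,
# treating arms as independent. Var(s^2) ~ (m4 - s^4)/n.
recovery_ses <- function(d, wtp) {
  nb <- d$records$qaly * wtp - d$records$cost
  arm <- factor(d$records$arm, levels = d$arms)
  n <- as.numeric(table(arm))
  s2 <- as.numeric(tapply(nb, arm, var))
  m4 <- as.numeric(tapply(nb, arm, function(x) mean((x - mean(x))^4)))
  v <- s2 / n                      # variance of each arm's mean NB
  var_v <- (m4 - s2^2) / n^3       # Var of that estimate
  ref <- which(d$arms == d$reference)
  alt <- setdiff(1:3, ref)
  sig <- sqrt(v[alt] + v[ref])
  rho <- v[ref] / prod(sig)
  se_mu <- sqrt(v[alt] + v[ref])
  se_sig <- sqrt(var_v[alt] + var_v[ref]) / (2 * sig)
  grad_ref <- 1 / prod(sig) - rho / 2 * (1 / sig[1]^2 + 1 / sig[2]^2)
  se_rho <- sqrt((rho / (2 * sig[1]^2))^2 * var_v[alt[1]] +
                 (rho / (2 * sig[2]^2))^2 * var_v[alt[2]] +
                 grad_ref^2 * var_v[ref])
  list(mu = se_mu, sigma = se_sig, rho = se_rho)
}
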