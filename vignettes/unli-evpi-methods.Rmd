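---
title: "Methods: the 2-D unit normal loss integral and EVPI estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 2-D unit normal loss integral and EVPI estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unli2d)
```

## Model and scope

A three-strategy decision problem is summarised by the incremental net
benefits $Y_1, Y_2$ of the two alternatives against a common reference,
assumed (exactly, or via the central limit theorem in data-driven
evaluations) to follow a bivariate normal law with means $(\mu_1,\mu_2)$,
standard deviations $(\sigma_1,\sigma_2)$ and correlation $\rho$. Deciding
under current evidence yields $\max(\mu_1,\mu_2,0)$; under perfect
information $E\max(Y_1,Y_2,0)$; the difference is the EVPI. The package
computes $E\max(Y_1,Y_2,0)$ in closed form. No closed form exists for
$m>2$ alternatives (the density of the maximum is then no longer built
from univariate normal kernels), so the three-strategy case is the scope
boundary, enforced at the type level.

## The closed form

For the ordered pair $(i,j)$ write
$\tau^2=\sigma_i^2+\sigma_j^2-2\rho\sigma_i\sigma_j$ (the variance of
$Y_i-Y_j$; positive whenever $|\rho|<1$), and

$$a=\frac{\mu_i}{\sigma_i},\quad b=\frac{\mu_i-\mu_j}{\tau},\quad
r=\frac{\sigma_i-\rho\sigma_j}{\tau},$$

where $r$ is the correlation between $Y_i$ and $Y_i-Y_j$ and satisfies
$|r|<1$ strictly (indeed $\tau^2-(\sigma_i-\rho\sigma_j)^2 =
\sigma_j^2(1-\rho^2)>0$). With
$c_1=(b-ra)/\sqrt{1-r^2}$ and $c_2=(a-rb)/\sqrt{1-r^2}$ — note
$c_1=(\rho\sigma_j\mu_i-\sigma_i\mu_j)/(\sigma_i\sigma_j\sqrt{1-\rho^2})$,
i.e. $\Phi(c_1)=P(Y_j<0\mid Y_i=0)$ — each ordered pair contributes

$$E\big[Y_i\,1\{Y_i>0,\;Y_i>Y_j\}\big] =
\mu_i\,\Phi_2(a,b,r)+\sigma_i\big[\varphi(a)\Phi(c_1)+r\,\varphi(b)\Phi(c_2)\big],$$

and $E\max(Y_1,Y_2,0)$ is the sum over both ordered pairs. The derivation
conditions on the event $\{Y_i>0,\,Y_i-Y_j>0\}$ and applies the standard
identity for the mean of a standard normal coordinate over an upper
bivariate orthant,
$E[U\,1\{U>h,V>k\}]=\varphi(h)\Phi\!\big(\tfrac{rh-k}{\sqrt{1-r^2}}\big)
+r\,\varphi(k)\Phi\!\big(\tfrac{rk-h}{\sqrt{1-r^2}}\big)$.

`unli_2d_terms()` reports this per pair as two terms whose four-way sum is
the exact floating-point result, with branch indicator
$\delta_{i,j}=\mathrm{sign}(\sigma_i-\rho\sigma_j)=\mathrm{sign}(r)$:

* $r_{i,j} = \mu_i 1\{\delta_{i,j}>0\}
  + \Phi(c_1)\,[\sigma_i\varphi(a)-\mu_i\Phi(-a)]$ — the part built from
  univariate distribution functions;
* $q_{i,j} = \mu_i[\Phi_2(a,b,r)-1\{\delta_{i,j}>0\}+\Phi(-a)\Phi(c_1)]
  + \sigma_i r\,\varphi(b)\Phi(c_2)$ — the part carrying $\Phi_2$.

When $\sigma_i-\rho\sigma_j=0$ the pair degenerates: $Y_i$ and $Y_i-Y_j$
are independent, the contribution factorises to
$\Phi(c_1)\cdot\mathrm{UNLI}_1(\mu_i,\sigma_i)$ (all of it reported in
$r_{i,j}$, with $q_{i,j}=0$ and $\delta=0$). Both limits of the
non-degenerate expression agree with this value, so the total is
continuous in $\rho$ across the branch; the property suite checks
continuity at $\sigma_1=1,\sigma_2=2,\rho=0.5$ to $10^{-5}$.

Every term was validated against two independent oracles before the rest
of the package was wired to it: an adaptive-quadrature evaluation of
$\int_0^\infty y\,f_{Y_i}(y)\,P(Y_j<y\mid Y_i=y)\,dy$ per ordered pair
(machine-precision agreement across random parameters in both branches)
and seeded Monte-Carlo integration.

### Numerical choices

* **$\Phi_2$.** The Genz reformulation of the Drezner–Wesolowsky single
  integral (6/12/20-point Gauss–Legendre by $|\rho|$, tail expansion for
  $|\rho|>0.925$), an established algorithm with absolute error around
  $10^{-15}$ — far inside the $10^{-10}$ contract asserted in the tests.
  The test suite dual-routes it against both a quadrature oracle and
  `mvtnorm::pmvnorm`.
* **Degeneracy tolerance.** The exact-zero branch is taken when
  $|\sigma_i-\rho\sigma_j|\le 10^{-12}\max(\sigma_i,\sigma_j)$. By the
  continuity property either branch is accurate to far below any
  practical scale there; the cutoff only decides how the decomposition is
  reported.
* **Domain.** $\sigma\le 0$ and $|\rho|\ge 1$ are rejected (the closed
  form divides by $\sqrt{1-\rho^2}$); they are not treated as limits.
* **Scalars.** All closed-form operations take and return scalars; grid
  sweeps iterate. EVPI is clamped at 0 against $-10^{-16}$-scale noise.

## Monte-Carlo oracle and the factorial verification

`mc_max_expectation()` draws $Y=\mu+LZ$ with $L$ the lower-triangular
factor of the covariance, using a private, explicitly seeded stream
(the caller's RNG state is saved and restored), and reports the sample
mean of $\max(Y_1,Y_2,0)$ with its Monte-Carlo standard error.

`run_verification()` crosses $\mu_1,\mu_2\in\{-2,0,2\}$,
$\sigma^2_1,\sigma^2_2\in\{1,3\}$ and
$\rho\in\{-0.75,\dots,0.75\}$ (252 settings, lexicographic order, seed
for setting $k$ equal to `base_seed` $+k$) at $N=100{,}000$ draws and
standardises the discrepancy by the MC standard error. If the closed form
is exact the 252 $z$-values are standard normal; the acceptance band —
every $|z|\le 4$, at most two beyond 3 — is the correct multiple-look
reading of "agreement within MC error" ($\approx 0.7$ exceedances of
$3\sigma$ expected by chance alone; a hard $1\cdot$SE rule would reject
an exact implementation almost surely).

## Trial pipeline

Per patient, $NB=\lambda\cdot QALY-cost$. Per arm, the mean NB and the
variance of that mean ($s^2/n$). In a parallel randomized trial the arms
are independent, so the two incremental means covary only through the
shared reference arm:

$$\mu_i=\bar{NB}_i-\bar{NB}_{ref},\quad
\sigma_i^2=v_i+v_{ref},\quad
\rho=\frac{v_{ref}}{\sigma_1\sigma_2},$$

with $v=s^2/n$ per arm. This estimator is exact for the shared-arm
covariance (no estimator is needed for cross-arm terms, which are zero by
design) and is validated against the bootstrap covariance on synthetic
data. EVPI is invariant to which arm is called the reference — the
maximum over $\{0,Y_1,Y_2\}$ shifts by a constant — and the tests assert
this invariance at $10^{-6}$ relative tolerance for all three labelings.

The **bootstrap estimator** resamples patients within arm (original arm
sizes, with replacement), computes each arm's mean NB per resample, and
forms $\text{EVPI}=\text{mean}_b[\max_k \bar{NB}_k^{(b)}]-\max_k
[\text{mean}_b \bar{NB}_k^{(b)}]$; the reported SE is the MC error of the
first term. This is the standard data-driven estimator; it is
non-negative by construction.

**Missing data.** The analysis functions require complete data and name
the offending patients otherwise. `handle_missing()` offers complete-case
deletion and within-arm mean imputation as simple stand-ins; proper
multiple imputation is out of scope by design, but `rubin_pool()` accepts
externally produced per-imputation (mean, covariance) estimates and pools
them with Rubin's rules — mean of means, $\bar W+(1+1/m)B$ — feeding
`evpi_from_pooled()`.

## The synthetic trial generator

`generate_trial()` emulates the analysis-ready layer of a 12-month,
449-patient, three-arm COPD inhaler trial (arms 145/156/148, ~7% of cost
and QALY cells missing): per patient a latent standard bivariate normal
pair with configurable correlation drives a **lognormal cost** marginal,
moment-matched to the configured mean/sd (costs are strictly positive and
right-skewed, as hospitalisation-driven cost data are), and a **normal
QALY** marginal clipped to $[0, 1.2]$. Missingness is MCAR, independent
per cell — sufficient to exercise the missing-data pathways, though real
trial missingness is rarely MCAR. Longitudinal structure (visits, cost
diaries, utility mapping) is deliberately not emulated. Configured
moments refer to the unclipped marginals; configurations used in tests
keep the clip probability negligible.

`case_study_like()` pins the printed case-study quantities: reference
(single-inhaler) arm mean cost 2,678 and mean QALY 0.7092, triple arm
4,042 and 0.7217, and per-arm cost sds back-solved — given QALY sd 0.20
and latent correlation $-0.1$, both fixed a priori — so the *induced*
incremental-NB parameters at $\lambda=50{,}000$ equal
$\sigma_1=4{,}678$, $\sigma_2=4{,}645$, $\rho=0.50$ exactly
(`induced_bvn_params()` exposes this analytic ground truth). Three
consequences are worth stating plainly:

* The printed arm means force $\mu_2=-739$ at $\lambda=50{,}000$, not the
  pooled $-2{,}668$ printed alongside them — the source's pooled
  estimates and rounded arm means are mutually inconsistent (the same
  inconsistency is visible in its ICER arithmetic). The generator keeps
  the arm means and the three second-moment targets and accepts the
  induced $\mu_2$.
* The implied per-patient NB sd of $\approx\$40$k, with QALYs bounded in
  $[0,1.2]$, can only come from a very heavy-tailed cost marginal
  (lognormal with cv $\approx 14$ — rare catastrophic costs). Realized
  sample variances at $n\approx450$ therefore scatter widely below their
  expectation; the cross-method acceptance check compares the two EVPI
  estimators *on the same realized dataset*, which is the comparison that
  is statistically meaningful in this world. A consequence of the forced
  $\mu_2=-739$ world is that the *analytic* probability that the
  reference arm is optimal is only
  $\Phi_2(-\mu_1/\sigma_1,-\mu_2/\sigma_2,\rho)\approx 0.52$, rather than
  the 80% reported on the non-public real data (on the fixed seed-2024
  realization the bootstrap frequency happens to be 0.96); the tests
  therefore assert only the direction — the reference arm is the modal
  optimum.
* Missingness is 0 in this preset: the pinned quantities describe the
  post-imputation, full-$n$ analysis set. The default `synth_config()`
  (moderate cost skew, 7% MCAR missingness) exercises the missing-data
  pathway instead.

A separate mild-tailed three-arm configuration (defined in the test
helpers) with genuine decision uncertainty is used for parameter-recovery
and bootstrap-vs-closed-form consistency checks, with delta-method
standard errors ($\mathrm{Var}(s^2)\approx(m_4-s^4)/n$) supplying the
3-SE recovery bands.

## What a green suite does and does not establish

It establishes: the closed form agrees with quadrature at machine
precision and with MC across the factorial design; the pipeline's
estimators are internally consistent (closed form vs bootstrap within
bootstrap error; reference invariance; Rubin pooling algebra) on data the
generator can produce. It does not establish: behaviour under non-normal
*mean* NBs at small $n$ (the CLT premise), informative missingness, or
the exact figures of the original non-public trial data — the $976
bootstrap EVPI, the 80% optimal-strategy frequency and the 3% mean
relative error are not reproducible and are replaced by the internal
consistency checks above.

## Known limitations

* Three strategies only; no EVPPI/EVSI extensions.
* Bivariate normality is assumed, not tested; heavy-tailed per-patient
  NBs are handled only insofar as arm *means* normalise.
* `handle_missing()` policies are deliberately naive; pooling of external
  multiple imputations is the supported route.
* The bootstrap SE reflects resampling error of $E[\max]$ only, matching
  the conventional estimator it mirrors.
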