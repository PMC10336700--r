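# unli2d

Closed-form value-of-information analysis for decision problems with
**three** strategies.

## The problem

In cost-effectiveness analysis each strategy is scored by its *net benefit*
(NB), `NB = QALY × λ − cost`, where λ is the willingness-to-pay per
quality-adjusted life year. The *expected value of perfect information*
(EVPI) is the expected gain in NB if all uncertainty about which strategy is
best were resolved:

```
EVPI = E[ max_k NB_k ] − max_k E[ NB_k ].
```

With two strategies and a normal incremental net benefit `Y ~ N(μ, σ²)`,
EVPI has long been available in closed form through the one-dimensional
*unit normal loss integral* (UNLI),

```
UNLI₁(μ, σ) = E max(Y, 0) = μ[1 − Φ(−μ/σ)] + σ φ(−μ/σ).
```

With three strategies one needs `E max(Y₁, Y₂, 0)` for a *bivariate* normal
pair of incremental net benefits `(Y₁, Y₂)` (each alternative against a
common reference; the choice of reference does not affect the result).
This package implements the exact closed form for that two-dimensional
UNLI — a finite combination of φ, Φ and the bivariate normal CDF Φ₂ — so
EVPI for three-strategy problems needs no Monte-Carlo simulation:

```
E max(Y₁, Y₂, 0) = r₁,₂ + q₁,₂ + r₂,₁ + q₂,₁,      EVPI = E max(Y₁, Y₂, 0) − max(μ₁, μ₂, 0)
```

where each ordered pair (i, j) contributes `E[Yᵢ·1{Yᵢ > 0, Yᵢ > Yⱼ}] = rᵢ,ⱼ + qᵢ,ⱼ`,
with a branch indicator `δᵢ,ⱼ = sign(σᵢ − ρσⱼ)` and a degenerate branch when
`σᵢ − ρσⱼ = 0`. See the methods vignette (`vignettes/unli-evpi-methods.Rmd`)
for the full expressions and their derivation.

Audience: health-economic and decision analysts who have either (a)
bivariate-normal parameters of two incremental net benefits (from a
probabilistic analysis, a Wald approximation, or Rubin-pooled multiple
imputations), or (b) patient-level cost/QALY data from a parallel
three-arm trial.

## Worked example

Pooled parameters of the incremental net benefits of double- and
triple-inhaler therapy versus single-inhaler therapy in a 449-patient COPD
trial, at λ = $50,000/QALY:

```r
library(unli2d)
p <- bvn_params(mu1 = -4734, mu2 = -2668,
                sigma1 = 4678, sigma2 = 4645, rho = 0.50)
unli_2d_terms(p)
#> 2-D UNLI term decomposition (E(max(Y1, Y2, 0)) = sum of r and q)
#>  i j delta            r            q degenerate
#>  1 2     1 -2015.537664 2289.1461847      FALSE
#>  2 1     1   115.094410  630.2499522      FALSE
#> total: 1018.952883
evpi_from_bvn(p)
#> [1] 1018.953
```

Both incremental means are negative — on current evidence the reference
strategy is optimal — yet uncertainty about that choice is worth ≈ $1,019
per patient: the closed-form EVPI. A seeded Monte-Carlo cross-check
(`mc_max_expectation(p, 1e5, seed = 1)`) gives 1021.58 with standard error
6.24 (z = −0.42).

From patient-level data instead:

```r
d <- generate_trial(case_study_like())     # or read_trial_csv("trial.csv")
evpi_unli(d, wtp = 50000)                  # closed form
evpi_bootstrap(d, wtp = 50000, B = 1000, seed = 1)  # conventional bootstrap
wtp_sweep(d, c(25000, 50000, 75000, 100000))        # both, over a WTP grid
```

## Verifying the closed form

`run_verification()` evaluates the closed form against independent seeded
Monte-Carlo estimates (N = 100,000) over a 252-setting factorial grid of
means, variances and correlations:

```r
summary(run_verification(n = 100000, base_seed = 1))
#> Verification over 252 settings (N = 100000, base seed = 1)
#>   max |z|      : 3.410
#>   count |z| > 3: 1
#>   band (all |z| <= 4, at most 2 > 3): PASS
```

## Command line

```sh
Rscript inst/cli/unli2d unli --mu1 -4734 --mu2 -2668 --sigma1 4678 --sigma2 4645 --rho 0.5
Rscript inst/cli/unli2d verify --n 100000 --seed 1 --out report.csv
Rscript inst/cli/unli2d synth --preset case-study --out trial.csv
Rscript inst/cli/unli2d evpi --data trial.csv --wtp-grid 25000,50000,75000,100000 \
    --missing complete_cases --out evpi.json
```

Exit codes: 0 success, 2 invalid input, 1 runtime failure.

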