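# cfascale

Scaling the variance of a latent variable in confirmatory factor analysis
(CFA) is an arbitrary choice: fixing a marker loading to 1, fixing the
latent variance to 1, or constraining the loading sum (effect coding) or
squared-loading sum to a criterion number all identify the model, and each
yields a different variance estimate for the *same* solution. cfascale is
for researchers — e.g. in psychometrics, assessment and epidemiological
measurement — who want to use latent variances as information anyway:
comparing the contribution of a trait factor against a method or nuisance
factor (multitrait–multimethod and bifactor designs), or tracking variance
across occasions, without the result depending on which indicator happened
to be the marker.

## The core idea

With the model-implied covariance `Σ = ΛΦΛ′ + Θ`, any per-factor constant
c > 0 applied as

```
Λ* = Λ diag(c),    Φ*_jk = Φ_jk / (c_j c_k)
```

leaves the true part `ΛΦΛ′` — and hence Σ, the fit, and every implied
moment — unchanged. All standard scaling methods are choices of c:

* marker variable: `c = 1/λ_i` (marker loading becomes 1)
* reference group: `c = √(φ/φ_target)` (variance becomes the target)
* effect coding: `c = p_c / 1′λ` (loadings sum to the criterion number p_c)
* squared loadings: `c = √(p_c / λ′λ)` (squared loadings sum to p_c)

so the scaled variance is always `φ_sc = φ/c²`. Setting `p_c = 1` for every
factor makes each scaled variance the variance that factor explains,
`λ′λ·φ = trace(λφλ′)` — contributions comparable across factors like
standardized regression weights, and equal to the nonzero eigenvalue of the
rank-one true part for unidimensional models. The package provides these
operations, a constancy checker, a minimal ML CFA fitter that can impose
each identification at estimation time, and a seeded synthetic-data
generator, plus a `cfascale` command-line tool (subcommands `scale`,
`table`, `compare`, `fit`, `simulate`).

## Worked example

Two sources drive six indicators: a construct factor on all of them
(loadings 0.7) and a nuisance "speed" factor on the last three
(loadings 0.3). How much of the responding is construct, how much speed?

```r
library(cfascale)

truth <- cfa_model(
  cbind(construct = rep(0.7, 6), speed = c(0, 0, 0, 0.3, 0.3, 0.3)),
  phi = c(1, 1), theta = rep(0.35, 6))
study <- sample_study(truth, n = 500, seed = 42)

fit <- fit_cfa(study$sample, spec_from_model(truth, "reference_group"))
glance(fit)
#>   discrepancy chi_square    df normed_chi_square rmsea    srmr   cfi   gfi
#> 1     0.00957       4.78     6             0.796     0 0.00882     1 0.997

comparison_scaling(fit$estimates)
#> Per-factor variance contributions (criterion number 1):
#>   factor      phi constant scaled_variance degenerate  rank
#> 1 construct     1    0.598           2.79  FALSE          1
#> 2 speed         1    2.23            0.201 FALSE          2
#> Total across factors: 2.9942
```

The fitted model reproduces the sample covariance (χ²(6) = 4.78,
RMSEA = 0, SRMR = 0.009). Comparison scaling rescales each latent variance
to the variance its factor explains: about 2.79 for the construct versus
0.20 for speed (population values 6·0.49 = 2.94 and 3·0.09 = 0.27) — the
construct dominates responding, and this verdict does not depend on how
the model was identified. The effect of the criterion number itself is
tabulated by

```r
criterion_sensitivity_table(c(0.2, 0.4, 0.6), c(4, 8, 12),
                            c("1/1", "1/2", "1/4"), wide = TRUE)
#>   criterion     p   p_c loading_0.2 loading_0.4 loading_0.6
#> 1 1/1           4     4        0.04        0.16        0.36
#> 2 1/1           8     8        0.04        0.16        0.36
#> 3 1/1          12    12        0.04        0.16        0.36
#> # ... 6 more rows
```

larger loadings raise the scaled variance, larger criterion numbers lower
it, and a criterion proportional to p removes the dependence on the number
of indicators. See `vignette("scaling-constancy")` for the methods account
(scaling framework, ML fitter, MTMM workflow, generator assumptions).

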