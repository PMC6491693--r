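---
title: "Scaling latent-variable variances without changing the model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling latent-variable variances without changing the model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfascale)
```

## The problem

A confirmatory factor model reconstructs a p x p covariance matrix as

    Sigma = Lambda Phi Lambda' + Theta

with a p x q loading matrix Lambda, a q x q latent variance/covariance
matrix Phi and a diagonal error covariance Theta. The model is not
identified until each latent variable is given a metric, and every common
way of doing that — fixing a marker loading to 1, fixing the latent
variance to 1, or constraining the (squared) loading sum to a criterion
number — is a choice of scale, not of substance. The variance parameter of
a latent variable therefore depends on an arbitrary decision, which is the
main reason it is usually ignored as a source of information, even though
questions like "how much of the responding is trait, how much is method?"
are exactly questions about latent variances.

cfascale implements the observation that all of these scaling methods are
instances of one operation: scalar multiplication. For any constant c > 0,

    Lambda* = c Lambda,   Phi* = Phi / c^2

leaves the *true part* `Lambda Phi Lambda'` — and with it Sigma, the fit,
and every model-implied moment — unchanged. We call the max-norm difference
between two solutions' true parts the *constancy distance*
(`constancy_distance()`); a legitimate rescaling has distance zero up to
floating point. With several factors the package applies one constant per
factor, i.e. post-multiplies Lambda by a positive diagonal matrix D and
replaces Phi by D^-1 Phi D^-1, dividing each latent covariance by c_j c_k;
the identity `(Lambda D)(D^-1 Phi D^-1)(D Lambda') = Lambda Phi Lambda'`
holds for any symmetric Phi, so correlated factors (as in
multitrait–multimethod models) are covered even though the entrywise proof
object `true_part_entry()` is only defined for diagonal Phi and refuses
otherwise.

## The four scaling methods

Each method picks c per factor from the unscaled solution
(`build_plan()` + `rescale()`):

| method | constant | post-condition |
|---|---|---|
| marker (`marker_constant`) | `c = 1 / lambda_i` | marker loading becomes 1 |
| reference group (`reference_constant`) | `c = sqrt(phi / target)` | variance becomes `target` |
| effect coding (`effect_coding_constant`) | `c = p_c / sum(lambda)` | loading sum becomes `p_c` |
| squared loadings (`sum_squares_constant`) | `c = sqrt(p_c / lambda'lambda)` | squared-loading sum becomes `p_c` |

The marker constant requires a strictly positive marker loading; the
reference-group constant a positive variance; the criterion-based methods a
positive criterion number `p_c` and a non-degenerate loading column (sum,
or sum of squares, bounded away from zero — we refuse below 1e-12 rather
than return an astronomically large constant). A latent variance parameter
may be negative (estimation can and does produce such values); the scaled
variance then inherits the sign and the model object carries a flag, but c
itself must stay positive, and nothing is clamped silently.

The criterion number is a genuine tuning knob with units of (squared)
loadings. Because `phi_sc = phi * lambda'lambda / p_c` for the
squared-loadings method, the scaled variance is strictly decreasing in
`p_c` — a larger criterion number buys a smaller, more tightly ranged
scaled variance. `criterion_sensitivity_table()` tabulates this over grids
of equal loadings; when `p_c` is given as a proportion of p (`"1/1"`,
`"1/2"`, `"1/4"`), `phi_sc = phi * lambda^2 / r` is independent of p, while
an absolute `p_c` makes the value grow with the number of indicators. A
proportion like `"1/2"` of an odd p yields a non-integer criterion number;
we accept it, since the formulas require only `p_c > 0`.

## Comparison scaling

Setting `p_c = 1` for every factor (`comparison_scaling()`) makes each
rescaled variance equal the variance the factor explains in the
indicators, `lambda'lambda * phi = trace(lambda phi lambda')`
(`explained_variance()`). These values play the role standardized
regression weights play in regression: contributions of different sources
(say, a construct factor and a nuisance-method factor) measured on one
scale, rankable, and — for a unidimensional model — equal to the nonzero
eigenvalue of the rank-one true part (`rank1_eigen_check()`). Contributions
are reported from the diagonal of the rescaled Phi only; rescaled latent
*covariances* are attached separately as shared variance, because the
comparison rationale presumes separable sources. Ranking ties are broken by
input factor order (documented in the output), and an all-zero loading
column is flagged as degenerate rather than dropped.

Unlike marker scaling — where each admissible marker choice yields a
different variance estimate, so no unique statistic exists — the
comparison-scaled values are invariant to how the input solution happened
to be identified; this is tested both algebraically and through the ML
fitter.

## The ML fitter

`fit_cfa()` minimises the maximum-likelihood discrepancy

    F = log|Sigma| + tr(S Sigma^-1) - log|S| - p

over the free parameters of a `cfa_spec()`. Design choices:

* **Optimizer**: BFGS (`stats::optim`) with the analytic gradient
  `dF = tr[Sigma^-1 (Sigma - S) Sigma^-1 dSigma]`, restarted from the
  incumbent until the gradient norm drops below 1e-7 (at most 5 restarts,
  2000 iterations each). Restarting resets BFGS's Hessian approximation,
  which in practice is what is needed to polish the last two digits.
* **Starting values**: free loadings `0.5 * sqrt(diag(S))`, latent
  variances 1, latent covariances 0, error variances `0.5 * diag(S)` —
  scale-aware and reproducible.
* **Identification at estimation time**: marker loadings and reference
  variances are fixed values in the parameter masks; the effect-coding sum
  constraint is imposed by exact reparameterisation (one loading per factor
  is `p_c` minus the sum of the others, with the matching chain-rule term
  in the gradient), so the constraint holds to machine precision rather
  than approximately through a penalty.
* **Inadmissible estimates**: error variances are unbounded; a negative
  estimate (Heywood case) is returned with a flag, never truncated,
  because truncation would silently change the implied covariance.
* **Degrees of freedom**: `p(p+1)/2` minus the number of free parameters;
  a spec with negative df is refused before optimisation.
* **Standard errors** (optional, `se = TRUE`): inverse numerical Hessian
  of F (central differences of the analytic gradient, step
  `1e-5 * (1 + |theta|)`) times `2/(n-1)`. The z ratios are invariant to
  the criterion number — rescaling scales estimate and standard error
  alike — which the suite checks across `p_c` of 1 and 3.
* **Correlation input**: analysed as a covariance matrix, with a logged
  caveat that chi-square-based indices assume covariance input.

Fit indices follow the standard definitions: `chi^2 = (n-1) F`; RMSEA from
`sqrt(max(chi^2 - df, 0) / (df (n-1)))` (df = 0 reported as 0 with a
note); SRMR as the RMS standardized residual over the lower triangle
including the diagonal; CFI against the independence baseline, which for ML
has the closed-form solution `Sigma_b = diag(S)`; GFI from the weighted
residual traces.

Constancy is asserted on the true part only: if two identifications
reproduce the same S with the same true part, their Theta estimates agree
automatically, so checking `Lambda Phi Lambda'` is the sharper and
sufficient test.

## The MTMM workflow

The 3-trait x 3-method demonstration uses a published synthetic
correlation matrix that this package does not redistribute; what it ships
is everything needed to rerun the workflow on that matrix or any
stand-in: the reported reliabilities (`mtmm_reliabilities`), the adjusted
main diagonal (`mtmm_adjusted_diagonal`) with `adjust_diagonal()` — which
replaces the unit diagonal so error variances stay positive and line up
with the reliability complements while leaving every correlation
bit-identical — and `mtmm_spec()`, the correlated trait–correlated method
specification in which only the trait1–trait2 and method2–method3
correlations remain free (df = 16, matching the reported fit). Exact
reproduction of the published MTMM estimates is deliberately out of scope:
the source matrix is external and the sample size behind its chi-square is
not stated, so no value is assumed. Both routes to criterion-based
variances are available — constrained re-estimation
(`identification = "effect_coding"`) and post-hoc rescaling of a
reference-group solution — and the suite verifies they agree on population
input.

## The synthetic-data generator

`generate_model()` builds population models from per-factor loading values
and indicator sets, including the two-source design (a construct factor on
all indicators, a second source on a subset). When error variances are
omitted they default to `1 - diag(Lambda Phi Lambda')`, i.e. standardized
indicators, which is the metric the criterion-grid configurations assume.
`sample_study()` draws raw scores `x = mu + Lambda xi + delta` with
Gaussian latent and error scores (matching the ML fitter's assumptions; no
distribution is otherwise privileged) and computes the sample covariance
with the n − 1 denominator; raw scores are generated rather than Wishart
draws so future estimators can consume them. Everything is seed-
deterministic; `recovery_study()` gives replicate r the seed `seed + r`.

What the generator does not emulate: non-normal or ordinal indicators,
missing data, model misspecification beyond sampling error. Passing
recovery tests therefore show that the estimator and the scaling chain are
correct under the model's own assumptions — not that the model is robust
to violations of them.

## Problem sizes and numerical tolerances

The suite checks constancy on 500 random model x method draws (p up to 12,
q up to 3) at 1e-10 — double precision leaves orders of magnitude to
spare at these sizes — and method post-conditions at 1e-12.
Identification equivalence is checked on 20 random population covariances
(one- and two-factor, four indicators per factor) at 1e-6, the practical
resolution of a fit driven to gradient norm 1e-7. Eigenvalue
correspondence uses 100 random one-factor models at 1e-10. Monte-Carlo
recovery uses 50 replicates of n = 5000 from an eight-indicator,
loading-0.4 truth, a size at which the mean squared-loadings-scaled
variance sits within 0.02 of its population value 0.16. Symmetry checks
tolerate 1e-10 internally and 1e-6 on file input (text round-trips are
printed at 6 significant digits; the structured JSON format keeps full
precision).

## Limitations

Standard errors of *rescaled* parameters are not recomputed: rescaling
changes the parameterisation, and the delta-method adjustment is out of
scope here. Mean structures are carried only for data generation; there is
no fitting of intercepts, no multi-group or longitudinal machinery, no
robust or categorical estimation. The eigenvalue correspondence is
asserted only as the rank-one identity; nothing stronger is claimed for
multidimensional models.
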