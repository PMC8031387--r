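---
title: "Robust rank-based ridge regression with Stein-type shrinkage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust rank-based ridge regression with Stein-type shrinkage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transcriptomic prediction problems — a continuous phenotype such as a log
production rate regressed on thousands of log gene-expression levels —
combine three difficulties: severe multicollinearity, response outliers, and
possibly more covariates than samples (p > n).  Least squares fails on all
three counts.  `rankridge` combines three remedies:

* **rank (R-) estimation**, which replaces squared residuals by the Jaeckel
  dispersion of residual ranks and is robust to response outliers;
* **ridge regularization**, which stabilizes estimation under
  multicollinearity and remains defined when p > n;
* **Stein-type shrinkage**, which pulls the regularized coefficients toward
  the origin by an amount governed by a global-null test statistic, gaining
  accuracy when the signal is weak.

# Model and estimators

The model is the linear regression `y = X b + e` with iid errors whose
density has finite Fisher information.  The intercept is removed by centring
both `y` and the columns of `X` (`prepare_data()`); optionally the columns
are scaled to unit Euclidean norm ("correlation form"), the convention used
for all simulated designs.

## Scores and dispersion

A score system is a nondecreasing, square-integrable function
`psi: (0,1) -> R` evaluated at the quantile points `i/(n+1)`; the default is
the Wilcoxon score `psi(u) = sqrt(12)(u - 1/2)`, for which
`sigma_a^2 = sum(a^2)/(n-1)` tends to 1.  Sign and normal (van der Waerden)
scores are available behind the same interface.  The quantile form of the
scores is used rather than order-statistic expectations: it is deterministic
and the standard computational choice.  Ties in residuals are handled by
mid-ranks, which keeps the scores of any vector summing to zero for centred
score functions.

The Jaeckel dispersion `D(v) = sum_i a(R(v_i)) v_i` is a convex pseudo-norm:
nonnegative, scale-equivariant, and invariant to adding constants.
`fit_rank()` minimizes `D(y - X b)` by scored Gauss-Newton steps — the
negative gradient `X' a(R(e))` mapped through `(X'X)^{-1}` — with an exact
line search along each direction (the one-dimensional restriction of a convex
piecewise-linear function, minimized by `optimize()` to tolerance 1e-12).
Convergence is declared when the relative dispersion decrease falls below
1e-10 or the gradient norm below 1e-8 of its initial size, capped at 200
iterations; the start is the minimum-norm least-squares fit.  This
direction-plus-line-search scheme costs O(np) per step, which is what makes
Monte-Carlo studies with hundreds of replicates at n = 180, p = 120 cheap;
a pairwise-difference IRLS formulation of the same objective costs O(n^2 p)
per step and was rejected for that reason.

An important degeneracy: with centred columns, a design of rank n - 1 spans
the whole sum-zero subspace, which contains the centred response — the
dispersion minimum is then `y` itself and carries no information.
`fit_rank()` therefore refuses designs with rank >= n - 1 ("saturated") and
defers to the ridge machinery below.

## The scale parameter tau

The scale functional `tau`, with `1/tau = integral psi(u) psi_f(u) du`,
links rank-based and least-squares asymptotics; for Gaussian errors with
standard deviation `sigma` the Wilcoxon value is `sigma * sqrt(pi/3)`, and
for Uniform(0,1) errors it is `1/sqrt(12)`.  `estimate_tau()` implements the
Koul–Sievers–McKean window estimator for Wilcoxon scores: the proportion of
absolute pairwise residual differences under a bandwidth (the 0.8 quantile of
the differences divided by `sqrt(n)`, 0.95 when n/p <= 5) estimates
`2 * integral f^2`, with the p smallest differences dropped and a
`sqrt(n/(n-p-1))` degrees-of-freedom correction.  For sign scores the
median-interval estimator is used.  In saturated designs, where no exact rank
fit exists, `tau` is estimated from a pilot ridge fit tuned by GCV restricted
to fits keeping at least 25% residual degrees of freedom (an unrestricted
pilot would interpolate and report a near-zero scale).

## Ridge, rank ridge, and the shrinkage estimator

With `A_k = n^{-1} X'X + k I`, the three estimators are

* `ridge_ls()`: `b(k) = s A_k^{-1} X' y`,
* `ridge_rank()`: `b_psi(k) = s A_k^{-1} X' yhat_psi`, where `yhat_psi` is
  the rank-fit prediction, and
* `sse()`: `b_sse(k, d) = (1 - d / R_n(k)) b_psi(k)`,

where `R_n(k)` is the test statistic below and the scaling factor `s` follows
one of two documented conventions.  The **calibrated** convention (`s = 1/n`,
the default) makes the `k -> 0` limit recover the unpenalized fit exactly;
the **literal** convention (`s = 1`) reproduces the formulas as usually
printed, whose `k -> 0` limit is n times the unpenalized fit.  Both are
exposed because published numbers for this estimator family can follow
either; every function takes a `scaling` argument.

In the saturated case the rank fit degenerates (see above) and the estimator
substitutes `X' yhat_psi -> 2 tau X' y` — the linearization that also
underlies the hat-matrix representation: the fitted values are then exactly
`L2(k) y` with `L2(k) = 2 tau s X A_k^{-1} X'`.  The provenance of the
constant 2 is not derived here; it is implemented as part of the estimator's
definition.  Note one consequence: through `2 tau`, the saturated rank-ridge
smoother is *not* invariant to rescaling the response, and when
`2 tau > 1` it overshoots `y`, which matters for tuning (below).

The shrinkage identities are exact and tested: `d = 0` returns the rank
ridge coefficients bit-for-bit, `d = R_n(k)` the zero vector, and for
`0 < d < 2 R_n(k)` every l_q norm of the SSE is strictly below the rank
ridge's, since `||b_sse||_q = |1 - d/R_n| ||b_psi(k)||_q`.  No positive-part
truncation is applied by default — `d > R_n(k)` flips signs, as the estimator
is defined — but `positive_part = TRUE` is available.

# The ridge rank-based (RRB) test

The global null `H0: b = 0` is tested with the quadratic form

```
R_n(k) = sigma_a^{-2} a(R(y))' X A_k^{-1} [X(k)]^{-1} A_k^{-1} X' a(R(y)),
X(k)   = B^{-1} - k B^{-2},   B = n^{-1} X'X + I.
```

computed through the SVD of `X` (no p-by-p matrices are formed; the p > n
case costs O(n^2 p)).  The statistic depends on `y` only through its ranks,
so it is exactly invariant to monotone response transformations, and it is
defined when p > n, which the classical F test (`f_test()`) is not.

`X(k)` loses positive definiteness for large `k` — under an
orthonormal-scaled design it equals `(0.5 - 0.25 k) I`, singular at `k = 2` —
so validity is checked spectrally and default tuning grids are confined to
the region where `X(k)` is positive definite (`k` below `1 + lambda_min`,
with `lambda_min = 0` for rank-deficient designs).  Two compatibility flags
exist: `xk_variant = "ridge"` replaces the inner `B` by `A_k` (a plausible
variant of the definition under which the whole form collapses algebraically
to the classical rank-score statistic `a'Ha/sigma_a^2`, but which is singular
for rank-deficient designs), and `scaling = "calibrated"` divides the
quadratic form by n.

## Calibration of the decision rule

The asymptotic decision rule compares `R_n(k)` to the upper chi-square
quantile with p degrees of freedom.  Its finite-sample accuracy is poor: the
literal-scale statistic has null mean far above p (its spectral weights sum
to roughly n p under correlation-form designs), and even the collapsed
rank-score form is noticeably conservative when p/n is large, because the
permutation-null variance of the quadratic form is below the chi-square
value 2p.

The package therefore defaults to a **two-moment permutation calibration**
(`calibration = "moment"` in `rrb_test()`).  Under `H0` the score vector
`a(R(y))` is a uniformly random permutation of a fixed vector, so the exact
null mean and variance of *any* quadratic form `a' Q a` with centred `Q` and
centred scores are available in closed form (they involve only `tr Q`,
`tr Q^2`, the diagonal of `Q` and `Q^2`, and the score power sums; the
formula is verified in the test suite against full enumeration of all n!
permutations at small n).  The statistic is then referred to a scaled
chi-square with matched first two moments (a Satterthwaite match).  This is
not a resampling procedure — no permutations are drawn — and it applies
uniformly to every scaling/variant combination and to p > n.  In the
package's simulations the moment rule holds the nominal 5% level inside the
Monte-Carlo binomial band in both low- and high-dimensional regimes, while
the asymptotic rule is either conservative or invalid depending on the
variant; the asymptotic rule remains available via `calibration = "chisq"`.

# Tuning by generalized cross-validation

The fitted values of all three estimators are linear smoothers of `y` with
hat matrices `L1(k)` (ridge), `L2(k) = 2 tau L1(k)` (rank ridge), and
`L(k,d) = (1 - d/R_n(k)) L2(k)` (SSE).  The GCV criterion

```
GCV = [ n^{-1} ||(I - L) y||^2 ] / [ 1 - n^{-1} tr L ]^2
```

is minimized jointly over `(k, d)` for the SSE (`optimize_gcv()`), with the
expected risk identity `E(GCV) ~ E(risk) + tau^2` (checked empirically in the
test suite: the offset is constant across a (k, d) grid to within a few
tenths of a percent and close to `tau^2`).  The search uses a log-spaced grid
— `k` over `[1e-4, k_max]` with `k_max` the positive-definiteness bound
above, and `d` parameterized as a fraction of `R_n(k)` over `[1e-6, 1]`, so
the grid always spans "no shrinkage" to "shrink to zero" — followed by a
Nelder-Mead refinement in log-parameters.  Grids of 40 points per axis are
the default for data analysis; Monte-Carlo drivers use 10 x 10 without
refinement for tractability, and both sizes are recorded in results.

## Guarding the interpolation regime

For saturated designs GCV has a known failure mode: the denominator
`1 - tr(L)/n` cannot fall below about `1/n` (with centred data the smoother
has at most n - 1 unit eigenvalues), so a near-zero threshold never
triggers, while the numerator vanishes for near-interpolating fits — GCV
then decreases toward the interpolation corner rather than identifying a
smoothing optimum.  The guard is therefore an effective-degrees-of-freedom
cap: a `(k, d)` cell is invalid unless it keeps at least `min_resid_frac`
(default 10%) residual degrees of freedom; the pilot fit behind `tau` uses a
stricter 25%.

A related structural fact is worth knowing when reading GCV surfaces from
this family.  Because the shrinkage factor multiplies the whole smoother,
the SSE family contains, at `k` far below the smallest design eigenvalue,
near-uniform shrinkers `c P` (`P` the projection on the column space) whose
GCV is strictly decreasing in `c` for saturated designs.  On weak-signal
draws the surface minimum can therefore sit on the small-`k` edge of the
grid (or on the df cap) instead of strictly inside it; with a clear signal
the spectral-smoothing optimum wins and the minimum is interior.  Both
behaviours are visible across seeds of the bundled synthetic fixtures, and
the acceptance suite documents the boundary case rather than hiding it.

# Model assessment

`loo_cv()` computes plain leave-one-out refit-and-predict mean squared error
on the raw response scale; tuning parameters are held fixed at their
full-data optima (one CV number per estimator at its selected tuning), and
standardization is redone inside each fold.  `r_squared()` reports both the
standard residual-based formula and a "printed" variant
(`1 - sum((yhat - ybar)^2)/Syy`) that circulates under the same name but
measures fitted-value spread; the default is the standard one and both are
returned by `evaluate_estimators()`.  `efficiency()` implements the
Monte-Carlo relative efficiency (ratio of mean squared estimation risks
against a reference method), and `leverage()` the projection diagonal, with
a ridge-regularized variant for rank-deficient designs.

# The synthetic-data generator

The generator *is* the package's study conditions, not a tunable fixture:

* **Design** (`gen_design()`): `x_ij = sqrt(1 - gamma^2) z_ij + gamma z_ip`,
  columns then centred and scaled to unit norm.  The pairwise population
  correlation among the first p - 1 columns is `gamma^2`; the construction
  applies the same rule at `j = p`, so the last column is more strongly
  correlated with the rest — implemented exactly as defined, and documented.
* **Coefficients** (`gen_beta()`): the first `ceiling(0.1 p)` (sparse) or
  `ceiling(0.2 p)` (non-sparse) entries standard normal, the rest exactly 0.
* **Errors** (`gen_errors()`): the first `h = round(n (1 - CS/100))` entries
  are `N_h(0, sigma^2 V)` with `sigma^2 = 0.44` and the rapidly decaying
  AR kernel `v_ij = exp(-9 |i - j|)`; the remaining `n - h` are iid
  non-central chi-squared with 1 df and non-centrality 8 — mean 9, never
  negative, deliberately *not* centred: the one-sided outliers are the point,
  pulling non-robust fits toward them.  The normal block is generated through
  the symmetric eigenvalue square root of `V` up to h = 600 and by the exact
  AR(1) recursion (autocorrelation `exp(-9)`) above that — the two are
  distributionally identical.
* **Driver** (`run_monte_carlo()`): regressors, coefficients (by default) and
  errors are redrawn each replicate; each method is tuned per replicate on a
  coarse grid; squared estimation errors, efficiencies against the first
  method, and RRB/F rejection indicators are accumulated.  Sub-seeds for
  design, coefficients and errors are derived independently from the master
  seed so changing one regime leaves the others' draws untouched.

What this emulates — and what it does not.  The generator reproduces
controlled collinearity, sparse signals, and asymmetric heavy contamination,
which is what the estimators' robustness claims are about.  It does not
emulate gene-gene correlation structure of real expression data, batch or
normalization artefacts, heteroscedasticity, or covariate (leverage-point)
outliers; passing tests on the generator therefore demonstrates robustness to
*response* contamination under multicollinearity, not performance on any
particular real dataset.

# Problem sizes and numerical choices

The test-suite study sizes are chosen to make each check sharp at desk
scale: null-calibration at n = 180, p = 60, gamma = 0.2 with M = 500
replicates (95% binomial band 0.032–0.071 around the 5% level);
contamination efficiency at n = 180, p = 120, gamma = 0.95, CS = 40% with
M = 200 (reduced from the reference M = 1000; the efficiency ratios are far
from 1, so M = 200 resolves their direction comfortably); scale-functional
recovery at n = 2000.  Tolerances follow the quantity: exact algebraic
identities at 1e-10 to 1e-12, closed-form oracles at 1e-10, brute-force grid
comparisons at the grid resolution, stochastic recoveries at 10–15%.
Degenerate inputs (constant columns under standardization, all-tied
residuals, saturated GCV cells, `X(k)` beyond its validity region) raise
typed errors — `rr_input_error` for bad input, `rr_numeric_error` for
numerical pathology — which the command-line interface maps to exit codes 2
and 3.

# Known limitations

* The saturated-case rank ridge depends on the response scale through
  `2 tau`, inherited from the estimator's definition.
* The Koul–Sievers–McKean `tau` estimator is count-based, hence only
  piecewise-continuous in its inputs; reorderings of the data can shift it
  within its sampling accuracy.
* GCV surfaces for the SSE family can have boundary minima on weak-signal
  saturated data (see the interpolation-guard section); reading `k_opt`
  off such a surface as a physical smoothing scale is not meaningful there.
* Normal-score `tau` estimation is not implemented; Wilcoxon and sign scores
  cover the supported inference paths.
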