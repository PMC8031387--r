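# rankridge

Robust rank-based ridge regression with Stein-type shrinkage, for
multicollinear, outlier-contaminated, possibly high-dimensional (p > n)
linear models — the typical shape of transcriptomic prediction problems such
as regressing a log production rate on thousands of log gene-expression
levels.  The intended users are statisticians and computational biologists
who need coefficient estimates and a global significance test that survive
response outliers and p > n.

## The method

For the centred linear model *y = Xβ + ε* the package provides, with
*A<sub>k</sub> = n⁻¹XᵀX + kI<sub>p</sub>*:

* the **rank (R-) estimator** β̂<sub>ψ</sub> = argmin ‖y − Xβ‖<sub>ψ</sub>,
  where ‖v‖<sub>ψ</sub> = Σᵢ a(R(vᵢ)) vᵢ is the Jaeckel dispersion with
  Wilcoxon scores a(i) = ψ(i/(n+1)), ψ(u) = √12 (u − ½) — robust to response
  outliers (`fit_rank()`);
* the **rank ridge estimator**
  β̂<sub>ψ</sub>(k) = s·A<sub>k</sub>⁻¹ Xᵀ ŷ<sub>ψ</sub>
  (`ridge_rank()`), defined also when p > n;
* the **ridge rank-based (RRB) test** of H₀: β = 0 with the quadratic-form
  statistic
  R<sub>n</sub>(k) = σ<sub>a</sub>⁻² aᵀ(R(y)) X A<sub>k</sub>⁻¹ [X(k)]⁻¹ A<sub>k</sub>⁻¹ Xᵀ a(R(y)),
  X(k) = B⁻¹ − kB⁻², B = n⁻¹XᵀX + I (`rrb_test()`), with an
  exact-permutation-moment calibrated decision rule by default;
* the **Stein-type shrinkage estimator (SSE)**
  β̂<sub>ψ</sub><sup>(S)</sup>(k, d) = (1 − d/R<sub>n</sub>(k)) β̂<sub>ψ</sub>(k)
  (`sse()`);
* a **generalized cross-validation** criterion minimized jointly over the
  ridge parameter k and shrinkage parameter d through the hat matrix
  L(k, d) = (1 − d/R<sub>n</sub>(k))·2τ̂<sub>ψ</sub>·s·X A<sub>k</sub>⁻¹Xᵀ
  (`optimize_gcv()`);
* assessment metrics — leave-one-out CV, R², Monte-Carlo relative efficiency,
  leverage (`loo_cv()`, `r_squared()`, `efficiency()`, `leverage()`) — and a
  **simulation framework** reproducing collinear correlation-form designs,
  sparse coefficient regimes and one-sided non-central-χ² contamination
  (`gen_design()`, `gen_beta()`, `gen_errors()`, `run_monte_carlo()`).

The methods vignette (`vignettes/rank-ridge-shrinkage.Rmd`) documents the
model, the scaling conventions, the test-statistic calibration, the GCV
guards and the generator in detail.

## Worked example

```r
library(rankridge)

# a contaminated, collinear simulated dataset: n = 60 samples, p = 12
# covariates, pairwise correlation 0.9^2, 20% one-sided outliers
sim  <- simulate_dataset(sim_config(n = 60, p = 12, gamma = 0.9,
                                    cs_percent = 20, M = 1, seed = 42))
data <- sim$data

# joint GCV selection of the ridge and shrinkage parameters for the SSE
tuned <- optimize_gcv(data, estimator = "sse")
tuned
#> <tuning_result> sse: k_opt = 0.00316488, d_opt = 48764.8, min GCV = 18.1097 (refined)

fit <- sse(data, tuned$k_opt, tuned$d_opt, rn = tuned$rn_opt)
fit
#> <shrinkage_estimate> k = 0.00316488, d = 48764.8, R_n(k) = 59339.4261, shrink factor = 0.1782

rrb_test(data, tuned$k_opt)
#> <rr_test> RRB: statistic = 59339.4261, df = 12, critical = 79413.5582 (alpha = 0.05) -> do not reject H0

round(rbind(ridge_ls   = ridge_ls(data, tuned$k_opt)[1:6],
            rank_ridge = ridge_rank(data, tuned$k_opt)$coef[1:6],
            sse        = fit$beta[1:6],
            truth      = sim$beta_true[1:6]), 3)
#>               x1     x2     x3    x4     x5    x6
#> ridge_ls   3.741 -1.743 -9.142 2.182 -4.690 8.965
#> rank_ridge 1.838 -1.237 -4.326 0.679 -1.422 4.076
#> sse        0.328 -0.220 -0.771 0.121 -0.253 0.726
#> truth      0.434 -1.094  0.000 0.000  0.000 0.000
```

Reading the output: GCV picks a small ridge parameter and a shrinkage level
that multiplies the rank ridge coefficients by 0.178 (the factor
1 − d/R<sub>n</sub>(k)); the moment-calibrated RRB test does not reject the
global null at this weak signal.  The one-sided outliers drag the
least-squares ridge coefficients far from the truth (entries near ±9 where
the truth is 0), while the rank-based fits stay an order of magnitude
closer.  A Monte-Carlo repeat of the same configuration quantifies that
ordering as relative efficiencies:

```r
run_monte_carlo(sim_config(60, 12, gamma = 0.9, cs_percent = 20,
                           M = 50, seed = 7))
#> risks (mean squared estimation error):
#>   ridge_ls ridge_rank        sse
#>   90.62357    1.99727    1.97082
#> efficiencies vs ridge_ls :
#>   ridge_ls ridge_rank        sse
#>     1.0000    45.3738    45.9827
#> RRB rejection rate: 0.0600 (alpha = 0.05, moment calibration)
#> F   rejection rate: 0.0600
```

A command-line interface over the same functions ships in
`inst/exec/rankridge` (subcommands `fit`, `test`, `tune`, `cv`, `simulate`,
`fixture`; exit codes 0 = success, 2 = input error, 3 = numerical validity
error).

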