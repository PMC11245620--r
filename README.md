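# ccapower

Stability, power and sample-size analysis for canonical correlation
analysis (CCA) and partial least squares (PLS-SVD).

## Why

CCA and PLS find weight vectors `w_X`, `w_Y` that maximize the correlation
(CCA) or covariance (PLS) between the scores `X w_X` and `Y w_Y`. In
high-dimensional applications — brain–behavior association studies,
multi-omics — the scientific conclusion usually rests on *interpreting the
weights*, which is only defensible if they are stable across independent
samples. A statistically significant association is not evidence of stable
weights: with few samples per feature, in-sample association strengths are
badly inflated and estimated weight profiles can be close to orthogonal to
the truth while still clearing a permutation test.

ccapower quantifies this with a generative model. The two datasets are
jointly multivariate normal; within-set principal component spectra follow
power laws `sigma_i = c * i^a` (decay exponent `a <= 0`); and a single
rank-1 between-set mode with known true correlation `r_true` is planted in
the cross-covariance block — via `Sigma_XY = s w_X w_Y^T` for PLS, or
`Sigma_XY = Sigma_XX^{1/2} (Sigma_XX^{1/2} w_X) r_true (Sigma_YY^{1/2}
w_Y)^T Sigma_YY^{1/2}` for CCA, so the first canonical correlation equals
`r_true` exactly. Because the truth is known, every element of a fitted
solution can be scored: statistical power, relative association-strength
error Δr, weight error Δw, score error Δt and loading error Δℓ (the last
three as one minus absolute cosine/correlation with the truth), plus weight
stability and similarity to the first principal component axis.

On top of the model the package provides:

- seeded parameter sweeps over `r_true`, dimensionality, spectrum decay and
  sample size (`run_sweep()`),
- required sample sizes by cubic-spline interpolation of metric curves
  under the combined criterion power ≥ 0.9 and all errors ≤ 0.1, taking
  the maximum across the five metrics (`required_from_sweep()`),
- a log-linear sample-size calculator fitted to sweep output
  (`calibrate_calculator()`, `predict_sample_size()`),
- retrospective weight-error estimation for a *reported* CCA given only
  `(n, p_X, p_Y, r_observed)` (`estimate_weight_error()`),
- an empirical-data pipeline: deconfounding, rank-based inverse normal
  transform, PCA reduction, pairwise-complete covariance with
  nearest-positive-definite repair, spectrum decay estimation, and a
  subsampled non-overlapping stability audit
  (`subsampled_stability_analysis()`).

## Worked example

```r
library(ccapower)

model <- generate_model(p_x = 8, p_y = 8, a_x = -1, a_y = -1,
                        r_true = 0.3, method = "cca", seed = 1)

for (n in c(80, 800)) {
  d  <- sample_dataset(model, n, seed = 2)
  f  <- fit_cca_pls(d$X, d$Y, "cca")
  pt <- permutation_test(d$X, d$Y, "cca", n_perm = 999, seed = 3)
  cv <- cross_validate(d$X, d$Y, "cca", seed = 4)
  cat(sprintf("n = %4d: r_hat = %.3f  p = %.3f  cv = %.3f  weight error = %.3f\n",
              n, f$assoc_strength, pt$p_value, cv$mean_value,
              weight_error(f$w_x_hat, f$w_y_hat, model$w_x_true, model$w_y_true)))
}
#> n =   80: r_hat = 0.703  p = 0.002  cv = 0.418  weight error = 0.324
#> n =  800: r_hat = 0.340  p = 0.001  cv = 0.282  weight error = 0.073
```

At 5 samples per feature (n = 80 for 16 features) the association is
"significant" (p = 0.002) yet the canonical correlation is estimated at
0.70 against a true value of 0.30, and the weight vector is off by a
cosine error of 0.32 — interpretation of individual features would be
unreliable. At 50 samples per feature the estimate (0.34) approaches the
truth and the weight error drops to 0.07. Sweeping this systematically and
applying the combined criterion yields the headline number: at
`r_true = 0.3` (with decay sum −2), CCA needs roughly **50 samples per
feature** for stable, accurate solutions — far more than the 5 or so that
are typical of the published literature.

A command-line front end covering the main workflows ships in
`inst/cli/ccapower` (`generate`, `sweep`, `sample-size`, `calibrate`,
`weight-error`, `audit`), configured by a YAML file plus `--seed`,
`--out`, `--reps`, `--n-perm`, `--quiet` flags.

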