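# bimansem

Simulation-backed analysis of bimanual finger coordination and its
neural connectivity, for motor-control and neuroimaging researchers
who want every stage of such an analysis — behavioral scoring,
first-level GLM, and path-analytic connectivity modelling — as
tested, reusable R functions with synthetic ground truth.

The paradigm: visually paced bimanual tapping in a stable **in-phase**
mode (mirror-symmetric fingers) and a difficult **anti-phase** mode
(parallel fingers), at pacing frequencies of 1.0/1.5/2.0 Hz, in young
and elderly groups, inside a 340 s block-design fMRI run (20 s blocks,
9 rest + 8 task, TR 3 s, 113 volumes). The package provides:

* **Behavioral scoring** — a press is correct when its latency to the
  opposite hand's paired finger beats the unpaired one
  (in-phase: same finger closer; anti-phase: different finger closer);
  accuracy = correct / total presses; plus selection of the pacing
  frequency that maximizes the young−elderly anti-phase gap subject to
  a young-performance floor.
* **First-level GLM** — canonical double-gamma HRF-convolved boxcars
  with temporal derivatives, intercept and polynomial drift, OLS
  estimates and task-vs-rest contrasts per ROI.
* **A from-scratch ML SEM engine** for observed-variable path models
  over the ten motor-association ROIs (L/R × M1, S1, PMd, SMA, SPL):
  the model-implied covariance is Σ(θ) = (I−A)⁻¹Ψ(I−A)⁻ᵀ and fitting
  minimizes F = log|Σ| + tr(SΣ⁻¹) − log|S| − p, with χ² = (N−1)F_min,
  standard errors from the observed information, standardized path
  coefficients β, the GFI/CFI/RMSEA battery, χ²-based AIC/BIC, greedy
  specification search (add/delete/reverse edges), significance tiers
  (p<0.001 / p<0.01 / ns) and cross-condition tier comparison.
* **Synthetic-data generators** for press-event streams, multivariate
  ROI observations drawn from known path models, and BOLD-like ROI
  series with AR(1) noise — so all of the above is testable without
  any external data.

## Worked example

```r
library(bimansem)

truth <- connectivity_fixture("young", "anti_phase")   # known 26-path model
x     <- simulate_roi_observations(truth, 500, seed = 2)
fit   <- fit_ml(as_path_model(truth), sample_moments(x))
print(fit)
```

```
sem_fit: 10 variables, 26 paths, N = 500
  chisq(19) = 26.222, p = 0.124 | GFI 0.990 CFI 0.998 RMSEA 0.028 | AIC 98.2 BIC 249.9
  from    to estimate    se      z p_value   beta
 L.PMd R.PMd    0.603 0.120  5.047   0.000  0.475
 R.PMd L.PMd    0.349 0.114  3.076   0.002  0.443
 L.SMA R.SMA    0.347 0.273  1.270   0.204  0.306
  R.M1  L.M1    0.623 0.120  5.204   0.000  0.375
 ...
```

The χ² test is non-significant (p = 0.124 > 0.05), GFI/CFI exceed
0.95 and RMSEA is below 0.05, so the fitted topology meets the
conventional acceptance battery (`meets_fit_criteria(fit)` is `TRUE`);
the strong generating paths land in the p<0.001 tier of
`classify_path_tiers(fit)`.

The full pipeline — simulate press events for both groups at all
three frequencies, score them, select the frequency, simulate BOLD,
extract GLM betas, fit all four group × mode path models and compare
tiers:

```r
report <- run_pipeline(pipeline_config(seed = 1), out_dir = "out")
print(report)
#> selected pacing frequency: 1.5 Hz
#> accuracy (mean [95% CI]):
#>   young   anti_phase 1.5 Hz: 0.899 [0.889, 0.909]
#>   elderly anti_phase 1.5 Hz: 0.371 [0.354, 0.389]
#>   ...
#> SEM fits:
#>   young.in_phase     chisq(19) =  26.19, p = 0.125 | GFI 0.814 CFI 0.946 RMSEA 0.141
#>   ...
```

1.5 Hz is selected because 2.0 Hz drops young anti-phase accuracy
below the 0.8 floor while the young−elderly gap peaks at 1.5 Hz. Note
the honest small-sample behavior at N = 20 subjects per group: fit
indices are much noisier than at n = 500 (see the methods vignette,
`vignettes/bimanual-connectivity.Rmd`, on chi-square inflation and
improper solutions in this regime).

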