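# spectralct

Fully Bayesian spectral spatial regression for region-level cortical
thickness. The package compares thickness between patient groups (left and
right temporal lobe epilepsy) and healthy controls across the 68 regions of
a Desikan-style parcellation while modelling the spatial dependence between
regions, and benchmarks the resulting region selections in a classification
task. Because cohorts of this kind are not publicly distributable, it ships
a synthetic cohort generator with known ground truth, used by all
calibration studies and tests.

## The model

For subject *i* at region centroid *v* on the unit sphere,

```
Y_i(v) = Σ_k X_ik B_k(v) + Σ_j Z_j(v) γ_ij + E_i(v)
```

* `B_k(v)` — spatially varying fixed-effect surfaces (intercept, centered
  age, sex, LTLE/RTLE dummies with HC baseline);
* `Z_j` — the `J` lowest-frequency spherical-harmonic basis functions, with
  subject coefficients `γ_i ~ N(0, Σ)` giving low-rank nonstationary
  covariance;
* `E_i` — a Gaussian process with Matérn-plus-nugget covariance
  `σ² 1[v=v'] + τ² M_ν(3d/φ)` on chordal distance `d`.

A spherical-harmonic transform at maximum degree `L = 7` turns each
68-region profile into 64 de-correlated real coefficients; in the spectral
domain every frequency carries an independent normal likelihood with
variance `λ(l) = σ² + τ² c (α² + l(l+1))^-(ν+1)`, `α = 3/φ`. The
hierarchical prior stack (horseshoe or Gaussian shrinkage on fixed-effect
basis coefficients, inverse-Wishart random-effect covariance, three
Matérn variance blocks on unconstrained scales) is sampled by conjugate
Gibbs updates plus adaptive random-walk Metropolis for the Matérn shapes.
Group maps are posterior z-scores (posterior mean / posterior SD per
region), thresholded by the one-sided Bayesian false-discovery-rate rule
at `q = 0.01`.

## Worked example

```r
library(spectralct)
library(dplyr)

atlas  <- make_atlas(1)                      # synthetic 68-region sphere atlas
basis  <- harmonic_basis(atlas, 7)           # 68 points x 64 real columns
truth  <- ground_truth(atlas, basis, J = 9)  # -0.15 mm LTLE deficit, cingulate/frontal
ds     <- simulate_thickness(atlas, table1_cohort(), truth, basis)
ds
#> <thickness_dataset> 53 subjects x 68 regions; groups: HC=20 LTLE=19 RTLE=14

fit <- fit_spectral(ds, spectral_config(seed = 2))
fit
#> <spectral_fit> 53 subjects, 68 regions, L = 7 , J = 9
#>   1000 retained draws ( 5000 iterations, burn-in 1000 , thin 4 )

tidy(fit) |> filter(term == "LTLE") |> arrange(statistic) |> head(3)
#> # A tibble: 3 × 6
#>   term  region                      hemisphere estimate std.error statistic
#>   <chr> <chr>                       <chr>         <dbl>     <dbl>     <dbl>
#> 1 LTLE  rostralmiddlefrontal_rh     R           -0.0499     0.388    -0.129
#> 2 LTLE  rostralanteriorcingulate_rh R           -0.0509     0.403    -0.126
#> 3 LTLE  posteriorcingulate_rh       R           -0.0419     0.378    -0.111

glance(fdr_map(fit, "LTLE", q = 0.05))
#> # A tibble: 1 × 4
#>       q n_regions n_rejected z_threshold
#>   <dbl>     <int>      <int>       <dbl>
#> 1  0.05        68          0          NA
```

`estimate` is the posterior mean effect in mm per covariate unit,
`statistic` the posterior z-score; negative values mean thinning in the
LTLE group relative to controls. Here the planted 0.15 mm deficit is too
small to clear the FDR threshold at 19 patients — the honest outcome for
an effect of that size at this sample size; the packaged recovery study
(`recovery_study()`) shows the intervals are calibrated, and a 0.5 mm
deficit is detected reliably.

Other entry points: `posterior_null_prob()` / `bayesian_fdr()` for the
multiplicity rule, `loocv_mse()` / `loocv_grid()` / `select_best()` for
the 16-configuration model comparison, `regionwise_glm()`,
`mlp_loocv_scores()`, `roc_auc()` and `classification_benchmark()` for the
classifier benchmark, `chisq_homogeneity()` / `anova_from_summary()` /
`pooled_moments()` for cohort demographics, and `run_pipeline()` (or
`inst/cli/spectralct.R`) to drive everything from a YAML config.
`autoplot()` methods draw z-score maps and ROC curves; see the vignette
`vignettes/spectral-model.Rmd` for the model, priors, and design
decisions.

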