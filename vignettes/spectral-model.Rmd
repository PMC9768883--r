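---
title: "The spectral Bayesian model for regional cortical thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spectral Bayesian model for regional cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralct)
```

## The problem

Regional cortical thickness measurements are spatially dependent: nearby
regions of the cortex thin together, and subject-level anatomy induces
long-range correlation across the whole parcellation. Comparing groups
region by region with t tests or separate regressions ignores both, which
costs power and inflates the type-I error of the resulting maps. This
package implements a fully Bayesian spatial regression for subjects-by-
regions thickness tables (we work with the 68-region Desikan parcellation,
34 per hemisphere) that models those dependencies explicitly and produces
region-level posterior z-score maps with one-sided Bayesian FDR control.

## Model

For subject $i$ and region centroid $v$ on the unit sphere,

$$Y_i(v) = \sum_{k=0}^{p} X_{ik} B_k(v) + \sum_{j=1}^{J} Z_j(v)\,\gamma_{ij} + E_i(v),$$

where $B_k(v)$ are spatially varying fixed-effect surfaces (intercept,
centered age, sex, and LTLE/RTLE group dummies against the HC baseline),
$Z_j$ are fixed low-frequency spherical-harmonic basis functions whose
subject coefficients $\gamma_i \sim N(0, \Sigma)$ capture low-rank
nonstationary covariance, and $E_i$ is a mean-zero Gaussian process with
isotropic Matérn-plus-nugget covariance

$$\mathrm{Cov}[E_i(v), E_i(v')] = \sigma^2 I(v = v') + \tau^2 M_\nu(3d/\varphi),$$

with $d$ the chordal distance between the unit vectors of $v$ and $v'$.
Chordal distance keeps the Matérn family positive definite on the sphere
for every smoothness; the $3/\varphi$ scaling makes the correlation
roughly 0.05 at $d = \varphi$ when $\nu = 1/2$, so $\varphi$ reads as a
range.

### Spectral de-correlation

Fitting in the spatial domain requires dense 68x68 covariance solves
inside MCMC. Instead, every subject's profile is projected onto a real
spherical-harmonic basis truncated at degree $L$. The basis columns are
built from $P_l^m(\cos s_1)e^{-ims_2}$ with the Condon–Shortley phase,
scaled by $1/\sqrt{2l+1}$ and Schmidt semi-normalized by
$\sqrt{(l-m)!/(l+m)!}$; each $m>0$ harmonic contributes $\sqrt 2$-scaled
real and imaginary columns so a real field keeps one real coefficient per
frequency, $(L+1)^2$ in total. The semi-normalization matters: raw
associated Legendre functions grow like $(l+m)!$, and without putting all
orders of a degree on a common scale a "variance per degree" model is
meaningless numerically. At the default $L = 7$ a 68-region profile
becomes 64 coefficients.

Because the 68 centroids are scattered rather than a quadrature grid, the
forward transform is least squares, solved by QR. A ridge
(`1e-8 * trace/cols`) is kept only as a fallback for rank-deficient point
sets; on quasi-uniform 64-point designs the QR round trip is exact to
~1e-10, while regularized normal equations would lose the round trip
entirely at the ~1e5 condition numbers these systems have.

Both hemispheres are placed on one sphere (left centroids on the
longitude half $[0,\pi)$, right on $[\pi,2\pi)$), since the transform is
taken jointly over all 68 regions. This placement is a convention of the
synthetic atlas, not an anatomical claim.

After the transform, the model becomes independent across frequencies
$\omega$: the spectral coefficients $\tilde Y_i(\omega)$ are normal with
mean $\sum_k X_{ik}\tilde B_k(\omega) (+ \gamma_{ij}$ on the $J$
lowest-frequency columns$)$ and variance $\tilde\lambda(\omega|\theta)$.
We take the Matérn/SPDE spectral analogue on the sphere,

$$\tilde\lambda(l) = \sigma^2 + \tau^2\, c\, (\alpha^2 + l(l+1))^{-(\nu+1)},
\qquad \alpha = 3/\varphi,$$

with $c$ normalizing the discrete spectral measure
$\sum_{l\le 50}(2l+1)\,c\,(\alpha^2+l(l+1))^{-(\nu+1)}$ to one so that a
nugget-free process integrates back to $\tau^2$. The exact spectral
density used in the literature this model descends from is not uniquely
pinned down; this form is the standard correspondence and exposes the
same four parameters.

### Priors

Three Matérn blocks carry the variance structure: residual ($\theta$),
intercept process ($\theta_0$) and one slope process shared by all
covariates ($\theta_1$). Each is sampled on the unconstrained scale
(total variance $v$, logit spatial proportion $r$, log range, log
smoothness) with $v \sim$ InvGamma$(\epsilon,\epsilon)$ conjugate,
$r \sim N(0,1)$, $\log\varphi \sim N(0, 1/\epsilon^2)$,
$\log\nu \sim N(-2, 1)$, $\epsilon = 0.1$. The fixed-effect surfaces get
prior means $\sum_j \tilde Z_j(\omega)\beta_{kj}$ on the low-frequency
window, with $\beta_{0j} \sim N(0,\delta_0^2)$ and, for covariates,
either a Gaussian prior $N(0, \delta_k^2)$ or the horseshoe
($\beta_{kj} \sim N(0,\delta_{kj}^2)$,
$\delta_{kj} \sim \mathrm{halfCauchy}(\delta_k)$, implemented through the
inverse-gamma scale-mixture augmentation so every variance update stays
conjugate). $\Sigma \sim$ InvWishart$(J+\epsilon,
\frac{\nu_3}{J+\epsilon}I_J)$; the scale hyperparameter $\nu_3$ carries
its own InvGamma$(\epsilon,\epsilon)$ prior and is sampled by a
random-walk Metropolis step on $\log\nu_3$ (its full conditional is
generalized inverse Gaussian; a 1-D random walk is simpler and mixes
fine at $J \le 9$).

### Sampler

All updates are Gibbs except the three $(r, \log\varphi, \log\nu)$ shape
blocks and $\log\nu_3$, which use Gaussian random walks adapted to
25–45% acceptance during burn-in only (frozen afterwards, preserving
ergodicity). Because the spectral variances depend only on the degree,
the joint update of all five fixed-effect surfaces needs one small
Cholesky per degree (8 at $L=7$) and the random-effect update one $J
\times J$ Cholesky shared by all subjects, which keeps the sampler fast
in plain R. The desk-scale default schedule is 5,000 iterations, 1,000
burn-in, thin 4; `preset = "paper"` switches to 100,000 / 10,000 / 10.
Retained draw counts are exactly `(iterations - burnin)/thin`.

For conjugate-oracle testing, any variance block can be clamped via
`spectral_config(fixed = ...)`; with all blocks clamped in the
independent/Gaussian/no-random-effect configuration the per-frequency
posterior is available in closed form and the sampler is checked against
it to Monte-Carlo accuracy.

## Inference outputs

Posterior z-scores are the ratio of posterior mean to posterior SD of
each $B_k(v)$, computed by pushing every retained spectral draw back
through the inverse transform. Thinning hypotheses are one-sided
($H_0: B_k(v) \ge 0$), with the posterior null probability estimated as
the fraction of draws $\ge 0$. The Bayesian FDR rule sorts those
probabilities and rejects the largest prefix whose running mean stays
below $q$ (default 0.01); the reported "z threshold" is the largest
posterior z among the rejected regions, which is data dependent by
construction.

## The synthetic cohort generator

Real MRI cohorts of this kind are not publicly distributable, so the
package ships a generator that emulates the study conditions: a 68-region
synthetic atlas (two interleaved Fibonacci lattices, one per hemisphere
half, jittered per seed and kept > 0.2 apart in chordal distance); a
53-subject cohort with groups of 20 HC / 19 LTLE / 14 RTLE, sex splits
10/10, 11/8, 10/4, and group age moments 27.95 ± 6.32, 32.10 ± 8.47,
28.28 ± 6.28 matched exactly (ages are drawn from the corresponding
normals under a fixed seed and affinely adjusted — means and SDs are the
only constraints available, so higher moments are synthetic); and
thickness surfaces generated exactly from the model above. The default
baseline surface is a smooth harmonic expansion around 2.7 mm so values
land in the range real parcellations report; default deficits are
-0.15 mm for LTLE over cingulate/frontal clusters, -0.10 mm for RTLE at
right entorhinal, -0.005 mm/year for age, chosen as magnitudes typical of
published group differences. Residual defaults are
$\sigma^2 = 0.01, \tau^2 = 0.02, \varphi = 0.5, \nu = 1$ (regional SD
about 0.17 mm) with subject random effects $\Sigma = 0.004 I_9$.

What the generator does *not* emulate: vertex-level structure within
regions, measurement artefacts, site effects, or any relationship between
effects and clinical covariates beyond the linear model. Passing
calibration tests on these cohorts therefore demonstrates correctness of
the machinery under the model's own assumptions, not robustness to real
scanner data.

## Calibration studies and their problem sizes

Two replicate studies are packaged as functions so tests and scripts can
run them identically. `recovery_study()` plants a smooth negative group
effect (a harmonic bump with -0.5 mm peak, projected into the basis span
so the truth is representable at the working degree) and measures
empirical coverage of 90% equal-tailed credible intervals at the regions
with a substantial deficit; we run 50 replicates of 40 subjects with
2,000-iteration chains, sizes at which the coverage estimate's
Monte-Carlo error is a few percent. Planting a sharp single-region spike
instead would conflate interval calibration with representation error —
an $L=7$ basis cannot express a spike, so the model estimates its smooth
projection and intervals at the spike undercover for that reason alone.
`fdr_null_study()` simulates cohorts with all covariate effects zero and
records the realized false-discovery proportion of the q = 0.01 map over
50 replicates (every rejection on null data is false, so the FDP is the
indicator of any rejection).

## Model comparison under the no-leakage rule

`loocv_mse()` scores a configuration by leave-one-out posterior
predictive mean squared error, and `loocv_grid()` runs the 16-point grid
(residual structure x fixed-effect prior x nonstationarity x J in
{4, 9}). A held-out subject's prediction uses only their covariates: the
random effects are marginalized to their prior mean, so no subject
-specific information leaks. A direct consequence — verified here by
paired simulation — is that on cohorts generated with iid harmonic random
effects the grid's structural choices move the LOOCV MSE only through
second-order estimation efficiency: paired MSE gaps between matched
configurations are about 1% and sign-random at desk scale. Grid MSE
differences should therefore be read as meaningful only when they are
large relative to that scale, and the packaged tests freeze the paired
equivalence property rather than a winner. Conditioning part of the
held-out subject's own data to estimate their $\gamma$ would create
genuine separations, but crosses the leakage line this design
deliberately draws.

## Classification benchmark

`classification_benchmark()` compares two region-selection routes into
the same shallow classifier: regions flagged by the Bayesian FDR map
versus regions with negative group coefficients at p < 0.05 from
per-region OLS of thickness on group, age and sex. Features feed a
one-hidden-layer perceptron (logistic hidden units, linear output,
default 3 hidden units — the size is not dictated by the benchmark's
design, so it is exposed in `mlp_spec()`), trained per leave-one-out fold
with features standardized by training-fold statistics only. Pooled
held-out scores give the ROC; the AUC is the Mann–Whitney pair
probability with ties counted one half.

## Numerical choices and edge cases

- Forward transform: QR least squares; ridge fallback only on rank
  deficiency. Uniformly random 64-point designs at $L=7$ are numerically
  singular (condition ~1e9) for any solver; quasi-uniform designs are the
  intended use.
- Metropolis proposals that overflow the spectral shape (extreme ranges /
  smoothness) evaluate to non-finite likelihoods and are rejected rather
  than propagated.
- A non-positive-definite $\Sigma$ draw is retried with a 1e-8 jitter and
  counted in the fit's `jitter_events`.
- Degenerate chains (zero posterior SD at a region) raise an error naming
  the region instead of returning infinite z-scores.
- `matern_reparam()` clamps the logit spatial proportion at ±30 with a
  warning when a variance component is exactly zero.
- Ties in the FDR sort are included only while the running mean stays
  below q; enlarging q never shrinks the rejection set.

## Limitations

The model compares region-level means; it says nothing about within-
region heterogeneity. The single-sphere placement of both hemispheres is
a convention; per-hemisphere transforms are a plausible alternative not
implemented here. The spectral density is the standard SPDE analogue,
not a derived equivalence to the chordal-distance spatial form. And all
calibration evidence is conditional on the generator's assumptions, as
discussed above.
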