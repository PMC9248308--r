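---
title: "Decomposing scan-rescan reliability into day, session and residual error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing scan-rescan reliability into day, session and residual error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icedecomp)
```

## The model

A test-retest study measures each person on k occasions that are grouped
into days and, within days, into sessions (blocks acquired in one head
positioning). `icedecomp` treats the k measurements of person *p* as

$$y_{po} = \mu_o + T_p + D_{p,\mathrm{day}(o)} + S_{p,\mathrm{session}(o)} + E_{po},$$

with mutually independent zero-mean Gaussian effects: a person-level true
score $T_p$ with variance $\sigma^2_T$, a day effect shared by all
measurements of one day ($\sigma^2_D$), a session effect shared within one
positioning ($\sigma^2_S$), and i.i.d. residual error ($\sigma^2_E$). The
means $\mu_o$ are saturated — one free mean per occasion — so the model
constrains only the covariance:

$$\Sigma = \sigma^2_T \mathbf{1}\mathbf{1}' + \sigma^2_D L_D L_D' +
  \sigma^2_S L_S L_S' + \sigma^2_E I,$$

where $L_D$ and $L_S$ are the binary day/session membership matrices of
the design (`loading_matrix()`).

The default design, `mpm_design()`, has four occasions over two days:
back-to-back scans without repositioning on day 1, and two scans with
repositioning (plus a new prescan) on day 2. The day-1 pair shares one
session factor while each day-2 scan gets its own. This assignment is the
one under which $\sigma^2_S$ is identifiable: repositioning is what defines
a session, so the no-repositioning pair must load on a common session
factor, and its within-pair covariance
($\sigma^2_T + \sigma^2_D + \sigma^2_S$) then separates session variance
from the day-2 within-pair covariance ($\sigma^2_T + \sigma^2_D$). Designs
are fully user-definable (`study_design()`, YAML/JSON-loadable); the
four-occasion layout is merely the named default.

### Assumptions

* Gaussian effects and errors; the likelihood is multivariate normal.
  Heavy-tailed alternatives are deliberately out of scope.
* Complete data: every person contributes all k occasions (listwise
  deletion is available as an explicit option in `reliability_data()`).
* Exchangeable persons — no covariates, no person-specific error
  variances.

## Estimation

`iced()` maximises the likelihood with the occasion means profiled out at
their sample values (their ML estimates under a saturated mean structure).
The profile objective depends on the data only through the ML sample
covariance, so each evaluation is $O(k^3)$ regardless of sample size.
Optimisation is bound-constrained quasi-Newton (L-BFGS-B) with an analytic
gradient; every free component is floored at a **lower bound of 1e-4** on
the scale of the fitted data. Start values come from method-of-moments
reasoning on the sample covariance (cross-day covariance for
$\hat\sigma^2_T$, day-2 within-pair covariance for
$\hat\sigma^2_T+\hat\sigma^2_D$, and so on), clipped to the bounds; on
non-convergence up to three jittered restarts are tried, and a
non-converged result is always flagged, never silent. The convergence
tolerance is tight (relative objective tolerance ~2e-14, gradient
tolerance 1e-12) so that scale-free summaries agree across affine
transformations of the data to well below 1e-6.

Estimates are reported twice: raw, in squared modality units, and rescaled
so the four proportions sum to one. The rescaled true-score proportion *is*
the ICC. In formatted output tables (`iced_table()`), a component whose raw
estimate sits exactly at the lower bound is displayed as 0 — the bound is a
numerical floor, not evidence of nonzero variance — while the raw estimate
retains the bound value.

Because the bound is absolute, two regimes deserve note:

* On data whose total variance is near 1, the bound contributes at most
  ~1e-4 to any proportion and is negligible.
* On data with tiny absolute variance (MT maps have total ROI variance of
  order 1e-3), the bound can be a visible fraction of the total. For that
  regime `iced(standardize = TRUE)` divides the values by the grand SD
  first, which puts the bound on a proportional scale; proportions, ICC,
  ICC2 and test statistics are invariant to this global rescaling whenever
  the solution is interior.

## Reliability coefficients

* **ICC** $= \sigma^2_T / (\sigma^2_T+\sigma^2_D+\sigma^2_S+\sigma^2_E)$:
  reliability of a single measurement.
* **Effective error**: the error variance of the best linear unbiased
  (precision-weighted) composite of all k occasions,
  $1 / (\mathbf{1}' \Sigma_E^{-1} \mathbf{1})$ with
  $\Sigma_E = \Sigma - \sigma^2_T \mathbf{1}\mathbf{1}'$. With only
  residual error it reduces to the classical $\sigma^2_E / k$. The
  precision-weighted composite was chosen over the unweighted mean because
  it is the definition under which the effective error is the smallest
  achievable for the design; the two coincide exactly in the
  pure-residual case, which is also the only case used for validation
  against published values (rows with day and session variance reported as
  zero).
* **ICC2** $= \sigma^2_T / (\sigma^2_T + \text{effective error})$:
  reliability of the whole design.

## Inference

* **Likelihood-ratio tests** (`lrt_component()`): each of
  $\sigma^2_T, \sigma^2_D, \sigma^2_S$ is set to zero in turn and the
  refitted null model compared to the full one; the statistic is twice the
  log-likelihood difference, clipped at zero, against $\chi^2_1$. The
  naive $\chi^2_1$ p-value is the default, matching common practice;
  because the null lies on the boundary of the parameter space a 50:50
  $\chi^2_0{:}\chi^2_1$ mixture option (`mixture = TRUE`) is provided,
  which halves the naive p-value for positive statistics.
* **Wald test** (`wald_residual()`): the residual variance has no
  estimable null model (removing it leaves a singular covariance), so it
  is tested as (estimate/SE)² with the SE from the inverse observed
  information (numerical Hessian of the profile likelihood) at the ML
  solution.
* **Fit statistics** (`fit_stats()`): the model is compared against the
  saturated covariance model; $\chi^2 = (N-1) F_{ML}$ with
  $F_{ML} = \log|\Sigma| + \mathrm{tr}(\Sigma^{-1}S) - \log|S| - k$, the
  degrees of freedom are $k(k+1)/2$ minus the number of free components
  (6 for the default design with all four free), and
  $\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$. The
  $(N-1)$ convention is recorded in the provenance output.
* **Bootstrap CIs** (`bootstrap_ci()`): persons are resampled with
  replacement, the model refitted per resample, and percentile intervals
  taken (the interval type is a convention choice; percentile is the
  default and is recorded in the output). Failed or non-converged
  resamples are dropped and counted; more than 20% drops aborts with a
  diagnostic. All resampling flows from one explicit seed and leaves the
  caller's RNG state untouched.

## Signal-level computations

The parameter maps that feed the reliability analysis derive from
multi-echo FLASH acquisitions, and the package implements the desk-scale
versions of those estimation steps:

* `estatics_fit()`: all echo trains (T1w/PDw/MTw) are fitted jointly by
  unweighted OLS on log-signals with one common slope $-R_2^*$ and one
  TE = 0 intercept per contrast. Echo times are millisecond-valued at the
  interface and converted to seconds internally so $R_2^*$ comes out in
  1/s. Unweighted OLS is the implemented reading; no SNR weighting is
  applied.
* `ernst_signal()` / `dual_flip_angle_r1()`: the spoiled gradient-echo
  steady-state signal
  $S = A \sin\alpha (1-E_1)/(1-\cos\alpha E_1)$, $E_1 = e^{-TR \cdot R_1}$,
  and its inversion from two flip angles (protocol: 6° and 21° at
  TR = 24.5 ms). The inversion is exact bracketed root finding on the
  signal-ratio equation over $R_1 \in [10^{-4}, 100]$ 1/s rather than the
  classical small-angle rational approximation; the approximation is
  available as `dual_flip_angle_r1_approx()` for comparison. Signal
  ratios outside the attainable range of the model raise an error instead
  of extrapolating.
* `calibrate_pd()`: PD maps are rescaled so the white-matter mean equals
  69 percent units, since the global PD level is not identified without an
  external standard.

## Synthetic data: what it emulates and what it does not

`simulate_roi_dataset()` inverts the generative model exactly — Gaussian
person, day, session and residual effects with specified variances added
to occasion means — so the generator and the fitter form a calibrated
pair: across replicates the mean estimated proportions sit on the
simulated truth. Defaults mirror the reference study's conditions: 15
persons, the four-occasion two-day design, occasion means at the
gray-matter MT level (0.874 p.u.), and a total variance of 0.0025 (an SD
of 0.05 p.u. across persons, consistent with percent-level
coefficients of variation at that mean) split 0.883 / 0 / 0.003 / 0.114
across T/D/S/E as in the gray-matter MT decomposition.
`simulate_voxel_maps()` applies the same model per voxel with spatially
varying parameter fields; `simulate_multiecho()` generates
mono-exponential echo trains at the protocol echo times with additive
Gaussian noise.

What the generator does **not** emulate: Rician magnitude noise, motion
and susceptibility artifacts, B0/B1 field inhomogeneity, spatial
autocorrelation between voxels, segmentation and registration error.
Passing tests on synthetic data therefore demonstrate the statistical
machinery — identifiability, unbiasedness, coverage, invariances — not
robustness to MRI physics violations; on real data those upstream effects
end up inside the day/session/residual compartments, which is precisely
what the decomposition is for.

## Voxel-wise analysis

`voxelwise_iced()` applies the identical fit independently at every
in-mask voxel of aligned per-person per-occasion volumes and returns ICC,
ICC2, proportion and convergence-flag maps. Out-of-mask voxels are NA;
per-voxel failures are flagged NA rather than fatal (the handling of
non-convergent voxels is a deliberate choice — flagged, never silently
interpolated). Voxels are processed independently so results do not depend
on traversal order. No spatial smoothing is applied by the fitter; any
smoothing belongs upstream. `roi_extract()` averages labelled voxels into
ROI-level datasets ready for `iced()`.

## Descriptive conventions

`participant_cov()` divides the sample SD (n−1 denominator) of a person's
k values by their mean; `cov_table()` aggregates per-person CoVs across
persons (mean and n−1 SD). `occasion_mean_sd()` reports the grand mean
and the SD across the k occasion-level means. Negative person means raise
an error rather than returning a negative CoV.

## Numerical choices and degenerate inputs

* Convergence: relative objective tolerance ~2e-14, gradient tolerance
  1e-12, at most 500 iterations, up to 3 jittered restarts; the
  `converged` flag is part of every result.
* Singular model covariances (all components at zero) are errors in the
  likelihood, not silently regularised.
* The observed information for the Wald test is computed without the
  non-negativity guard so finite-difference steps may legitimately cross
  zero near bound-adjacent estimates.
* Estimation refuses fewer than 3 persons, and missing cells are a hard
  error unless listwise deletion is requested explicitly.

## Problem sizes used in the validation suite

The test suite validates parameter recovery on 200 replicates of 100
persons, bootstrap coverage on 200 replicates with 199 resamples each,
and voxel-wise recovery on an 8×8×2 two-region phantom with 60 persons —
sizes chosen so the full suite documents the estimator's behaviour while
remaining comfortably runnable on one CPU. Large-sample checks (such as
the 50,000-person covariance comparison) are generated at run time, never
stored.

## Known limitations

* The model is the fixed T/D/S/E decomposition, not a general SEM: no
  arbitrary path structures, no REML, no covariates.
* ICC2 is design-specific; comparing ICC2 across designs with different k
  conflates reliability with design efficiency.
* Percentile bootstrap intervals can undercover for variance-ratio
  statistics near the boundary (ICC close to 0 or 1).
* Published ICC2 values for decompositions with nonzero day/session
  variance are not exactly recoverable from rounded printed proportions
  under any effective-error definition, so only pure-residual rows serve
  as worked examples.
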