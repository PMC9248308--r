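# icedecomp

Variance-component decomposition of scan–rescan reliability for
quantitative MRI.

## The problem

Quantitative MRI protocols such as multiparameter mapping (MPM) deliver
maps of magnetization transfer saturation (MT), proton density (PD), and
the relaxation rates R1 and R2\*. Before such maps can be used to track
within-person change — learning, training, disease progression — one has
to know how much of their variability reflects stable between-person
differences and how much is measurement error, and *where that error comes
from*. A scan–rescan design with a deliberate structure makes the sources
separable: each participant is measured twice back-to-back on day 1
(without repositioning) and twice on day 2 with repositioning (and a new
prescan) in between.

`icedecomp` models the resulting four measurements per person as
multivariate normal with a saturated mean structure and the structured
covariance

```
Σ = σ²_T 11' + σ²_D L_D L_D' + σ²_S L_S L_S' + σ²_E I
```

where `σ²_T` is true-score (between-person) variance, `σ²_D` day-specific
error shared within a day, `σ²_S` session-specific error shared within one
head positioning, `σ²_E` residual error, and `L_D`, `L_S` are binary
day/session membership matrices. Maximum-likelihood estimates (each
component floored at a small lower bound, 1e-4) are rescaled to
proportions of total variance, giving directly:

- **ICC** = σ²_T / (σ²_T + σ²_D + σ²_S + σ²_E), the test–retest
  reliability of a *single* measurement (equal to the rescaled true-score
  proportion);
- **ICC2** = σ²_T / (σ²_T + effective error), the reliability of the whole
  k-occasion design, where the effective error is the error variance of
  the precision-weighted composite of all occasions
  (`1 / (1' Σ_E⁻¹ 1)`, reducing to σ²_E / k for pure residual error);
- likelihood-ratio tests of σ²_T, σ²_D, σ²_S against their null models and
  a Wald test of σ²_E;
- χ²/RMSEA model-fit statistics and person-bootstrap percentile confidence
  intervals.

The package also implements the signal-estimation steps the maps derive
from — joint log-linear multi-echo R2\* fitting (ESTATICS), the Ernst
equation with dual-flip-angle R1 recovery, PD white-matter calibration —
plus voxel-wise reliability maps (NIfTI in/out), coefficient-of-variation
summaries, and seeded synthetic-data generators for every stage.

## Worked example

```r
library(icedecomp)

design <- mpm_design()          # D1M1 D1M2 | D2M1 D2M2, 2 days, 3 sessions
dat <- simulate_roi_dataset(
  n_persons = 100, occasion_means = rep(10, 4),
  components = variance_components(0.6, 0.1, 0.1, 0.2), seed = 5)

fit <- iced(dat)
fit
#> Intra-class effect decomposition (100 persons x 4 occasions)
#>
#> Variance proportions (sum to 1):
#> var_t var_d var_s var_e
#> 0.559 0.151 0.065 0.225
#>
#> ICC  = 0.559   ICC2 = 0.782   effective error = 0.146
#> log-likelihood = -447.2439

summary(fit)
#> Model fit: chi-square = 5.691, df = 6, RMSEA = 0.000
#>
#> Component tests:
#>  component test statistic df  p_value
#>      var_t  LRT    53.160  1 3.07e-13
#>      var_d  LRT     8.137  1 4.34e-03
#>      var_s  LRT     1.667  1 1.97e-01
#>      var_e Wald    50.934  1 9.55e-13

bootstrap_ci(fit, "icc", n_boot = 1000, seed = 3)
#> 95% percentile bootstrap CI for icc: [0.453, 0.660]  (1000 resamples, 0 dropped)
```

The data were generated with 60% true-score, 10% day, 10% session and 20%
residual variance; the fit recovers those proportions within sampling
error, flags the (true) day effect as significant at this sample size, and
cannot distinguish the small session effect from zero — exactly the
trade-off the decomposition quantifies. ICC2 exceeds ICC because averaging
four occasions shrinks the error term.

A thin command-line wrapper (`inst/cli/icedecomp`) exposes `simulate`,
`fit-roi`, `fit-voxelwise`, `estatics` and `cov` subcommands over the same
functions, writing CSV tables, NIfTI maps and a provenance JSON that
records the seed and statistical conventions.

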