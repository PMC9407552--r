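---
title: "Evaluating pear stone cell content from Vis/NIR spectra"
author: "pearscc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pear stone cell content from Vis/NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearscc)
```

## The problem

Stone cells are clusters of lignified sclereids in pear pulp. They degrade
eating quality, and their content — the stone cell content, SCC — is
traditionally measured destructively: pulp cubes are frozen, homogenised,
sedimented, and the dried sclereid mass is weighed, giving

$$X = \frac{m_{total} - m_{filter}}{m_{pulp}} \times 100\%$$

with $m_{total}$ the mass of filter paper plus dried stone cells,
$m_{filter}$ the filter paper mass, and $m_{pulp}$ the fresh pulp mass
(`compute_scc()`). Typical values for fragrant pears span roughly
0.24–0.66 % with a mean near 0.49 %.

Visible/near-infrared diffuse reflectance spectroscopy offers a
non-destructive alternative. Reflectance between roughly 500 and 1000 nm
carries pigment bands (chlorophyll near 680 nm, anthocyanin-related
structure near 550 nm) and carbohydrate/water overtone bands (near 750 and
980 nm). Because SCC correlates negatively with carbohydrate content, these
bands carry indirect SCC information. This package implements the full
calibration pipeline from replicate reflectance spectra to a tuned
regression model, plus a synthetic data generator with known ground truth
so that every stage can be verified without proprietary instrument data.

## Pipeline overview

1. **Trim** to the effective window (default 498–1020 nm, closed interval):
   channels at the grid edges are dominated by detector noise
   (`trim_wavelengths()`).
2. **Average replicates**: three spectra per fruit, captured at 120°
   rotations, are averaged channel-wise (`average_replicates()`).
3. **Preprocess**: standard normal variate (SNV), multiplicative scatter
   correction (MSC), Savitzky–Golay smoothing (S-G), and their
   combinations; the candidate that maximises validation-set correlation of
   a PLSR model wins (`compare_preprocessing()`).
4. **Partition** with SPXY (`spxy_split()`), the joint x–y extension of
   Kennard–Stone, at a 3:1 calibration:validation ratio.
5. **Select characteristic wavelengths** with either the successive
   projections algorithm (SPA; `spa_select()`) or Monte-Carlo uninformative
   variable elimination (MCUVE; `mcuve_run()`).
6. **Model** SCC with epsilon-SVR on the selected channels, RBF kernel
   $K(u,v) = \exp(-g\|u-v\|^2)$, with the penalty $C$ and width $g$ tuned
   by particle swarm optimization (`pso_optimize()`, `train_svr()`).
7. **Report** R and RMSE on both sets plus the maximum relative error
   (`evaluate_model()`, `run_pipeline()`, `render_report()`).

## The models and their assumptions

### PLSR core

All intermediate evaluations (preprocessing comparison, SPA phase 2/3,
MCUVE) use PLS1 regression implemented with the SIMPLS algorithm on
mean-centered data (`fit_plsr()`). Variance scaling is deliberately not
applied inside PLSR — scatter conditioning is the preprocessing stage's
job, and double-scaling would mask its effect. With as many factors as the
rank of the centered predictor matrix, SIMPLS reproduces ordinary least
squares; the test-suite pins this identity and cross-checks the
coefficients against an independent NIPALS implementation. The factor cap
defaults to 10; `choose_factors()` picks the count by venetian-blind
(index-stride) 10-fold cross-validation, which is deterministic without a
seed, breaking ties toward fewer factors.

### SPXY

The joint distance is
$d(i,j) = d_x(i,j)/\max d_x + d_y(i,j)/\max d_y$ with Euclidean $d_x$ on
the spectra entering modelling and $|y_i-y_j|$ on SCC. Selection seeds with
the pair at maximal joint distance and grows the calibration set by the
max–min rule. The algorithm is deterministic; ties resolve toward the
lowest position after sorting sample ids, so permuting file rows cannot
change the selected id sets. SPXY pushes response extremes into the
calibration set; with small sample counts a *near-duplicate* of an extreme
can still land in validation, so `validate_split()` reports coverage rather
than asserting it, along with per-set statistics and a two-group ANOVA
(`anova_two_groups()`, reported but never used to gate the pipeline).

### SPA

Phase 1 builds, for every starting channel, a chain of minimally collinear
channels by successive orthogonal projection on the column-centered
calibration matrix (largest residual norm appended next; an exact duplicate
has residual zero and is appended last). Phase 2 scores every chain prefix
of length `n_min`..`n_max` by the validation RMSE (RMSEV) of a PLSR model
and keeps the argmin, preferring shorter prefixes then lower starting
channels on ties. Phase 3 ranks the surviving channels by the relevance
index |regression coefficient × channel SD| and keeps the shortest ranked
prefix whose RMSEV passes an F-criterion at significance 0.25:
$\mathrm{RMSEV}(j) \le \mathrm{RMSEV}_{min}\sqrt{F^{-1}(0.75;\,n_{val},n_{val})}$.
The RMSEV ratio and threshold are kept in the diagnostics. Two choices are
worth flagging. First, the regression inside SPA uses PLSR (capped at
min(10, prefix length)) rather than the MLR of canonical SPA, keeping a
single regression engine across the pipeline. Second, the F-criterion is
formulated on the RMSE ratio against the inverse F distribution — the
standard SPA elimination rule — because a literal "RMSEV below the ratio
threshold" reading is dimensionally inconsistent.

### MCUVE

`n_runs` (default 500) Monte-Carlo draws of 80 % of the calibration
samples each yield a PLSR coefficient vector $\beta$; the stability of
channel $k$ is $C(k) = \mathrm{mean}(\beta_k)/\mathrm{sd}(\beta_k)$.
Channels are ranked by $|C|$ — a stable, strongly negative coefficient is
as informative as a positive one — and the top-$j$ subset minimising RMSEV
is selected. The scan is capped at `max_channels` (default 100) subset
sizes: the point of wavelength selection here is a model with fewer than
100 channels, and the cap also bounds the cost of the trajectory. Channels
whose coefficient SD underflows get $C = 0$ (zero mean) or a capped
magnitude, with a warning.

### PSO-SVR

SVR uses the gamma parameterisation of the RBF kernel, on
column-standardized predictors and standardized response so that a single
$g$ is meaningful across channels. Standardization uses population (1/n)
SDs, which makes training exactly invariant under duplicating the sample
set. The tube width is fixed at 0.01 on the standardized response scale —
about 1 % of the response SD, small enough not to blunt a calibration whose
errors are of that order. If every standardized target fits inside the
tube, the correct solution is the constant mean predictor, and `train_svr()`
returns exactly that instead of an empty machine. The PSO searches
$(\log_{10} C, \log_{10} g)$ in $C \in [0.01, 100]$, $g \in [0.001, 10]$
with 20 particles, 100 iterations, inertia decaying linearly 0.9 → 0.4 and
cognitive = social = 1.7; fitness is 5-fold cross-validated RMSE on the
calibration set (an RMSE-scale quantity in % SCC). Positions are clipped to
the bounds; the global best is non-increasing by construction, and the run
is fully reproducible from its seed.

## The synthetic generator

`simulate_pear_spectra()` emulates what the pipeline needs from pear
spectra, not fruit optics: a flat reflectance envelope (0.60) carrying
Gaussian bands (SD 30 nm) — peaks at 550 and 750 nm, valleys at 680 and
980 nm — on a 498–1020 nm grid at 0.5 nm (1045 channels). The 750 and
980 nm band amplitudes depend linearly on SCC with slope −0.25 per % SCC
(higher SCC, weaker carbohydrate-linked bands); SCC is drawn uniformly on
(0.240, 0.657) %, which matches the reported range of real fragrant-pear
samples and approximates their mean of about 0.49 % (a truncated normal
with mean 0.486 and SD 0.100 is available). Each of the three replicates
per sample is corrupted by a multiplicative gain (SD 0.05), a linear
additive baseline drift (slope SD 1e-4 per nm) and white channel noise
(SD 0.004) — exactly the nuisance family SNV and MSC are designed to
remove, which is what makes the preprocessing comparison meaningful. Band
width, envelope level, amplitudes and the SCC slope are not measured
constants; they were fixed once at values giving band structure and
signal-to-nuisance ratios visually comparable to published pear spectra.

What the generator does *not* emulate: radiative transfer or Kubelka–Munk
behaviour, skin pigment kinetics, instrument-specific stray light, or
nonlinear SCC–spectrum links. Passing tests on this generator therefore
demonstrate that the algorithms recover a known linear band-depth signal
under scatter/drift/noise nuisance — not that any particular accuracy will
be achieved on real fruit.

Registered fixtures: `"paper-like-120"` (study-scale conditions: 120
samples, 3 replicates, full grid), `"tiny-10x8"` (noise-free, RNG-free,
hand-checkable), and `"noise-only"` (no informative bands — a negative
control on which any apparent validation skill is leakage through
selection and tuning).

## Numerical choices and degenerate inputs

* S-G edge handling: the polynomial is refitted on the truncated window so
  output length equals input length; polynomial reproduction up to the
  fitting order is preserved everywhere. Frames are restricted to odd
  {3,5,7,9}, orders 1–7 below the frame.
* Trimming uses a closed interval; "498–1020 nm" retains both endpoints.
* SNV uses the sample (n−1) SD; a constant spectrum is an error naming the
  sample, as is an MSC slope below 1e-12.
* Preprocessing winner rule: highest validation R, then lowest validation
  RMSE, then smallest |R_C − R_V| (robustness), then first listed.
* The full matrix is preprocessed before SPXY splitting; the comparison
  stage builds a provisional split on raw spectra to score candidates,
  then the final split is recomputed on the winner's output.
* All stochastic stages (MCUVE draws, SVR CV folds, PSO) take explicit
  seeds; `run_pipeline()` derives stage seeds from the master seed as
  `master * 1000 + offset` (offset 2 for MCUVE, 3 for PSO), keeping values
  in 32-bit range. The synthetic configuration carries its own seed because
  it defines the dataset's identity.
* Ties: SPA chain growth and MCUVE ranking prefer the lowest channel
  index; trajectory argmins prefer the smallest subset size; CV factor
  choice prefers fewer factors.

## Problem sizes used by the tests

The test-suite verifies oracle equivalences (brute-force SPXY, exhaustive
projection chains, NIPALS-vs-SIMPLS, hand-assembled CV) on instances of
6–50 samples and 3–12 channels, and runs the complete pipeline at the
study scale of 120 samples × 1045 channels with 500 MCUVE draws. PSO
budgets in tests (10–15 iterations, swarms of 6–12) are smaller than the
default 20 × 100 configuration; on this two-dimensional, log-scaled search
space the optimizer reaches grid-search-level fitness well before the
default budget, which the acceptance checks confirm against a 20 × 20 grid
oracle.

## Known limitations

* SCC enters linearly in the generator; the pipeline's nonlinear SVR stage
  is therefore only mildly stressed — its advantage over PLSR on real,
  nonlinear fruit data is not demonstrated here.
* Wavelength selection minimises RMSEV on the validation set, as is usual
  in this workflow; the validation set consequently participates in model
  selection, and reported validation metrics are optimistic relative to a
  held-out test set. The noise-only negative control bounds this leakage.
* MCUVE's subset scan stops at `max_channels` (100) channels; a
  hypothetical optimum above that size would be missed by construction.
* SPXY coverage of the validation response range by the calibration range
  is a strong tendency, not a theorem; audit it with `validate_split()`.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synthetic = "paper-like-120",
  preprocessing = preprocess_spec("snv"),
  selection = "mcuve",
  pso = pso_config(swarm_size = 12, iterations = 30),
  seed = 7)
report <- run_pipeline(cfg)
report
render_report(report, "scc-run", formats = c("json", "csv", "plots"))
```
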