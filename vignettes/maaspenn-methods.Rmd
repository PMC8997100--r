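---
title: "Measuring and predicting the reproducibility of CT radiomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and predicting the reproducibility of CT radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maaspenn)
library(dplyr)
```

## The model

Handcrafted radiomic features (HRFs) are deterministic scalar statistics
of an image region — intensity summaries and texture measures over
gray-level co-occurrence, run-length, size-zone, dependence and
neighbourhood gray-tone difference matrices. Their values depend not only
on the imaged object but on how the scan was acquired and reconstructed.
This package works at the level of *scan pairs*: two scans of the same
phantom acquired under different settings form one scenario, and the
question is how many of the 91 registry features agree across the pair.

Agreement per feature is Lin's concordance correlation coefficient over
the pair's 160 aligned volumes of interest (VOIs),

$$\rho_c = \frac{2\,\mathrm{cov}(x,y)}
  {\mathrm{var}(x)+\mathrm{var}(y)+(\bar x - \bar y)^2},$$

which discounts location and scale shifts in addition to imperfect
correlation, so a feature that is merely offset between two protocols is
*not* concordant. A feature is reproducible in a scenario iff
$\rho_c > 0.9$, strictly: a value of exactly 0.9 does not qualify. We use
population ($1/n$) moments, Lin's original definition; a sample-moment
variant is available via `lin_ccc(..., moments = "sample")` because some
epidemiology implementations use it — at $n = 160$ VOIs the difference is
far below any decision boundary, but the choice should be explicit, not
silent. When both vectors are constant, concordance is undefined; such
features return `NA`, are flagged `degenerate`, and count as
non-reproducible. We compute $\rho_c$ jointly over all 160 VOIs rather
than per layer; the VOI is the unit of pairing and layering adds no
information to a concordance statistic.

## Encoding acquisition differences

Each scenario is summarised by eight agreement values in $[0,1]$, one per
acquisition parameter:

* **vendor, model** — binary, 1 iff identical;
* **tube current, exposure, exposure time, slice thickness, pixel
  spacing** — $\min/\max$ across the pair, so equal settings give 1 and
  a factor-of-two difference gives 0.5. Anisotropic in-plane pixel
  spacing is averaged to a scalar before the ratio;
* **convolution kernel** — kernels are mapped to a numeric *rank*
  ordering them by limiting frequency (sharpness); the agreement value is
  the rank ratio $\min/\max$. The ratio rule matches the one used for
  every other continuous parameter; it makes equally ranked kernels from
  different vendors encode to 1, which is the intended notion of
  "same or similar kernel".

The shipped `default_kernel_schema()` is a stand-in that places common
GE / Siemens / Philips / Canon kernels into five sharpness tiers. It is
deliberately a user-editable table (`read_kernel_schema()`): kernel
naming is vendor-specific and sites should encode their own ranking.
Whether "similar" kernels across vendors should share a rank is a
modelling decision the schema makes explicit rather than hard-coding.

Dose-related header values of 0 are treated as *missing*, never as
legitimate physical values. Missing parameters are a hard error by
default; `encode_pairs(..., on_missing = "drop")` instead excludes the
affected pairs and reports how many were dropped. We never impute.

## The feature pipeline contract

The 91-feature registry (18 first-order, 22 GLCM, 16 GLRLM, 16 GLSZM,
14 GLDM, 5 NGTDM) pins names and family counts and is asserted at load.
The feature mathematics are *delegated*: `extract_features()` is a
contract wrapper around an external extractor function (in practice a
PyRadiomics bridge), owning VOI-box-to-voxel-index mapping (physical mm,
half-open boxes, floor the start and ceil the end), the fixed 25 HU
discretisation bin width, output validation against the registry and
per-VOI error collection. The packaged `demo_extractor()` exists so the
pipeline can be exercised end to end; its values are summary statistics
mapped onto registry names, not radiomics, and are documented as such.

The phantom grid is 10 texture layers × 16 VOIs of 2 × 2 × 2 cm; we fix
the in-plane layout to a centred 4 × 4 arrangement (the exact placement
and margins within each layer are not observable from feature tables and
are configurable). Three processing arms are defined: native grid, and
resampling to 0.68 × 0.68 × 1.5 mm (median voxel) or
0.98 × 0.98 × 3.75 mm (largest voxel). `resample_volume()` implements
separable cosine-windowed-sinc interpolation (window radius 3,
row-normalised weights so constants — and hence HU calibration — are
preserved; the output grid shares the input origin, a convention choice).

## Harmonization

The harmonizability arm applies empirical-Bayes location/scale batch
adjustment (ComBat) with one batch per scan within each pair — the
pairwise reading of the scenario analysis; a global mode (batching across
a whole dataset) is available through `fit_combat()` directly since both
readings are defensible. Phantom data have no biological covariates:
rows with equal VOI index are replicates of the same ground truth, so
only batch indicators enter. The implementation is authored in-package
with an explicit fit/apply split and a serialisable model object
(`write_combat_model()`); the parametric EB iteration stops at relative
change `1e-4` or 100 iterations, zero-variance features pass through
unadjusted, and a non-parametric weighted-posterior mode is available.
The test suite cross-checks the adjusted values against the reference
implementation in the `sva` package to `1e-6`.

## The MaasPenn score

A regression random forest (500 trees, 3 variables per split — the
published configuration) maps the eight encodings to the percent of
reproducible features. We use *percent* rather than count as the outcome
so the model is registry-size invariant. Importance is permutation
importance (unscaled mean decrease in MSE) by default; the originating
analysis used an R random-forest default without naming the measure, and
permutation importance is the better-behaved choice for correlated
predictors (impurity importance is available behind a flag). The top
three parameters are retained and their importances normalised to
weights summing to 1 (`derive_weights()`); small negative permutation
importances are clamped to zero first.

`published_weights()` — kernel 0.48, slice thickness 0.33, pixel spacing
0.19 — is the default scoring mode and the basis of the packaged cut-off
table `published_cutoffs()`; refitted weights are labelled
`provenance = "fitted"` so the two modes cannot be confused. The score is
the weighted sum of the retained encodings: in $[0,1]$, equal to 1 iff
kernel rank, slice thickness and pixel spacing all agree, and monotone in
each component. Its practical lower bound (~0.3) is set by the smallest
kernel-rank ratio in the schema.

ROC analysis labels a pair 1 iff its percent reproducible strictly
exceeds a threshold (10–90%), computes AUC by the rank (Mann–Whitney)
statistic with midrank ties — the suite proves it equal to the exhaustive
pairwise-concordance count — and selects the cut-off maximising Youden's
$J$, breaking ties toward the smaller cut-off. "Best threshold" was
underdetermined in the source analysis; Youden's $J$ is the standard
choice. Decisions at a cut-off are strict (`score > cutoff`), matching
the strict CCC rule. Robustness is assessed over 100 random 80/20
train/validation splits with per-run seeds fanned out from a master seed
by a counter; cut-offs are re-selected on each training split and
evaluated on both splits.

Screening (`screen_scans()`, default cut-off 0.94, the 70% row of the
packaged table) and dataset audits (`audit_signature_dataset()`, verdict
positive iff a *strict* majority of pairs exceeds the cut-off) are pure
functions of metadata, schema and cut-off.

## What the synthetic generator emulates — and what it does not

`generator_config()` encodes the study conditions: 40 scans by default
(780 pairs; 251 scans is the full-scale profile), four vendors with
vendor-specific models and kernels, log-spaced numeric parameter grids
spanning typical CT protocols, and a 160 × 91 feature table per scan.
Every scan shares a fixed per-VOI texture signature $b_{vf}$ (mean per
feature drawn from $U(50,150)$, VOI spread sd 20); a scan's settings
distort it multiplicatively,

$$y_{vf} = b_{vf}\bigl(1 + \textstyle\sum_p \beta_{fp} d_p\bigr) +
\varepsilon,\qquad \varepsilon \sim N(0, 1),$$

with $d_p$ the scan's standardised (log-scale) parameter value and
$\beta_{fp}$ the feature's effect size. Effect sizes embody the known
ordering: kernel 0.20 > slice thickness 0.12 > pixel spacing 0.06, dose
parameters 0.005, vendor/model 0. Each sensitive feature has one
*dominant* resolution parameter (drawn with probability proportional to
the effect sizes) plus the weak shared dose response — real features
specialise, texture measures tracking kernel sharpness and
volume-averaging statistics the slice thickness — and a heavy-tailed
overall sensitivity (log-normal, sd(log) 1, floored at 0.4), because
real feature sensitivities span orders of magnitude; this is what makes
the percent-reproducible outcome graded rather than all-or-nothing. Four
designed-insensitive first-order features (mean, median, root mean
squared, total energy) have all effects zero, mirroring the HU-anchored
statistics that survive every protocol change.

Because distortions are location/scale per feature, the default regime is
ComBat-favourable: harmonization recovers almost everything, and the
suite asserts harmonized counts never fall below raw counts. Setting
`voi_dependent = TRUE` makes distortions interact with the VOI signature,
which a location/scale adjustment cannot remove — the regime where
harmonizability genuinely depends on the parameter variation. At default
effect sizes a few weakly sensitive features survive *all* pairs of a
small dataset alongside the designed four; the exact-recovery property
(intersection = exactly the designed set) is asserted in a strong-effect
regime (resolution effects × 3) where every sensitive feature provably
fails somewhere.

What passing tests on this generator do **not** show: real HRFs respond
to reconstruction through non-linear, feature-specific physics (noise
texture, partial volume), not a clean multiplicative model; real kernels
are not totally ordered by a scalar rank; phantom texture is not patient
anatomy; and contrast-enhanced acquisitions are outside the model
entirely. The generator validates the *machinery* — encodings, CCC,
harmonization, importance recovery, cut-off selection — under a ground
truth where the right answer is known, not the published coefficients
themselves.

## Numerical choices and problem sizes

* CCC: population moments; both-constant features → flagged `NA`,
  non-reproducible; strict `>` at every decision boundary.
* ComBat: parametric EB, convergence `1e-4` / 100 iterations;
  zero-variance features passed through; per-pair batching in the
  scenario pipeline.
* ROC: midrank AUC; Youden cut-off with ties to the smaller value;
  candidate cut-offs at midpoints of consecutive distinct scores.
* Random forest: seeded via `set.seed(seed)` immediately before the fit;
  identical seeds give identical importances.
* Suite problem sizes: 40-scan (780-pair) studies for end-to-end checks,
  100 seeded repetitions for the ordering-recovery and robustness
  properties, 160-sample two-batch designs for harmonization recovery —
  sizes at which the estimators' sampling error is comfortably inside
  the asserted tolerances.

## Known limitations

The kernel schema ships as a stand-in and should be replaced with a
site-specific ranking; metadata ingestion reads delimited tables with
DICOM-style column names (a DICOM-file reader is deliberately out of
scope — export headers to CSV first); the published weights and cut-off
table are taken as given for screening, and refitting on a new dataset
produces weights that are *not* the published score. Feature-level
reproducibility prediction (which individual feature survives) is out of
scope: the unit of analysis is the scan pair.
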