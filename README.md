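# maaspenn

Quantifying the reproducibility of CT-based handcrafted radiomic features
(HRFs) across scans acquired with different settings — and predicting it
from acquisition metadata alone.

## The problem

HRF values shift with CT acquisition and reconstruction settings, so a
radiomic signature developed on one protocol may not transfer to another.
Reproducibility is normally established with dedicated phantom or
test–retest studies, which most retrospective datasets do not have. This
package implements a metadata-only alternative built around phantom
scan-pair analysis:

1. **Pair encoding.** For every unordered pair of scans, eight
   acquisition parameters (vendor, model, tube current, exposure, exposure
   time, slice thickness, pixel spacing, convolution kernel) are encoded
   into agreement values in [0, 1]: vendor/model binary (1 iff equal),
   numeric parameters `min/max`, and kernels the ratio of their
   limiting-frequency ranks from a configurable schema.
2. **Reproducibility measurement.** Per feature, agreement across the two
   scans' 160 phantom VOIs (10 layers × 16 cubes of 2 × 2 × 2 cm) is
   measured with Lin's concordance correlation coefficient

   ρ_c = 2·cov(x, y) / (var(x) + var(y) + (x̄ − ȳ)²),

   and a feature counts as reproducible when ρ_c > 0.9 (strict). The
   outcome per pair is the percent of the 91-feature registry (18 first
   order, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) that is
   reproducible.
3. **Harmonizability.** Empirical-Bayes location/scale (ComBat)
   harmonization and voxel-size resampling arms quantify how much of the
   loss is removable.
4. **The MaasPenn score.** A regression random forest (500 trees, mtry 3)
   of percent-reproducible on the eight encodings yields parameter
   importances; the top three (kernel, slice thickness, pixel spacing)
   are normalized into weights and the score of a pair is

   score = 0.48·e_kernel + 0.33·e_slice + 0.19·e_pixel ∈ [~0.3, 1],

   with ROC/Youden cut-offs per reproducibility threshold (e.g. score
   > 0.94 ⇒ ≥70% of HRFs expected reproducible). Screening and audit
   workflows apply these cut-offs to prospective scan inclusion and
   retrospective signature checks.

A synthetic phantom-study generator with known ground truth (which
parameters distort which features, and how strongly) makes the whole
pipeline testable without image data.

## Worked example

```r
library(maaspenn)
library(dplyr)

study <- simulate_study(generator_config(n_scans = 40, seed = 2026))
scen  <- compute_scenarios(study$features)   # Lin CCC over all 780 pairs
enc   <- encode_pairs(study$metadata)

summarize_scenarios(scen)
#>   arm      harmonized n_pairs mean_n  sd_n mean_pct sd_pct
#> 1 original FALSE          780   43.8  19.3     48.1   21.3

rf <- fit_reproducibility_rf(
  bind_cols(enc, pct_reproducible = scen$pct_reproducible), seed = 2026)
rf
#> Reproducibility random forest (500 trees, mtry 3)
#>   pairs: 780; variance explained: 96.4%
#>   importance (permutation):
#>     kernel            665.211
#>     slice_thickness   131.331
#>     pixel_spacing      10.570
#>     tube_current        2.790
#>     ...

derive_weights(rf)
#> MaasPenn score weights (fitted)
#>   kernel           0.824
#>   slice_thickness  0.163
#>   pixel_spacing    0.013

scored <- maaspenn_score(enc)   # published weights 0.48/0.33/0.19
score_outcome_correlation(scored$score, scen$pct_reproducible)
#> [1] 0.9606161
```

On average 48% of features are reproducible per pair here, with a wide
spread across pairs (sd 21) — the generator's kernel-dominated distortions
at work. The forest explains 96% of that variance from the encodings and
recovers the designed importance ordering (kernel ≫ slice thickness >
pixel spacing); the published-weight score tracks the measured outcome at
rho = 0.96. `threshold_analysis()`, `robustness_runs()`, `screen_scans()`
and `audit_signature_dataset()` continue from there; `plot_*()` and
`autoplot()` functions draw the standard figures, and `tidy()` / `glance()`
give broom-style views of fitted objects.

A thin command-line front end over the same functions lives at
`inst/cli/maaspenn.R` (subcommands `simulate`, `encode`, `ccc`, `combat`,
`fit`, `score`, `roc`, `robustness`, `screen`, `audit`).

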