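---
title: "Locating alpha-BOLD coupling across cortical depths: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating alpha-BOLD coupling across cortical depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layeralpha)
```

# The scientific problem

Posterior EEG alpha power (8–13 Hz) rises when the eyes close, and the
BOLD signal in visual cortex falls with it. At 7T, submillimetre fMRI can
resolve where across the cortical depth this negative alpha–BOLD coupling
lives — deep and superficial laminae would point to top-down generators,
middle depths (layer 4) to thalamocortical input. Gradient-echo BOLD,
however, is biased by ascending venous drainage: each depth's signal mixes
in signal from all deeper laminae, pushing apparent effects toward the
pial surface. `layeralpha` implements the full analysis chain needed to
make laminar statements from such data, and a seeded synthetic-subject
generator that provides ground truth for every stage.

The pipeline stages are:

1. **Regressors** (`make_regressor`, `make_boxcar`, `orthogonalize`): the
   alpha power series is demeaned over the run, convolved with a causal
   double-gamma HRF sampled at the EEG rate, and sampled at volume temporal
   midpoints. Three regressors are carried: the alpha regressor, the task
   boxcar (1 = eyes closed at the volume midpoint), and the alpha regressor
   orthogonalized against the boxcar (spontaneous alpha variance only).
2. **Voxelwise GLM** (`fit_glm`): ordinary least squares with six motion
   nuisance regressors and an intercept; t statistics are converted to z by
   CDF quantile matching (exact at low df). The negative contrast is
   cluster-corrected (`cluster_threshold`) at z < −2.3 with a sign-flipping
   permutation null on the model residuals — assumption-light and exactly
   testable, replacing the Gaussian-random-field correction used by
   standard tools.
3. **Laminar coordinates** (`compute_depths`, `make_columns`): six
   equivolume depths per GM voxel (depth 1 = WM-adjacent, 6 =
   CSF-adjacent) and cortical columns grown from the mid-depth surface by
   farthest-point seeding and geodesic (within-GM, 26-connected) nearest
   seed assignment.
4. **Column selection** (`select_columns`, `threshold_betas`): a column is
   included if *any* of its voxels is significant (drainage couples all its
   depths); retained voxels must exceed 5% of the maximum |β| across the
   included columns.
5. **Deveining** (`compute_alff`, `drainage_weights`, `forward_drain`,
   `spatial_deconvolve`, `devein_volume`): see below.
6. **Vein proximity** (`make_vein_mask`, `make_ring_mask`,
   `classify_gradient_change`, `class_ring_overlap`,
   `exclude_top_columns`): columns whose depth-profile gradient changes
   most under deveining are located, tested for enrichment in the
   surrounding-vein ring, and the top 25% excluded.
7. **Profiles and statistics** (`global_mean_profile`,
   `column_profile_mean`, `range_normalize`, `roi_weighted_average`,
   `rm_anova_1way`, `rm_anova_2way`, `posthoc_paired_t`).

# The drainage model and its inverse

The deveining contract is the triangular accumulation

$$m_1 = b_1, \qquad m_i = b_i + v_i \sum_{j<i} b_j \;(i = 2..6),$$

where $b_i$ is the depth-local signal, $m_i$ the measured one and $v_i$ a
nonnegative leakage weight: each depth's measurement contains a weighted
sum of all deeper local signals. Its exact inverse
($\hat b_i = m_i - v_i \sum_{j<i} \hat b_j$) is the spatial deconvolution.
The weights come from the amplitude of low-frequency fluctuations (ALFF),
a venous-blood-volume surrogate: per column and depth,
$v_i = \lambda\, \bar a_i / \overline{\bar a}$ with $\lambda = 0.25$ by
default (physiological range 0.2–0.3). The deconvolution is computed on
each column's depth-mean β vector and applied as an additive per-depth
correction to its voxels, preserving within-depth spatial variance —
voxel-level peeling would be ill-posed where depth occupancy is uneven.
Columns with no voxels at depth 1 are anchored at their deepest populated
depth and flagged.

Two operational choices matter here:

* **ALFF windows are delayed by the haemodynamic lag** (6 s, the HRF peak
  delay; `shift_s` in `compute_alff`). Without the shift, each 30 s
  eyes-closed window contains the onset transient of the evoked response,
  whose variance then masquerades as a venous fluctuation: measured on the
  synthetic subjects, the within-window SD of the (unit-SD) task drive
  falls from 0.70 to 0.28 when the windows are shifted. The shifted window
  is what "fluctuation amplitude during eyes-closed" is meant to capture.
* **Detected vein voxels are removed from the analysis mask** before
  fitting (the GM mask of a laminar study is corrected for intracortical
  veins); perivascular tissue stays in, which is exactly what the
  vein-proximity diagnostics then quantify.

# What the generator simulates

`make_ribbon` builds a quarter-annulus GM ribbon (inner radius 10 voxels,
outer 16, six slices, 0.8 mm voxels, ~780 GM voxels) between WM and a CSF
rim. The constant curvature makes equivolume ≠ equidistant while keeping
the equal-volume shell boundaries,
$\sqrt{r_1^2 + \tfrac{k}{6}(r_2^2 - r_1^2)}$, available in closed form as
an oracle. Depth bins are formed by volume-rank quantization of the local
curvature-reweighted depth metric, so each bin holds an equal share of
tissue volume on the discrete grid; this is exact for constant-curvature
ribbons, and would need a locally windowed normalization for strongly
varying curvature (a documented limitation, irrelevant to this geometry).
Near the angular cut of the sector the boundary-distance field is mildly
distorted — an artifact of truncating the ribbon that real cortex does not
have — so radial monotonicity of the bins is guaranteed only in the
sector interior.

Each synthetic subject adds, per GM voxel:

* a **neural drive**: −amplitude × depth-weight × the HRF-convolved,
  demeaned, unit-SD alpha power series (negative alpha–BOLD coupling).
  The default amplitude is 3 signal units on a baseline of 100 (a 3% peak
  response). Ground-truth laminar shapes: `"n"` (middle depths at 50%),
  `"flat"`, `"superficial"`;
* **draining-vein accumulation** of the six depth-local drives through
  `forward_drain`, with true weights
  $v = \lambda_{sim}\,s/\bar s$, $\lambda_{sim} = 0.25$;
* **low-frequency fluctuations**: eight seeded sinusoids per voxel in
  0.02–0.08 Hz with per-depth SD (0.5, 1.35, 7.0, 5.9, 5.9, 6.0) signal
  units — a venous-CBV proxy, small in the deep laminae and peaking at the
  middle depths, where cortical vascular density is densest;
* **vascular artifacts**: one radial vein (dark on the mean EPI by a 40%
  baseline drop) whose perivascular shell (Chebyshev radius 1) receives an
  added copy of the column's superficial measured signal at gain 0.6;
* **white noise** (SD 1) and six motion nuisance timecourses (pure
  nuisance; no motion artifact is injected);
* **between-subject variability**: ±30% uniform amplitude jitter, ±15%
  uniform jitter on $\lambda_{sim}$, 5% Gaussian jitter per depth on the
  laminar weights, and 25% Gaussian jitter per depth on the
  low-frequency amplitude profile. The last one deliberately decouples
  each subject's fluctuation profile from the drainage truth: ALFF is an
  imperfect surrogate at the single-subject level, as it is in vivo.

The drainage-shape default, `drain_shape = (0.306, 0.410, 1.462, 1.252,
1.270, 1.300)`, is the fixed point of a self-consistency calibration: it
equals (to measurement precision, over 80-subject calibration runs) the
expected λ-scaled ALFF profile that the pipeline itself estimates on these
subjects, so the deconvolution weights are unbiased for the simulated
drainage *on average*, with honest subject-level scatter. The steep step
between depths 2 and 3 encodes a venous compartment concentrated from the
middle depths up; it is also what makes the uncorrected profiles of an
"n"-shaped truth monotone toward the pial surface, the hallmark the
generator is required to reproduce. The dissociation study
(`study_glm_dissociation`) carries richer spontaneous fluctuations, whose
neural imprint on ALFF differs, so its drainage shape is calibrated by the
same fixed-point procedure under its own conditions.

What the generator does **not** emulate: EEG channel-level physics and
artifacts (the alpha series enters already source-localized), partial
volume effects, spatially coherent physiological noise, motion-coupled
signal changes, between-region ROI structure (the ribbon is one
V1-like ROI; `roi_weighted_average` is exercised on constructed inputs),
or multi-run sessions (`fixed_effects` is validated on constructed
multi-run data; the pipeline simulates one run per subject). Passing
tests therefore demonstrate correctness of the analysis chain and
recoverability under a faithful but idealized forward model, not
performance on real 7T data.

# Numerical and statistical choices

* Band-pass: 4th-order Butterworth, forward-backward, 8–13 Hz. Envelope:
  FFT analytic signal magnitude.
* Double-gamma HRF: response delay 6 s, undershoot delay 16 s, both
  dispersions 3 s, undershoot ratio 1/6, unit peak; parameters exposed.
* Whole-run demeaning before convolution; sampling at volume midpoints
  (onset sampling available).
* Segment length for repair is TR/4 rounded to samples; a trailing partial
  segment inherits the last full segment's flag. Repair uses the mean over
  clean segments among the four nearest neighbours when at least two are
  clean, else the run-level clean mean of the same condition.
* No prewhitening (68-volume runs) and no temporal filtering beyond
  demeaning; documented limitations.
* Cluster inference: 26-connectivity, 200 sign-flip permutations by
  default; the retained-size threshold is the 95th percentile of the null
  maximum cluster size.
* Group statistics: each subject's profile is range-normalised (divide by
  max − min without shifting; shift-and-scale available), averaged with
  equal subject weights; SEM is across subjects. rm-ANOVA uses
  `stats::aov()` error strata, each within-subject effect tested against
  its own subject-interaction term; no sphericity correction is applied.
  Subjects with depths emptied by the negative-voxel selection are
  excluded listwise and reported.
* Ties in nearest-seed distance go to the lowest seed index; gradient-change
  class boundaries sit at ranks n/4 and 3n/4 with ties resolved by rank.
* The vein-detection percentile default follows the simulated vein density
  (2% of the ROI ≈ one vein plus margin); the op-level default of the 5th
  percentile suits denser vasculature. Direction is "locally dark".

# Study sizes

The replicated studies (`study_laminar_recovery`,
`study_glm_dissociation`, `study_vein_proximity`,
`study_null_calibration`) use 8 subjects per group and 20 replicates, with
each subject's columns and veins independently seeded on the shared ribbon
lattice. These sizes mirror the source study's group size while keeping a
full acceptance run to roughly ten minutes of CPU; the analysis scripts
under `analysis/` run reduced replications of the same studies as quick
demonstrations.

# Known limitations

* The λ·ALFF deconvolution anchors at the deepest bin, so the deveined
  superficial depths scale with λ: range-normalised profiles for
  λ ∈ {0.2, 0.25, 0.3} differ substantially on the synthetic fixture
  (`study_lambda_sensitivity` reports the deviation) even though the
  recovered *shape ordering* is stable. In vivo reports of λ-insensitivity
  therefore do not transfer to this forward model at desk scale.
* The flat-truth type-I rate of the depth rm-ANOVA sits near, not
  comfortably under, the nominal level: percent-level systematic biases of
  the pipeline (negative-voxel selection under depth-dependent noise,
  finite-precision weight calibration) remain detectable when subject
  scatter is small.
* Range-normalising a genuinely flat profile divides by a noise-driven
  range; the group statistics remain valid but normalised values are then
  large and unstable.
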