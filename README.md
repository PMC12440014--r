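# layeralpha

Laminar analysis of EEG alpha–BOLD coupling with draining-vein
deconvolution, plus a seeded synthetic 7T-like data generator that makes
every stage testable against ground truth.

## The problem

Eyes-closed rest raises posterior EEG alpha power (8–13 Hz) and lowers the
BOLD signal in visual cortex. High-resolution gradient-echo fMRI can ask
*at which cortical depth* this negative alpha–BOLD coupling is generated —
but GE-BOLD accumulates signal from deep laminae into superficial ones via
ascending veins, biasing every depth profile toward the pial surface.
`layeralpha` implements the analysis chain for this question:

- alpha-power GLM regressors (Hilbert envelope, noisy-segment repair,
  double-gamma convolution, boxcar and orthogonalized variants);
- voxelwise OLS with motion nuisance, exact t→z conversion, and
  permutation-based cluster correction of the negative contrast
  (z < −2.3, cluster p < 0.05);
- six equivolume cortical depths (depth 1 = WM-adjacent) and cortical
  columns grown geodesically from the mid-depth surface;
- deveining by spatial deconvolution: each depth's measurement is modelled
  as `m_i = b_i + v_i * sum_{j<i} b_j`, with weights
  `v_i = lambda * ALFF_i / mean(ALFF)` (λ = 0.25), inverted exactly by
  `bhat_i = m_i − v_i * sum_{j<i} bhat_j`;
- vein-proximity diagnostics: unsharp-mask vein detection on the mean EPI,
  a 4-fold-dilated surrounding-vein ring, a 25/50/25 classification of
  columns by deveining-induced gradient change, and exclusion of the most
  affected quarter;
- depth profiles (global-mean and column-profile-mean, negative voxels,
  range-normalised) with one- and two-way repeated-measures ANOVA and
  Bonferroni post-hocs.

A synthetic-subject generator (`make_ribbon`, `make_veins`,
`make_alpha_timecourse`, `make_bold`) produces a curved GM ribbon,
penetrating veins with perivascular contamination, draining-vein signal
accumulation, low-frequency venous fluctuations and white noise — all
seeded, with the ground truth recorded for recovery tests.

## Worked example

```r
library(layeralpha)

p     <- paradigm()                       # 30 s blocks x 4, TR 3.8 s, 68 vols
alpha <- make_alpha_timecourse(p, seed = 3)
cmp   <- compare_conditions(alpha, p)
#> Alpha power eyes-closed 1.494 vs eyes-open 1.003
#> (paired t = 32.68, p = 0.0001)

chk <- study_equivolume_accuracy(10, 16, thickness = 4)
#> bin boundaries within 0.115 voxels of sqrt(r1^2 + k/6 (r2^2 - r1^2));
#> per-bin voxel counts 84/92/84/88/87/85 (max spread 6.2%)

cfg <- default_config()                   # the synthetic study conditions
res <- run_pipeline(cfg, seed = 1)        # 8 subjects, full chain
g   <- group_stats(res$subjects, "alpha", variant = "dev_excl")
round(g$mean, 2)                          # group deveined depth profile
g$anova$p                                 # rm-ANOVA across depths
```

On an "n"-shaped ground truth (middle depths at half amplitude) the
uncorrected group profile grows monotonically in |β| toward depth 6 —
the draining-vein hallmark — while the deveined profile is least negative
at depths 3–4 and the depth effect is significant; see
`analysis/07_group_profiles.R` for the replicated version and the numbers
it prints.

The numbered scripts under `analysis/` walk the pipeline end to end
(simulation, regressors, GLM maps, depth validation, deveining,
vein-proximity diagnostics, group statistics) and write their tables under
`results/`.

## Documentation

The methods vignette (`vignettes/laminar-alpha-pipeline.Rmd`) describes
the drainage model, the ALFF windowing, the equivolume construction, the
generator's noise model and calibration, and the known limitations.
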