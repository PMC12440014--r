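#!/usr/bin/env Rscript
## Simulate one synthetic laminar EEG-fMRI subject and write its volumes:
## labelled ribbon, equivolume depths, columns, vein truth, 4-D BOLD,
## alpha power series and motion nuisance.
library(layeralpha)

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config()
sub <- prepare_geometry(cfg, seed = 1)
sim <- simulate_subject(cfg, sub, seed = 2)

vx <- cfg$geometry$voxel_mm
write_volume(sub$geom$vol, file.path(out, "labels.nii.gz"), vx)
write_volume(ifelse(is.na(sub$depths$bin), 0L, sub$depths$bin),
             file.path(out, "depth_bin.nii.gz"), vx)
write_volume(ifelse(is.na(sub$columns$id), 0L, sub$columns$id),
             file.path(out, "column_id.nii.gz"), vx)
write_volume(sim$veins$vein, file.path(out, "vein_truth.nii.gz"), vx)
write_volume(sim$bold, file.path(out, "bold.nii.gz"), vx)
n <- length(sim$alpha$values)
write_table_tsv(data.frame(time_s = (seq_len(n) - 0.5) / sim$alpha$fs_hz,
                           alpha_power = sim$alpha$values),
                file.path(out, "alpha_power.tsv"))
write_table_tsv(as.data.frame(sim$motion), file.path(out, "motion.tsv"))
yaml::write_yaml(list(seed = 2, truth = sim$truth$shape_name,
                      gm_voxels = sum(sub$gm_mask),
                      true_drainage_weights = round(sim$drain_v, 4)),
                 file.path(out, "ground_truth.yaml"))
cat("Simulated one subject:", sum(sub$gm_mask), "GM voxels,",
    cfg$paradigm$n_vols, "volumes; ground-truth laminar shape:",
    sim$truth$shape_name, "\n")
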