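## End-to-end pipeline over synthetic subjects: simulate -> regressors ->
## GLM (+cluster correction) -> depths/columns -> ALFF/devein ->
## vein-proximity exclusion -> depth profiles -> group statistics.

#' Default pipeline configuration
#'
#' Every tunable defaults to the study value where one exists: 30 s blocks
#' x 4 cycles, TR 3.8 s, 68 volumes, 6 depths, lambda 0.25, 5% beta
#' threshold, z < -2.3 with cluster p < 0.05, 4 ring dilations, 5th
#' percentile vein cutoff. Geometry and noise defaults define the
#' synthetic study conditions (see the methods vignette).
#'
#' @param ... Named overrides of any top-level entry.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    paradigm = paradigm(),
    geometry = list(inner = 10, outer = 16, arc = pi / 2, thickness = 6,
                    voxel_mm = 0.8),
    alpha = list(modulation_depth = 0.5, ar1_coeff = 0.996, noise_sd = 0.1,
                 baseline = 1),
    noise = noise_config(),
    veins = list(n_veins = 1, ring_width_vox = 1),
    truth_shape = "n",
    task_weights = NULL,
    n_columns = 8,
    lambda = 0.25,
    beta_pct = 5,
    z_crit = -2.3,
    cluster_alpha = 0.05,
    n_perm = 200,
    n_dilations = 4,
    cutoff_pct = 2,
    n_subjects = 8,
    glm_kinds = "alpha")
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Build a subject's geometric substrate
#'
#' The ribbon lattice and its equivolume depths are deterministic for a
#' given configuration and may be shared (pass `base`); columns and vein
#' placement are seeded per subject, so each synthetic subject carries its
#' own column parcellation and vasculature.
#'
#' @param cfg A [default_config()].
#' @param seed Integer seed (vein placement, column seeding).
#' @param base Optional list with precomputed `geom` and `depths` for this
#'   configuration (avoids recomputing the shared lattice).
#' @return List: `geom`, `depths`, `columns`, `veins`, `gm_mask`.
#' @export
prepare_geometry <- function(cfg, seed = 1, base = NULL) {
  if (is.null(base)) {
    g <- cfg$geometry
    geom <- make_ribbon(g$inner, g$outer, g$arc, g$thickness, g$voxel_mm)
    depths <- compute_depths(geom)
  } else {
    geom <- base$geom
    depths <- base$depths
  }
  set.seed(seed)
  s2 <- sample.int(2^31 - 2, 2)
  columns <- make_columns(geom, depths, cfg$n_columns, seed = s2[1])
  veins <- make_veins(geom, cfg$veins$n_veins, cfg$veins$ring_width_vox,
                      seed = s2[2])
  list(geom = geom, depths = depths, columns = columns, veins = veins,
       gm_mask = geom$vol == 3L)
}

#' Simulate one subject on a prepared substrate
#'
#' @param cfg A [default_config()].
#' @param sub A [prepare_geometry()] result.
#' @param seed Integer subject seed.
#' @return A `subject_sim`.
#' @export
simulate_subject <- function(cfg, sub, seed = 1) {
  set.seed(seed)
  s2 <- sample.int(2^31 - 2, 2)
  a <- cfg$alpha
  alpha <- make_alpha_timecourse(cfg$paradigm, a$modulation_depth,
                                 a$ar1_coeff, a$noise_sd, a$baseline,
                                 seed = s2[1])
  truth <- if (inherits(cfg$truth_shape, "ground_truth")) cfg$truth_shape
           else ground_truth(cfg$truth_shape)
  make_bold(sub$geom, sub$depths, sub$columns, sub$veins, truth, alpha,
            cfg$paradigm, cfg$noise, seed = s2[2],
            task_weights = cfg$task_weights)
}

#' Analyse one simulated subject
#'
#' Runs the subject-level pipeline for each requested GLM kind: regressor
#' construction, voxelwise GLM with motion nuisance, cluster-corrected
#' negative contrast, column inclusion, 5% beta thresholding, ALFF-scaled
#' deveining, per-column gradient-change classification with ring-overlap
#' quantification, top-25% column exclusion, and global-mean depth
#' profiles (uncorrected and deveined, all and vein-filtered).
#'
#' @param sim A [simulate_subject()] result.
#' @param cfg A [default_config()].
#' @param sub The [prepare_geometry()] substrate.
#' @param seed Integer seed (cluster permutations).
#' @return A list with shared maps (`alff`, `vein_masks`) and one entry
#'   per GLM kind under `kinds`.
#' @export
run_subject <- function(sim, cfg, sub, seed = 1) {
  p <- cfg$paradigm
  gm <- sub$gm_mask
  regs <- build_regressors(sim$alpha, p, cfg$glm_kinds)
  mean_epi <- apply(sim$bold, 1:3, mean)
  vein_det <- make_vein_mask(mean_epi, gm, fwhm_mm = 2,
                             cutoff_pct = cfg$cutoff_pct,
                             voxdim_mm = cfg$geometry$voxel_mm)
  vmasks <- make_ring_mask(vein_det, cfg$n_dilations)
  ## detected veins are cut from the analysis mask (the GM mask is
  ## corrected for intracortical veins); perivascular tissue remains
  gm <- gm & !vein_det
  alff <- compute_alff(sim$bold, p, gm)
  set.seed(seed)
  perm_seeds <- sample.int(2^31 - 2, length(regs))
  kinds <- vector("list", length(regs))
  names(kinds) <- names(regs)
  for (k in seq_along(regs)) {
    kinds[[k]] <- analyse_kind(sim, cfg, sub, regs[[k]], alff, vmasks,
                               mask = gm, perm_seed = perm_seeds[k])
  }
  list(alff = alff, vein_masks = vmasks, regressors = regs, kinds = kinds)
}

#' Build the three GLM regressors from an alpha power series
#'
#' @param alpha An [alpha_series()].
#' @param p A [paradigm()].
#' @param kinds Subset of c("alpha", "boxcar", "alpha_orth").
#' @return Named list of `regressor`s.
#' @export
build_regressors <- function(alpha, p,
                             kinds = c("alpha", "boxcar", "alpha_orth")) {
  kinds <- match.arg(kinds, c("alpha", "boxcar", "alpha_orth"),
                     several.ok = TRUE)
  box <- make_boxcar(p)
  ra <- make_regressor(alpha, p)
  out <- list()
  for (k in kinds) {
    r <- switch(k, alpha = ra, boxcar = box,
                alpha_orth = orthogonalize(ra, box))
    r$values <- r$values / stats::sd(r$values)   # unit-SD interest column
    out[[k]] <- r
  }
  out
}

## subject-level analysis for one regressor kind
analyse_kind <- function(sim, cfg, sub, reg, alff, vmasks, mask,
                         perm_seed) {
  design <- glm_design(reg, sim$motion)
  fit <- fit_glm(sim$bold, design, mask)
  cl <- cluster_threshold(fit, cfg$z_crit, cfg$cluster_alpha, cfg$n_perm,
                          seed = perm_seed)
  included <- select_columns(sub$columns, cl$mask)
  out <- list(fit = fit, cluster = cl, included = included,
              detected = length(included) > 0)
  if (!out$detected) return(out)
  retained <- threshold_betas(fit$beta, sub$columns, included, cfg$beta_pct)
  beta_dev <- devein_volume(fit$beta, sub$columns, sub$depths, alff,
                            cfg$lambda, include = included)
  ## deveining can flip signs; redo the retention on the deveined map
  retained_dev <- threshold_betas(beta_dev, sub$columns, included,
                                  cfg$beta_pct)
  grad <- gradient_table(fit$beta, beta_dev, sub, retained, retained_dev,
                         included)
  classes <- if (nrow(grad) >= 4) classify_gradient_change(grad) else NULL
  overlap <- if (!is.null(classes))
    class_ring_overlap(classes, sub$columns, vmasks$ring, retained)
  else c(lower25 = NA_real_, middle50 = NA_real_, upper25 = NA_real_)
  kept <- exclude_top_columns(included, classes)
  prof <- function(map, ret, incl)
    global_mean_profile(map, sub$columns, sub$depths, ret, incl)
  out <- c(out, list(
    retained = retained, retained_dev = retained_dev,
    beta_dev = beta_dev, gradients = grad, classes = classes,
    ring_overlap = overlap, included_filtered = kept,
    profiles = list(
      unc_all = prof(fit$beta, retained, included),
      dev_all = prof(beta_dev, retained_dev, included),
      unc_excl = prof(fit$beta, retained, kept),
      dev_excl = prof(beta_dev, retained_dev, kept))))
  out
}

## per-column uncorrected/deveined slopes (negative retained voxels)
gradient_table <- function(beta_unc, beta_dev, sub, retained, retained_dev,
                           included) {
  rows <- lapply(included, function(id) {
    pu <- column_depth_means(beta_unc, sub, retained, id)
    pd <- column_depth_means(beta_dev, sub, retained_dev, id)
    data.frame(column = id, slope_unc = profile_gradient(pu),
               slope_dev = profile_gradient(pd))
  })
  tab <- do.call(rbind, rows)
  tab[!is.na(tab$slope_unc) & !is.na(tab$slope_dev), , drop = FALSE]
}

column_depth_means <- function(betamap, sub, retained, id) {
  sel <- retained & !is.na(sub$columns$id) & sub$columns$id == id &
    !is.na(betamap) & betamap < 0
  nd <- sub$depths$n_depths
  out <- rep(NA_real_, nd)
  db <- sub$depths$bin[sel]
  bv <- betamap[sel]
  for (i in seq_len(nd)) if (any(db == i)) out[i] <- mean(bv[db == i])
  out
}

#' Run the full pipeline on a group of synthetic subjects
#'
#' @param cfg A [default_config()].
#' @param seed Master seed; expands deterministically into substrate and
#'   per-subject streams.
#' @param out_dir Optional directory; when given, volumes, tables and a
#'   manifest are written there.
#' @return A `pipeline_result` list: `substrate`, `subjects` (per-subject
#'   analysis), `group` (per GLM kind: normalized profile matrices, group
#'   mean/SEM, rm-ANOVA and post-hocs, ring-overlap table).
#' @export
run_pipeline <- function(cfg = default_config(), seed = 1, out_dir = NULL) {
  set.seed(seed)
  seeds <- matrix(sample.int(2^31 - 2, 3 * cfg$n_subjects), ncol = 3)
  base <- NULL
  subjects <- vector("list", cfg$n_subjects)
  substrates <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    sub <- prepare_geometry(cfg, seed = seeds[i, 1], base = base)
    base <- list(geom = sub$geom, depths = sub$depths)
    sim <- simulate_subject(cfg, sub, seed = seeds[i, 2])
    subjects[[i]] <- run_subject(sim, cfg, sub, seed = seeds[i, 3])
    substrates[[i]] <- sub
  }
  group <- lapply(stats::setNames(nm = cfg$glm_kinds), function(k)
    group_stats(subjects, kind = k))
  res <- structure(list(config = cfg, seed = seed,
                        substrate = substrates[[1]],
                        substrates = substrates,
                        subjects = subjects, group = group),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' Group-level profile matrices and statistics for one GLM kind
#'
#' Collects each subject's range-normalised global-mean profile (deveined
#' and uncorrected; all columns and vein-filtered), excludes subjects with
#' missing depths (reported in `dropped`), and runs the one-way
#' repeated-measures ANOVA across depths with Bonferroni post-hocs on the
#' deveined variant.
#'
#' @param subjects List of [run_subject()] results.
#' @param kind GLM kind name.
#' @param variant Profile variant for the ANOVA ("dev_excl", "dev_all",
#'   "unc_all", "unc_excl").
#' @return List: `profiles` (list of subjects x 6 matrices per variant),
#'   `mean`, `sem`, `anova`, `posthoc`, `ring_overlap` (subjects x 3),
#'   `dropped`.
#' @export
group_stats <- function(subjects, kind = "alpha", variant = "dev_excl") {
  kres <- lapply(subjects, function(s) s$kinds[[kind]])
  ok <- vapply(kres, function(k) isTRUE(k$detected), logical(1))
  variants <- c("unc_all", "dev_all", "unc_excl", "dev_excl")
  mats <- lapply(stats::setNames(nm = variants), function(v) {
    rows <- lapply(kres[ok], function(k) {
      pr <- k$profiles[[v]]
      tryCatch(range_normalize(pr)$mean, error = function(e)
        rep(NA_real_, 6))
    })
    do.call(rbind, rows)
  })
  M <- mats[[variant]]
  complete <- if (is.null(M)) logical(0) else stats::complete.cases(M)
  dropped <- which(ok)[!complete]
  anova <- posthoc <- NULL
  if (sum(complete) >= 2) {
    anova <- rm_anova_1way(M[complete, , drop = FALSE])
    posthoc <- posthoc_paired_t(M[complete, , drop = FALSE])
  }
  ring <- do.call(rbind, lapply(kres[ok], function(k) k$ring_overlap))
  list(profiles = mats,
       mean = if (!is.null(M)) colMeans(M[complete, , drop = FALSE]),
       sem = if (!is.null(M))
         apply(M[complete, , drop = FALSE], 2, stats::sd) /
           sqrt(sum(complete)),
       anova = anova, posthoc = posthoc, ring_overlap = ring,
       dropped = dropped, n_detected = sum(ok))
}

## write volumes/tables/manifest for a pipeline result
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vx <- res$config$geometry$voxel_mm
  sub <- res$substrate
  write_volume(sub$geom$vol, file.path(out_dir, "labels.nii.gz"), vx)
  write_volume(replace_na(sub$depths$bin, 0L),
               file.path(out_dir, "depth_bin.nii.gz"), vx)
  write_volume(replace_na(sub$columns$id, 0L),
               file.path(out_dir, "column_id.nii.gz"), vx)
  write_volume(sub$veins$vein, file.path(out_dir, "vein_truth.nii.gz"), vx)
  stages <- c("simulate", "regressor", "glm", "layers", "devein", "veins",
              "profiles", "stats")
  files <- c("labels.nii.gz", "depth_bin.nii.gz", "column_id.nii.gz",
             "vein_truth.nii.gz")
  for (k in names(res$group)) {
    g <- res$group[[k]]
    for (v in names(g$profiles)) {
      if (is.null(g$profiles[[v]])) next
      df <- as.data.frame(g$profiles[[v]])
      names(df) <- paste0("depth", seq_len(ncol(df)))
      f <- paste0("profiles_", k, "_", v, ".tsv")
      write_table_tsv(df, file.path(out_dir, f))
      files <- c(files, f)
    }
    if (!is.null(g$anova)) {
      f <- paste0("anova_", k, ".tsv")
      write_table_tsv(as.data.frame(g$anova), file.path(out_dir, f))
      files <- c(files, f)
    }
  }
  manifest <- list(package = "layeralpha", seed = res$seed,
                   n_subjects = res$config$n_subjects,
                   glm_kinds = res$config$glm_kinds,
                   stages_completed = stages, files = files)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

replace_na <- function(a, v) { a[is.na(a)] <- v; a }
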