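## Synthetic laminar 7T-like subjects: curved GM ribbon, penetrating veins,
## alpha-power dynamics and 4-D BOLD with draining-vein signal accumulation.
## Every stochastic element is seeded so a subject is bit-reproducible.

#' Curved grey-matter ribbon geometry
#'
#' Builds a labelled volume containing a partial annulus of grey matter
#' (GM, label 3) bounded by white matter inside (WM, label 2) and a
#' cerebrospinal-fluid rim outside (CSF, label 1), extruded through a number
#' of slices. The annulus has nonzero curvature, so equivolume and
#' equidistant depth coordinates genuinely differ, while its equal-area
#' shell boundaries sqrt(r1^2 + k/6 (r2^2 - r1^2)) are available in closed
#' form for testing.
#'
#' @param inner_radius_vox Inner (WM/GM) boundary radius in voxels.
#' @param outer_radius_vox Outer (GM/CSF) boundary radius in voxels.
#' @param arc Angular extent of the sector in radians, in (0, 2*pi].
#' @param thickness_slices Number of slices the sector is extruded through.
#' @param voxel_size_mm Isotropic voxel size recorded in the geometry.
#' @param csf_rim_vox Width of the CSF rim outside the outer boundary.
#' @return A `lam_geometry` list: `vol` (integer 3-D array with labels
#'   0/1/2/3), `voxdim`, and the generating parameters (`inner`, `outer`,
#'   `arc`, `center`).
#' @export
make_ribbon <- function(inner_radius_vox = 10, outer_radius_vox = 16,
                        arc = pi / 2, thickness_slices = 4,
                        voxel_size_mm = 0.8, csf_rim_vox = 2) {
  if (!(inner_radius_vox >= 2 && inner_radius_vox < outer_radius_vox))
    stop("invalid geometry: need 2 <= inner_radius_vox < outer_radius_vox")
  if (!(arc > 0 && arc <= 2 * pi + 1e-9)) stop("arc must be in (0, 2*pi]")
  stopifnot(thickness_slices >= 1)
  rmax <- outer_radius_vox + csf_rim_vox
  full_circle <- arc >= 2 * pi - 1e-9
  ## voxel centre (cx, cy) is the annulus centre; quadrant-style sectors sit
  ## in the positive octant, full circles are centred
  pad <- 1L
  if (full_circle) {
    n <- 2L * (ceiling(rmax) + pad) + 1L
    cx <- cy <- ceiling(rmax) + pad + 1L
  } else {
    n <- ceiling(rmax) + 2L * pad + 1L
    cx <- cy <- pad + 1L
  }
  ix <- seq_len(n)
  dx <- outer(ix - cx, rep(1, n))
  dy <- outer(rep(1, n), ix - cy)
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  in_arc <- if (full_circle) r >= 0 else (th >= -1e-9 & th <= arc + 1e-9)
  slice <- matrix(0L, n, n)
  slice[in_arc & r < inner_radius_vox] <- 2L
  slice[in_arc & r >= inner_radius_vox & r <= outer_radius_vox] <- 3L
  slice[in_arc & r > outer_radius_vox & r <= rmax] <- 1L
  vol <- array(rep(slice, thickness_slices), dim = c(n, n, thickness_slices))
  structure(list(vol = vol,
                 voxdim = rep(voxel_size_mm, 3),
                 inner = inner_radius_vox, outer = outer_radius_vox,
                 arc = arc, center = c(cx, cy),
                 labels = c(CSF = 1L, WM = 2L, GM = 3L)),
            class = "lam_geometry")
}

## radius of every voxel from the annulus axis (voxel units); used by tests
## and by make_veins
geometry_radius <- function(geom) {
  d <- dim(geom$vol)
  ix <- seq_len(d[1]); iy <- seq_len(d[2])
  r2 <- outer((ix - geom$center[1])^2, (iy - geom$center[2])^2, "+")
  array(rep(sqrt(r2), d[3]), dim = d)
}

geometry_angle <- function(geom) {
  d <- dim(geom$vol)
  dx <- outer(seq_len(d[1]) - geom$center[1], rep(1, d[2]))
  dy <- outer(rep(1, d[1]), seq_len(d[2]) - geom$center[2])
  array(rep(atan2(dy, dx), d[3]), dim = d)
}

#' Penetrating veins and their perivascular shells
#'
#' Places `n_veins` radial lines of voxels crossing the ribbon from the WM
#' boundary to the CSF rim at seeded angular positions (one slice each), and
#' marks the perivascular shell: all voxels within a Chebyshev distance
#' `ring_width_vox` of a vein voxel, excluding the vein itself. These sets
#' are the ground truth against which vein detection and vein-proximity
#' column exclusion are validated.
#'
#' @param geom A [make_ribbon()] geometry.
#' @param n_veins Number of veins (0 allowed).
#' @param ring_width_vox Chebyshev radius of the perivascular shell.
#' @param seed Integer seed.
#' @return A `vein_truth` list with logical arrays `vein` and `peri`, and
#'   `n_veins`.
#' @export
make_veins <- function(geom, n_veins = 3, ring_width_vox = 2, seed = 1) {
  stopifnot(inherits(geom, "lam_geometry"), n_veins >= 0)
  d <- dim(geom$vol)
  vein <- array(FALSE, d)
  if (n_veins > 0) {
    set.seed(seed)
    full_circle <- geom$arc >= 2 * pi - 1e-9
    lo <- if (full_circle) -pi else 0.1 * geom$arc
    hi <- if (full_circle) pi else 0.9 * geom$arc
    angles <- sort(stats::runif(n_veins, lo, hi))
    slices <- sample(seq_len(d[3]), n_veins, replace = TRUE)
    r <- geometry_radius(geom)
    th <- geometry_angle(geom)
    for (k in seq_len(n_veins)) {
      ## voxels whose perpendicular distance to the ray at angles[k] is
      ## under half a voxel, spanning the ribbon plus one voxel either side
      perp <- abs(r * sin(th - angles[k]))
      along <- r * cos(th - angles[k])
      hit <- perp <= 0.5 & along >= geom$inner - 1 & along <= geom$outer + 1 &
        geom$vol > 0L
      hit[, , -slices[k]] <- FALSE
      vein <- vein | hit
    }
  }
  peri <- if (any(vein)) dilate26(vein, ring_width_vox) & !vein
          else array(FALSE, d)
  structure(list(vein = vein, peri = peri, n_veins = n_veins),
            class = "vein_truth")
}

## Chebyshev-ball dilation: n iterations of the full 26-neighbourhood.
dilate26 <- function(mask, n_iter) {
  d <- dim(mask)
  out <- mask
  for (i in seq_len(n_iter)) {
    grown <- out
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      if (sx == 0 && sy == 0 && sz == 0) next
      grown <- grown | shift3(out, sx, sy, sz)
    }
    out <- grown
  }
  out
}

shift3 <- function(m, sx, sy, sz) {
  d <- dim(m)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]) - sx; ys <- seq_len(d[2]) - sy; zs <- seq_len(d[3]) - sz
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  okz <- zs >= 1 & zs <= d[3]
  out[okx, oky, okz] <- m[xs[okx], ys[oky], zs[okz]]
  out
}

#' Synthetic occipital alpha-power timecourse
#'
#' Nonnegative power series at the EEG sampling rate:
#' `baseline * (1 + modulation_depth * closed)` plus an AR(1) spontaneous
#' fluctuation, floored at zero. The block modulation emulates the
#' posterior alpha increase on eye closure; the AR(1) term stands in for
#' spontaneous within-block power fluctuations (their true dynamics are not
#' characterised, so a single-timescale process is used).
#'
#' @param p A [paradigm()].
#' @param modulation_depth Fractional power increase during eyes-closed.
#' @param ar1_coeff Per-sample AR(1) coefficient, |coeff| < 1.
#' @param noise_sd Stationary standard deviation of the AR(1) fluctuation.
#' @param baseline Eyes-open mean power.
#' @param seed Integer seed.
#' @return An [alpha_series()] covering the full run.
#' @export
make_alpha_timecourse <- function(p, modulation_depth = 0.5,
                                  ar1_coeff = 0.996, noise_sd = 0.1,
                                  baseline = 1, seed = 1) {
  stopifnot(modulation_depth >= 0, abs(ar1_coeff) < 1)
  n <- round(run_duration(p) * p$eeg_fs_hz)
  t_s <- (seq_len(n) - 0.5) / p$eeg_fs_hz
  closed <- condition_at(p, t_s) == "closed"
  x <- baseline * (1 + modulation_depth * closed)
  if (noise_sd > 0) {
    set.seed(seed)
    innov_sd <- noise_sd * sqrt(1 - ar1_coeff^2)
    ar <- as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd),
                                   ar1_coeff, method = "recursive"))
    x <- x + ar
  }
  alpha_series(pmax(x, 0), p$eeg_fs_hz, tr_s = p$tr_s)
}

#' Noise and physiology configuration for the BOLD generator
#'
#' Defaults define the simulated study conditions. `amplitude` is the peak
#' laminar response in percent-of-baseline signal units; `lf_sd` is the
#' per-depth standard deviation of the low-frequency (0.01-0.08 Hz)
#' physiological fluctuation, a venous-CBV proxy rising steeply above the
#' middle depths; `drain_shape` is the laminar profile of draining-vein
#' leakage, tied to `lf_sd` so that the ALFF measured downstream is an
#' unbiased estimate of the drainage weights; `drain_lambda` scales it
#' (weights are `drain_lambda * drain_shape / mean(drain_shape)`).
#'
#' @param amplitude Laminar response amplitude (signal units; baseline 100).
#' @param baseline Mean signal level.
#' @param white_sd White (thermal) noise SD.
#' @param lf_sd Length-6 SD of low-frequency fluctuations per depth
#'   (deep to superficial).
#' @param lf_band Frequency band of the fluctuations, Hz.
#' @param n_lf Number of sinusoids summed per voxel.
#' @param drain_shape Length-6 relative drainage-weight profile.
#' @param drain_lambda Scaling of the drainage weights.
#' @param lambda_jitter Half-width of the per-subject uniform jitter on
#'   `drain_lambda` (fraction; subjects differ in true drainage strength).
#' @param truth_jitter SD of the multiplicative per-depth Gaussian jitter
#'   applied to each subject's laminar response weights (between-subject
#'   biological variability in the laminar profile).
#' @param lf_jitter SD of the multiplicative per-depth jitter on `lf_sd`
#'   per subject: the fluctuation-amplitude profile tracks the drainage
#'   profile only imperfectly, so the ALFF surrogate is decoupled from the
#'   true drainage weights at the single-subject level.
#' @param peri_gain Gain of the superficial-signal copy added to
#'   perivascular (and vein) voxels; 0 disables vascular contamination.
#' @param vein_drop Fractional baseline signal drop inside veins (makes
#'   them dark on the mean EPI, as in GE-EPI).
#' @param subject_jitter Half-width of the uniform per-subject amplitude
#'   jitter (fraction of `amplitude`).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(amplitude = 3, baseline = 100, white_sd = 1,
                         lf_sd = c(0.5, 1.35, 7.0, 5.9, 5.9, 6.0),
                         lf_band = c(0.02, 0.08), n_lf = 8,
                         drain_shape = c(0.306, 0.410, 1.462, 1.252, 1.270, 1.300),
                         drain_lambda = 0.25, lambda_jitter = 0.15,
                         truth_jitter = 0.05, lf_jitter = 0.25,
                         peri_gain = 0.6, vein_drop = 0.4,
                         subject_jitter = 0.3) {
  stopifnot(length(lf_sd) == 6, length(drain_shape) == 6,
            all(lf_sd >= 0), all(drain_shape >= 0))
  structure(list(amplitude = amplitude, baseline = baseline,
                 white_sd = white_sd, lf_sd = lf_sd, lf_band = lf_band,
                 n_lf = n_lf, drain_shape = drain_shape,
                 drain_lambda = drain_lambda, lambda_jitter = lambda_jitter,
                 truth_jitter = truth_jitter, lf_jitter = lf_jitter,
                 peri_gain = peri_gain,
                 vein_drop = vein_drop, subject_jitter = subject_jitter),
            class = "noise_config")
}

#' Drainage weights implied by a noise configuration
#' @param cfg A [noise_config()].
#' @return Length-6 nonnegative weight vector (deep to superficial).
#' @export
sim_drain_weights <- function(cfg) {
  if (all(cfg$drain_shape == 0)) return(rep(0, 6))
  cfg$drain_lambda * cfg$drain_shape / mean(cfg$drain_shape)
}

#' Ground-truth laminar response profile
#'
#' @param shape "n" (middle depths attenuated to 50%), "flat", or
#'   "superficial" (response confined to the upper depths).
#' @param weights Optional explicit length-6 nonnegative weight vector
#'   (overrides `shape` presets).
#' @return A `ground_truth` list with `depth_weights` and `shape_name`.
#' @export
ground_truth <- function(shape = c("n", "flat", "superficial"),
                         weights = NULL) {
  shape <- match.arg(shape)
  if (is.null(weights)) {
    weights <- switch(shape,
                      n = c(1, 1, 0.5, 0.5, 1, 1),
                      flat = rep(1, 6),
                      superficial = c(0.2, 0.2, 0.4, 0.8, 1, 1))
  }
  stopifnot(length(weights) == 6, all(weights >= 0), max(weights) > 0)
  structure(list(depth_weights = weights, shape_name = shape),
            class = "ground_truth")
}

#' Simulate a subject's 4-D BOLD run
#'
#' Forward model, per GM voxel: the depth-local neural drive is
#' `-truth$depth_weights[depth]` times the HRF-convolved, demeaned,
#' TR-sampled alpha power (negative: alpha power and BOLD are
#' anticorrelated). The six depth-local drives are passed through the
#' draining-vein accumulation [forward_drain()] with the configured
#' drainage weights, so measured signal grows toward the pial surface.
#' Perivascular and vein voxels additionally receive a copy of the
#' superficial (depth-6) measured signal scaled by `peri_gain`, vein voxels
#' have a darkened baseline, and every voxel gets seeded low-frequency
#' sinusoid-mixture fluctuations (per-depth SD) plus white Gaussian noise.
#'
#' When `task_weights` is supplied, the block-locked part of the alpha
#' drive (condition means) and the spontaneous residual are given separate
#' laminar profiles, allowing task-locked and spontaneous-alpha coupling to
#' differ across depths. The default (`NULL`) gives both the `truth`
#' profile, which is algebraically identical to a single coupled drive.
#'
#' @param geom A [make_ribbon()] geometry.
#' @param depths A [compute_depths()] map on `geom`.
#' @param columns A [make_columns()] set on `geom` (recorded; drainage is
#'   configured globally so all columns share the same accumulation).
#' @param veins A [make_veins()] truth.
#' @param truth A [ground_truth()] laminar profile for the spontaneous
#'   alpha drive.
#' @param alpha An [alpha_series()] covering the run.
#' @param p A [paradigm()].
#' @param noise_cfg A [noise_config()].
#' @param seed Integer seed for noise.
#' @param task_weights Optional length-6 laminar profile for the
#'   block-locked drive component.
#' @return A `subject_sim` list: `bold` (4-D array), `geometry`, `veins`,
#'   `truth`, `alpha`, `motion` (n_vols x 6), `paradigm`, `noise_cfg`,
#'   `seed`, plus ground-truth internals `drive` (the noise-free regressor),
#'   `local_beta` and `measured_beta` (per-depth effective amplitudes) and
#'   `drain_v`.
#' @export
make_bold <- function(geom, depths, columns, veins, truth, alpha, p,
                      noise_cfg = noise_config(), seed = 1,
                      task_weights = NULL) {
  stopifnot(inherits(geom, "lam_geometry"), inherits(truth, "ground_truth"),
            inherits(noise_cfg, "noise_config"))
  vol <- geom$vol
  d <- dim(vol)
  gm <- which(vol == 3L)
  dep <- depths$bin[gm]
  if (anyNA(dep))
    stop("make_bold: some GM voxels have no depth assignment")
  nv <- p$n_vols
  set.seed(seed)
  amp <- noise_cfg$amplitude
  if (noise_cfg$subject_jitter > 0)
    amp <- amp * stats::runif(1, 1 - noise_cfg$subject_jitter,
                              1 + noise_cfg$subject_jitter)
  lam <- noise_cfg$drain_lambda
  if (noise_cfg$lambda_jitter > 0)
    lam <- lam * stats::runif(1, 1 - noise_cfg$lambda_jitter,
                              1 + noise_cfg$lambda_jitter)

  ## --- depth-local drives ------------------------------------------------
  reg_alpha <- make_regressor(alpha, p)$values        # demeaned, convolved
  sc <- stats::sd(reg_alpha)
  if (sc == 0) sc <- 1
  reg_alpha <- reg_alpha / sc   # unit-SD drive; amplitude carries the scale
  jit_w <- function(w) {
    if (is.null(noise_cfg$truth_jitter) || noise_cfg$truth_jitter <= 0)
      return(w)
    pmax(w * (1 + stats::rnorm(6, 0, noise_cfg$truth_jitter)), 0)
  }
  if (is.null(task_weights)) {
    spont_w <- task_w <- jit_w(truth$depth_weights)
    drive_task <- reg_alpha
    drive_spont <- reg_alpha * 0
  } else {
    stopifnot(length(task_weights) == 6)
    spont_w <- jit_w(truth$depth_weights)
    task_w <- jit_w(task_weights)
    blocked <- condition_mean_series(alpha, p)
    drive_task <- make_regressor(blocked, p)$values / sc
    drive_spont <- reg_alpha - drive_task
  }
  ## local beta timecourses per depth (6 x T), negative coupling
  b_local <- -amp * (outer(spont_w, drive_spont) + outer(task_w, drive_task))
  v <- sim_drain_weights(noise_cfg) * lam / noise_cfg$drain_lambda
  m <- forward_drain(b_local, v)

  ## --- assemble 4-D signal ----------------------------------------------
  nvox <- prod(d)
  bold <- matrix(stats::rnorm(nvox * nv, sd = noise_cfg$white_sd),
                 nrow = nvox, ncol = nv) + noise_cfg$baseline
  bold[gm, ] <- bold[gm, ] + m[dep, , drop = FALSE]

  ## vascular contamination: copy of the superficial measured signal
  vasc <- which((veins$vein | veins$peri) & vol == 3L)
  if (length(vasc) && noise_cfg$peri_gain != 0)
    bold[vasc, ] <- bold[vasc, ] +
      noise_cfg$peri_gain * matrix(m[6, ], length(vasc), nv, byrow = TRUE)
  vein_idx <- which(veins$vein & vol > 0L)
  if (length(vein_idx) && noise_cfg$vein_drop > 0)
    bold[vein_idx, ] <- bold[vein_idx, ] -
      noise_cfg$baseline * noise_cfg$vein_drop

  ## low-frequency physiological fluctuations, per-voxel random phase
  if (any(noise_cfg$lf_sd > 0)) {
    t_mid <- volume_midpoints(p)
    lf_sd_s <- noise_cfg$lf_sd
    if (!is.null(noise_cfg$lf_jitter) && noise_cfg$lf_jitter > 0)
      lf_sd_s <- pmax(lf_sd_s * (1 + stats::rnorm(6, 0, noise_cfg$lf_jitter)),
                      0)
    sd_per_sine <- lf_sd_s / sqrt(noise_cfg$n_lf)
    a_vox <- sd_per_sine[dep] * sqrt(2)   # sinusoid amplitude for target SD
    for (k in seq_len(noise_cfg$n_lf)) {
      f <- stats::runif(length(gm), noise_cfg$lf_band[1], noise_cfg$lf_band[2])
      ph <- stats::runif(length(gm), 0, 2 * pi)
      bold[gm, ] <- bold[gm, ] + a_vox * sin(outer(f, t_mid) * 2 * pi + ph)
    }
  }

  motion <- matrix(stats::rnorm(nv * 6, sd = 0.02), nv, 6)
  motion <- apply(motion, 2, cumsum)

  structure(list(bold = array(bold, dim = c(d, nv)),
                 geometry = geom, veins = veins, truth = truth,
                 alpha = alpha, motion = motion, paradigm = p,
                 noise_cfg = noise_cfg, seed = seed,
                 drive = reg_alpha, lambda_subject = lam,
                 local_beta = -amp * spont_w,
                 task_beta = -amp * task_w,
                 measured_beta = forward_drain(-amp * spont_w, v),
                 drain_v = v),
            class = "subject_sim")
}

## alpha series with each sample replaced by its condition mean (the
## block-locked component of the alpha drive)
condition_mean_series <- function(series, p) {
  n <- length(series$values)
  t_s <- (seq_len(n) - 0.5) / series$fs_hz
  cond <- condition_at(p, t_s)
  mu <- tapply(series$values, cond, mean)
  alpha_series(as.numeric(mu[cond]), series$fs_hz, tr_s = p$tr_s)
}
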