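## Vein-proximity diagnostics: vein and surrounding-vein masks from the
## mean EPI, per-column deveining-induced gradient changes, 25/50/25
## classification, ring-overlap quantification and top-25% exclusion.

#' Vein mask from a mean EPI image
#'
#' Unsharp-mask detection of locally dark voxels: the mean EPI minus its
#' Gaussian-smoothed version (2 mm FWHM), thresholded at a low percentile
#' of the difference within the ROI. Veins are locally dark in
#' T2*-weighted GE-EPI, so the lower tail is taken; the percentile replaces
#' the manual threshold used interactively at full scale.
#'
#' @param mean_epi 3-D array.
#' @param roi_mask Logical array restricting detection.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param cutoff_pct Percentile of the within-ROI difference below which a
#'   voxel is called vein.
#' @param voxdim_mm Voxel size (scalar or length 3) in mm.
#' @return Logical vein mask.
#' @export
make_vein_mask <- function(mean_epi, roi_mask, fwhm_mm = 2, cutoff_pct = 5,
                           voxdim_mm = 0.8) {
  stopifnot(identical(dim(mean_epi), dim(roi_mask)))
  if (!any(roi_mask)) stop("empty ROI")
  voxdim_mm <- rep(voxdim_mm, length.out = 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxdim_mm
  sm <- gaussian_smooth3d(mean_epi, sigma_vox)
  diffim <- mean_epi - sm
  cut <- stats::quantile(diffim[roi_mask], cutoff_pct / 100, names = FALSE)
  ## a vein must be genuinely dark, not a numerical tie on a flat image
  floor_tol <- -1e-9 * max(abs(mean_epi), 1)
  roi_mask & diffim < pmin(cut, floor_tol)
}

#' Surrounding-vein ring mask
#'
#' Dilates the vein mask `n_dilations` times with a 6-connected structuring
#' element and subtracts the undilated mask, leaving a ring of perivascular
#' tissue.
#'
#' @param vein Logical vein mask.
#' @param n_dilations Number of dilation iterations.
#' @return A `vein_masks` list: `vein`, `ring`, `n_dilations`.
#' @export
make_ring_mask <- function(vein, n_dilations = 4) {
  ring <- if (any(vein)) dilate6(vein, n_dilations) & !vein
          else vein & FALSE
  structure(list(vein = vein, ring = ring,
                 n_dilations = as.integer(n_dilations)),
            class = "vein_masks")
}

#' Linear gradient of a depth profile
#'
#' Least-squares slope of a first-order polynomial of profile value against
#' depth index 1..6; unpopulated depths (NA) are omitted from the fit.
#'
#' @param profile Numeric vector of per-depth values (NA allowed).
#' @return Slope, or NA when fewer than 2 depths are populated.
#' @export
profile_gradient <- function(profile) {
  ok <- which(!is.na(profile))
  if (length(ok) < 2) return(NA_real_)
  x <- ok - mean(ok)
  sum(x * profile[ok]) / sum(x^2)
}

#' Classify columns by deveining-induced gradient change
#'
#' Ranks included columns by `delta = |slope_deveined - slope_uncorrected|`
#' and splits them into the lower 25%, middle 50% and upper 25% of gradient
#' changes (rank boundaries at n/4; ties broken by rank order, lower rank
#' to the lower class).
#'
#' @param tab Data frame with columns `column`, `slope_unc`, `slope_dev`.
#' @return The table with added `delta`, `rank` and `class` (factor
#'   lower25/middle50/upper25).
#' @export
classify_gradient_change <- function(tab) {
  stopifnot(all(c("column", "slope_unc", "slope_dev") %in% names(tab)))
  n <- nrow(tab)
  if (n < 4) stop("need at least 4 included columns to classify")
  tab$delta <- abs(tab$slope_dev - tab$slope_unc)
  tab$rank <- rank(tab$delta, ties.method = "first")
  n_low <- round(n / 4)
  n_up <- round(n / 4)
  cls <- rep("middle50", n)
  cls[tab$rank <= n_low] <- "lower25"
  cls[tab$rank > n - n_up] <- "upper25"
  tab$class <- factor(cls, levels = c("lower25", "middle50", "upper25"))
  tab
}

#' Ring-mask overlap percentage per gradient-change class
#'
#' For each class: 100 x (retained voxels of that class's columns that lie
#' in the surrounding-vein ring) / (retained voxels of that class's
#' columns). The denominator is the retained (beta-thresholded) voxel set.
#'
#' @param classes A [classify_gradient_change()] table.
#' @param columns A [make_columns()] set.
#' @param ring Logical ring mask.
#' @param retained Logical array of retained voxels.
#' @return Named numeric vector of percentages (NA for a class with no
#'   retained voxels).
#' @export
class_ring_overlap <- function(classes, columns, ring, retained) {
  out <- c(lower25 = NA_real_, middle50 = NA_real_, upper25 = NA_real_)
  for (cl in names(out)) {
    ids <- classes$column[classes$class == cl]
    sel <- retained & !is.na(columns$id) & columns$id %in% ids
    n <- sum(sel)
    if (n > 0) out[cl] <- 100 * sum(sel & ring) / n
  }
  out
}

#' Exclude the columns most affected by deveining
#'
#' @param included Integer vector of included column ids.
#' @param classes A [classify_gradient_change()] table (or NULL, returning
#'   `included` unchanged).
#' @return `included` minus the upper-25% columns.
#' @export
exclude_top_columns <- function(included, classes) {
  if (is.null(classes)) return(included)
  setdiff(included, classes$column[classes$class == "upper25"])
}
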