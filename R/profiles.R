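## Cortical depth profiles and their repeated-measures statistics.

#' Global-mean depth profile
#'
#' Mean and SEM of beta per depth over the retained voxels (negative betas
#' only, by default) pooled across all included columns. The
#' negative-voxel selection must be recomputed separately for uncorrected
#' and deveined maps, since deveining can flip beta signs.
#'
#' @param betamap 3-D beta array.
#' @param columns A [make_columns()] set.
#' @param depths A [compute_depths()] map.
#' @param retained Logical array of retained voxels.
#' @param include Integer vector of included column ids.
#' @param sign "negative" (keep beta < 0) or "all".
#' @return A `depth_profile` list: `mean`, `sem`, `n` (length-6 vectors,
#'   NA/0 at unpopulated depths), `scheme`.
#' @export
global_mean_profile <- function(betamap, columns, depths, retained,
                                include, sign = c("negative", "all")) {
  sign <- match.arg(sign)
  sel <- retained & !is.na(columns$id) & columns$id %in% include &
    !is.na(betamap)
  if (sign == "negative") sel <- sel & betamap < 0
  nd <- depths$n_depths
  m <- s <- rep(NA_real_, nd)
  n <- rep(0L, nd)
  db <- depths$bin[sel]
  bv <- betamap[sel]
  for (i in seq_len(nd)) {
    vi <- bv[db == i]
    n[i] <- length(vi)
    if (n[i] > 0) m[i] <- mean(vi)
    if (n[i] > 1) s[i] <- stats::sd(vi) / sqrt(n[i])
  }
  structure(list(mean = m, sem = s, n = n, scheme = "global_mean"),
            class = "depth_profile")
}

#' Column-profile-mean depth profile
#'
#' A per-column depth profile (mean over that column's retained negative
#' voxels per depth) averaged, unweighted, across columns: every column
#' contributes equally regardless of how many voxels it holds.
#'
#' @inheritParams global_mean_profile
#' @return A `depth_profile` (`sem` across columns).
#' @export
column_profile_mean <- function(betamap, columns, depths, retained,
                                include, sign = c("negative", "all")) {
  sign <- match.arg(sign)
  nd <- depths$n_depths
  per_col <- matrix(NA_real_, length(include), nd)
  for (r in seq_along(include)) {
    sel <- retained & !is.na(columns$id) & columns$id == include[r] &
      !is.na(betamap)
    if (sign == "negative") sel <- sel & betamap < 0
    db <- depths$bin[sel]
    bv <- betamap[sel]
    for (i in seq_len(nd))
      if (any(db == i)) per_col[r, i] <- mean(bv[db == i])
  }
  m <- s <- rep(NA_real_, nd)
  n <- integer(nd)
  for (i in seq_len(nd)) {
    vi <- per_col[!is.na(per_col[, i]), i]
    n[i] <- length(vi)
    if (n[i] > 0) m[i] <- mean(vi)
    if (n[i] > 1) s[i] <- stats::sd(vi) / sqrt(n[i])
  }
  structure(list(mean = m, sem = s, n = n, scheme = "column_profile_mean",
                 per_column = per_col),
            class = "depth_profile")
}

#' Range-normalise a depth profile
#'
#' Divides the profile by its range (max - min over populated depths),
#' preserving sign and shape; the range becomes 1. No shift is applied by
#' default (the shape, not the offset, is the quantity of interest);
#' shift-then-scale is available via `shift`.
#'
#' @param profile A `depth_profile` or numeric vector.
#' @param shift If TRUE, subtract the minimum before scaling.
#' @return Same type as the input, normalised.
#' @export
range_normalize <- function(profile, shift = FALSE) {
  vals <- if (inherits(profile, "depth_profile")) profile$mean else profile
  ok <- !is.na(vals)
  if (sum(ok) < 2) stop("need at least 2 populated depths")
  rng <- max(vals[ok]) - min(vals[ok])
  if (rng == 0) stop("profile has zero range; cannot normalise")
  out_vals <- (vals - if (shift) min(vals[ok]) else 0) / rng
  if (inherits(profile, "depth_profile")) {
    profile$mean <- out_vals
    if (!is.null(profile$sem)) profile$sem <- profile$sem / rng
    profile
  } else out_vals
}

#' Column-count-weighted average of per-ROI profiles
#'
#' @param profiles List of `depth_profile`s (or numeric vectors) on the
#'   same depth axis.
#' @param n_columns_per_roi Numeric weights (column counts per ROI).
#' @return Numeric length-6 weighted-mean profile.
#' @export
roi_weighted_average <- function(profiles, n_columns_per_roi) {
  stopifnot(length(profiles) == length(n_columns_per_roi))
  if (sum(n_columns_per_roi) == 0) stop("all ROI weights are zero")
  vals <- sapply(profiles, function(p)
    if (inherits(p, "depth_profile")) p$mean else as.numeric(p))
  as.numeric(vals %*% n_columns_per_roi / sum(n_columns_per_roi))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test of a single factor: F = MS_level over
#' MS_(level x subject), df = (k-1, (k-1)(n-1)). Fitted with
#' `stats::aov()` using an `Error(subject/level)` stratum.
#'
#' @param data n_subjects x n_levels numeric matrix (complete).
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_1way <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("rm-ANOVA requires a complete matrix")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 levels")
  ## degenerate case: every subject constant across levels
  scale <- max(abs(data), 1)
  if (max(apply(data, 1, function(r) diff(range(r)))) < 1e-12 * scale)
    return(list(F = 0, df1 = k - 1, df2 = (k - 1) * (n - 1), p = 1))
  dd <- data.frame(y = as.vector(data),
                   subj = factor(rep(seq_len(n), times = k)),
                   lev = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ lev + Error(subj / lev), data = dd)
  st <- extract_rm_effect(fit, "lev")
  if (is.na(st$F)) st <- list(F = 0, df1 = k - 1, df2 = (k - 1) * (n - 1),
                              p = 1)
  st
}

#' Two-way repeated-measures ANOVA
#'
#' Both factors within subject; each effect (A, B, A:B) is tested against
#' its own subject-interaction error stratum.
#'
#' @param data 3-D array: subjects x levels of A x levels of B (complete).
#' @param names_ab Length-2 character naming the factors (cosmetic).
#' @return Data frame with rows A, B, A:B and columns `F`, `df1`, `df2`,
#'   `p`.
#' @export
rm_anova_2way <- function(data, names_ab = c("A", "B")) {
  stopifnot(length(dim(data)) == 3)
  if (anyNA(data)) stop("rm-ANOVA requires a complete design")
  n <- dim(data)[1]; ka <- dim(data)[2]; kb <- dim(data)[3]
  if (n < 2 || ka < 2 || kb < 2) stop("need >= 2 subjects and levels")
  dd <- data.frame(y = as.vector(data),
                   subj = factor(rep(seq_len(n), times = ka * kb)),
                   A = factor(rep(rep(seq_len(ka), each = n), times = kb)),
                   B = factor(rep(seq_len(kb), each = n * ka)))
  fit <- stats::aov(y ~ A * B + Error(subj / (A * B)), data = dd)
  eff <- list(A = extract_rm_effect(fit, "A", stratum = "subj:A"),
              B = extract_rm_effect(fit, "B", stratum = "subj:B"),
              `A:B` = extract_rm_effect(fit, "A:B", stratum = "subj:A:B"))
  out <- do.call(rbind, lapply(eff, as.data.frame))
  rownames(out) <- c(names_ab, paste(names_ab, collapse = ":"))
  ## zero-variance effects (e.g. data constant in one factor) are exact
  ## nulls: F = 0, p = 1
  scale <- max(abs(data), 1)
  rngB <- max(apply(data, c(1, 2), function(v) diff(range(v))))
  rngA <- max(apply(data, c(1, 3), function(v) diff(range(v))))
  df1s <- c(ka - 1, kb - 1, (ka - 1) * (kb - 1))
  zero <- c(rngA < 1e-12 * scale, rngB < 1e-12 * scale,
            rngA < 1e-12 * scale || rngB < 1e-12 * scale)
  for (i in 1:3) {
    if (is.na(out$F[i]) || zero[i]) {
      out$F[i] <- 0; out$p[i] <- 1
      out$df1[i] <- df1s[i]; out$df2[i] <- df1s[i] * (n - 1)
    }
  }
  out
}

## pull one effect's F test out of a multistratum aov summary
extract_rm_effect <- function(fit, term, stratum = NULL) {
  sm <- summary(fit)
  for (nm in names(sm)) {
    if (!is.null(stratum) && !grepl(stratum, nm, fixed = TRUE)) next
    tab <- sm[[nm]][[1]]
    rn <- trimws(rownames(tab))
    hit <- which(rn == term)
    if (length(hit) == 1 && !is.na(tab[hit, "F value"])) {
      res <- which(rn == "Residuals")
      return(list(F = tab[hit, "F value"], df1 = tab[hit, "Df"],
                  df2 = tab[res, "Df"], p = tab[hit, "Pr(>F)"]))
    }
  }
  list(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_)
}

#' Post-hoc paired t-tests with Bonferroni correction
#'
#' All level pairs, two-sided paired t; adjusted p is `p_raw` times the
#' family size, clipped at 1. The family defaults to the number of pairs.
#'
#' @param data n_subjects x n_levels matrix.
#' @param family_size Multiplier for the Bonferroni correction.
#' @return Data frame: `level_i`, `level_j`, `t`, `p_raw`, `p_adj`.
#' @export
posthoc_paired_t <- function(data, family_size = NULL) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2) stop("need >= 2 subjects")
  pairs <- utils::combn(k, 2)
  if (is.null(family_size)) family_size <- ncol(pairs)
  res <- apply(pairs, 2, function(pr) {
    dd <- data[, pr[1]] - data[, pr[2]]
    if (stats::sd(dd) == 0) {
      c(t = if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf,
        p = if (mean(dd) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(data[, pr[1]], data[, pr[2]], paired = TRUE)
      c(t = unname(tt$statistic), p = tt$p.value)
    }
  })
  data.frame(level_i = pairs[1, ], level_j = pairs[2, ],
             t = res["t", ], p_raw = res["p", ],
             p_adj = pmin(1, res["p", ] * family_size))
}
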