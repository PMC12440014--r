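## Voxelwise GLM: OLS fitting against an interest regressor plus nuisance
## terms, t-to-z conversion by CDF quantile matching, fixed-effects
## combination over runs, permutation-based cluster thresholding of the
## negative contrast, and nearest-neighbour upsampling.

#' Assemble a GLM design
#'
#' Interest regressor, six motion nuisance regressors and an intercept.
#'
#' @param interest A `regressor` (or numeric vector), one value per volume.
#' @param motion n_vols x 6 matrix of motion nuisance timecourses (may be
#'   NULL for none).
#' @return A `glm_design` list: `X` (design matrix, interest first,
#'   intercept last), `interest_col`.
#' @export
glm_design <- function(interest, motion = NULL) {
  iv <- if (inherits(interest, "regressor")) interest$values
        else as.numeric(interest)
  X <- cbind(interest = iv)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == length(iv))
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
  }
  X <- cbind(X, intercept = 1)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, interest_col = 1L,
                 kind = if (inherits(interest, "regressor")) interest$kind
                        else "custom"),
            class = "glm_design")
}

#' Voxelwise ordinary least squares
#'
#' Fits `design` to every voxel in `mask` and returns beta, standard error,
#' t and z maps for the interest regressor. z is obtained by matching the
#' t CDF quantile to the standard normal (exact at low df, not a normal
#' approximation).
#'
#' @param bold 4-D array (x, y, z, t).
#' @param design A [glm_design()].
#' @param mask Logical 3-D array of voxels to fit.
#' @return A `glm_fit` list: maps `beta`, `se`, `t`, `z` (3-D arrays, NA
#'   outside the mask), `df`, plus internals used by [cluster_threshold()]
#'   (`resid`, unit-norm partialled regressor `x_tilde`, `mask`).
#' @export
fit_glm <- function(bold, design, mask) {
  d <- dim(bold)
  stopifnot(length(d) == 4, inherits(design, "glm_design"))
  X <- design$X
  stopifnot(nrow(X) == d[4])
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  Y <- matrix(aperm(bold, c(4, 1, 2, 3)), nrow = d[4])[, idx, drop = FALSE]
  p <- ncol(X)
  df <- nrow(X) - p
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Y)
  E <- Y - X %*% coefs
  sigma2 <- colSums(E^2) / df
  XtXinv_ii <- chol2inv(qr.R(qrX))[design$interest_col, design$interest_col]
  beta <- coefs[design$interest_col, ]
  se <- sqrt(sigma2 * XtXinv_ii)
  tstat <- beta / se
  z <- t_to_z(tstat, df)
  ## partialled interest regressor (residual on the other columns), unit norm
  others <- X[, -design$interest_col, drop = FALSE]
  x_t <- X[, design$interest_col] -
    others %*% qr.solve(others, X[, design$interest_col])
  x_t <- as.numeric(x_t) / sqrt(sum(x_t^2))
  mk <- function(v) { a <- array(NA_real_, d[1:3]); a[idx] <- v; a }
  structure(list(beta = mk(beta), se = mk(se), t = mk(tstat), z = mk(z),
                 df = df, resid = E, x_tilde = x_t, mask = mask,
                 kind = design$kind),
            class = "glm_fit")
}

#' Convert t statistics to z scores by quantile matching
#' @param t Numeric vector of t statistics.
#' @param df Degrees of freedom.
#' @return z scores with the same tail probabilities.
#' @export
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  neg <- !is.na(t) & t <= 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df, log.p = TRUE),
                           log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

#' Fixed-effects combination of runs
#'
#' Inverse-variance-weighted beta across runs; the combined z is the
#' combined beta over its pooled standard error.
#'
#' @param per_run List of `glm_fit` objects (or lists with `beta` and `se`
#'   arrays) on a common grid.
#' @return List with `beta`, `se` and `z` arrays.
#' @export
fixed_effects <- function(per_run) {
  stopifnot(length(per_run) >= 1)
  dims <- lapply(per_run, function(r) dim(r$beta))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("runs are on mismatched grids")
  W <- lapply(per_run, function(r) 1 / r$se^2)
  wsum <- Reduce(`+`, W)
  bsum <- Reduce(`+`, Map(function(w, r) w * r$beta, W, per_run))
  beta <- bsum / wsum
  se <- sqrt(1 / wsum)
  list(beta = beta, se = se, z = beta / se)
}

#' Cluster thresholding of the negative contrast
#'
#' Voxels with z below `z_crit` are grouped by 26-connectivity; a cluster
#' is retained when its size exceeds the (1 - alpha) quantile of the
#' maximum cluster size under a sign-flipping permutation null built from
#' the model residuals (which are exchangeable in sign under the null of no
#' interest effect).
#'
#' @param fit A [fit_glm()] result.
#' @param z_crit Cluster-forming threshold (negative tail).
#' @param alpha Family-wise error target.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed for the flips.
#' @return A list: `mask` (logical array of retained voxels), `clusters`
#'   (data frame of observed cluster sizes and retention), `size_threshold`,
#'   `null_max_sizes`, `n_perm`, and `low_n_perm` flag when `n_perm` < 100.
#' @export
cluster_threshold <- function(fit, z_crit = -2.3, alpha = 0.05,
                              n_perm = 200, seed = 1) {
  stopifnot(inherits(fit, "glm_fit"))
  d <- dim(fit$z)
  idx <- which(fit$mask)
  ## null distribution of max cluster size from sign-flipped residuals
  set.seed(seed)
  E <- fit$resid
  en2 <- colSums(E^2)
  df <- fit$df
  max_sizes <- integer(n_perm)
  supra <- array(FALSE, d)
  for (b in seq_len(n_perm)) {
    s <- sample(c(-1, 1), nrow(E), replace = TRUE)
    cvec <- as.numeric(crossprod(E, s * fit$x_tilde))
    r2 <- pmin(cvec^2 / pmax(en2, 1e-300), 1 - 1e-12)
    tnull <- sign(cvec) * sqrt(df * r2 / (1 - r2))
    znull <- t_to_z(tnull, df)
    supra[] <- FALSE
    supra[idx[znull < z_crit]] <- TRUE
    if (any(supra)) {
      lab <- label_components26(supra)
      max_sizes[b] <- max(tabulate(lab[lab > 0L]))
    }
  }
  ## permutation-exact threshold: the ceil((1-alpha)(B+1))-th order
  ## statistic of the null maxima (accounts for the observed map being one
  ## more member of the exchangeable family)
  k <- sort(max_sizes)[min(n_perm, ceiling((1 - alpha) * (n_perm + 1)))]
  ## observed clusters
  obs <- !is.na(fit$z) & fit$z < z_crit
  out_mask <- array(FALSE, d)
  clusters <- data.frame(cluster = integer(0), size = integer(0),
                         retained = logical(0))
  if (any(obs)) {
    lab <- label_components26(obs)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes > k)
    out_mask <- array(lab %in% keep, d)
    clusters <- data.frame(cluster = seq_along(sizes), size = sizes,
                           retained = seq_along(sizes) %in% keep)
  }
  list(mask = out_mask, clusters = clusters, size_threshold = k,
       null_max_sizes = max_sizes, n_perm = n_perm,
       low_n_perm = n_perm < 100)
}

#' Nearest-neighbour upsampling of a 3-D map
#'
#' Replicates voxel values onto a finer grid (value multiset preserved for
#' integer factors) and rescales the recorded voxel size.
#'
#' @param map 3-D array, optionally with a `voxdim` attribute.
#' @param factor Upsampling factor per axis (recycled to length 3);
#'   positive, typically integer (e.g. 4 for 0.7 mm to 0.175 mm).
#' @return Upsampled array with adjusted `voxdim` attribute.
#' @export
upsample_nn <- function(map, factor) {
  factor <- rep(factor, length.out = 3)
  if (any(factor <= 0)) stop("upsampling factors must be positive")
  d <- dim(map)
  stopifnot(length(d) == 3)
  nd <- round(d * factor)
  ix <- lapply(1:3, function(a) pmin(pmax(ceiling(seq_len(nd[a]) / factor[a]),
                                          1L), d[a]))
  out <- map[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  vd <- attr(map, "voxdim")
  if (!is.null(vd)) attr(out, "voxdim") <- vd / factor
  out
}
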