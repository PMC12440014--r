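## Draining-vein correction by spatial deconvolution. The model: each
## depth's measured GE-BOLD signal is its local signal plus a weighted sum
## of all deeper local signals (ascending venous drainage); the weights are
## the ALFF-derived venous-blood-volume surrogate scaled by lambda. The
## forward accumulation and its exact triangular inverse are the testable
## contract.

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel: the variance of the within-period-demeaned signal over each
#' eyes-closed period, averaged across periods and square-rooted to
#' amplitude (signal) units. Computed from eyes-closed periods only, when
#' the BOLD signal is elevated and venous fluctuations dominate; the
#' periods are delayed by the haemodynamic lag so the onset transient of
#' the evoked response does not masquerade as a fluctuation.
#'
#' @param bold 4-D array.
#' @param p A [paradigm()].
#' @param mask Logical 3-D array.
#' @param shift_s Haemodynamic delay in seconds applied when mapping task
#'   periods onto BOLD volumes, so each window samples the steady
#'   eyes-closed response rather than the onset transient. Defaults to the
#'   canonical HRF peak delay.
#' @return 3-D array of nonnegative amplitudes (NA outside the mask).
#' @export
compute_alff <- function(bold, p, mask, shift_s = 6) {
  d <- dim(bold)
  stopifnot(length(d) == 4)
  closed <- condition_at(p, volume_midpoints(p) - shift_s) == "closed"
  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  periods <- Map(`:`, starts[r$values], ends[r$values])
  if (length(periods) == 0) stop("paradigm has no eyes-closed volumes")
  if (any(vapply(periods, length, 1L) < 2))
    stop("an eyes-closed period has fewer than 2 volumes")
  idx <- which(mask)
  Y <- matrix(aperm(bold, c(4, 1, 2, 3)), nrow = d[4])[, idx, drop = FALSE]
  v <- Reduce(`+`, lapply(periods, function(tt) {
    Yp <- Y[tt, , drop = FALSE]
    colSums(sweep(Yp, 2, colMeans(Yp))^2) / (length(tt) - 1)
  })) / length(periods)
  out <- array(NA_real_, d[1:3])
  out[idx] <- sqrt(v)
  out
}

#' Per-column drainage weights from ALFF
#'
#' For each column, the depth-mean ALFF `a_i` is scaled to
#' `v_i = lambda * a_i / mean(a_1..a_6)`; depths with no voxels inherit the
#' weight of the nearest populated depth. A column with all-zero ALFF gets
#' zero weights (no correction).
#'
#' @param alff A [compute_alff()] map.
#' @param columns A [make_columns()] set.
#' @param depths A [compute_depths()] map.
#' @param lambda Scaling parameter (physiological range 0.2-0.3).
#' @param include Optional integer vector of column ids (default: all).
#' @return A `drainage_weights` list: `v` (n_columns x 6 matrix, rows named
#'   by column id), `lambda`.
#' @export
drainage_weights <- function(alff, columns, depths, lambda = 0.25,
                             include = NULL) {
  ids <- if (is.null(include)) sort(unique(stats::na.omit(c(columns$id))))
         else sort(include)
  nd <- depths$n_depths
  V <- matrix(0, length(ids), nd, dimnames = list(ids, NULL))
  for (r in seq_along(ids)) {
    sel <- !is.na(columns$id) & columns$id == ids[r] & !is.na(alff)
    a <- rep(NA_real_, nd)
    db <- depths$bin[sel]
    av <- alff[sel]
    for (i in seq_len(nd)) if (any(db == i)) a[i] <- mean(av[db == i])
    pop <- which(!is.na(a))
    if (length(pop) == 0) next
    for (i in which(is.na(a))) a[i] <- a[pop[which.min(abs(pop - i))]]
    if (all(a == 0)) next
    V[r, ] <- lambda * a / mean(a)
  }
  structure(list(v = V, lambda = lambda), class = "drainage_weights")
}

#' Forward draining-vein accumulation
#'
#' `m_1 = b_1`; for i >= 2, `m_i = b_i + v_i * sum_{j<i} b_j`: each depth's
#' measured signal accumulates a weighted sum of all deeper local signals.
#' Depth 1 is deep.
#'
#' @param b Length-6 vector of depth-local values, or a 6 x T matrix of
#'   depth-local timecourses.
#' @param v Length-6 weight vector (or a `drainage_weights` row).
#' @return Measured values, same shape as `b`.
#' @export
forward_drain <- function(b, v) {
  v <- as.numeric(v)
  mat <- is.matrix(b)
  B <- if (mat) b else matrix(b, ncol = 1)
  stopifnot(nrow(B) == length(v))
  S <- rbind(0, apply(B, 2, cumsum)[-nrow(B), , drop = FALSE])
  M <- B + v * S
  if (mat) M else as.numeric(M)
}

#' Spatial deconvolution (deveining) of measured values
#'
#' Exact inverse of [forward_drain()]: `bhat_1 = m_1`; for i >= 2,
#' `bhat_i = m_i - v_i * sum_{j<i} bhat_j` (peeling the accumulated deeper
#' signal off each depth in turn).
#'
#' @param m Length-6 measured vector or 6 x T matrix.
#' @param v Length-6 weight vector.
#' @return Deveined values, same shape as `m`.
#' @export
spatial_deconvolve <- function(m, v) {
  v <- as.numeric(v)
  mat <- is.matrix(m)
  M <- if (mat) m else matrix(m, ncol = 1)
  stopifnot(nrow(M) == length(v))
  B <- M
  run <- M[1, , drop = FALSE]
  for (i in seq_len(nrow(M))[-1]) {
    B[i, ] <- M[i, ] - v[i] * run
    run <- run + B[i, , drop = FALSE]
  }
  if (mat) B else as.numeric(B)
}

#' Devein a beta map column by column
#'
#' For each included column the depth-mean beta vector is deconvolved with
#' that column's drainage weights; the per-depth change `bhat_i - mean_i`
#' is then applied additively to every voxel at that depth of the column,
#' preserving within-depth spatial variance. Columns with no voxels at
#' depth 1 are anchored at their deepest populated depth and flagged.
#'
#' @param betamap 3-D beta array.
#' @param columns A [make_columns()] set.
#' @param depths A [compute_depths()] map.
#' @param alff ALFF map used to build weights (ignored when `weights`
#'   given).
#' @param lambda Scaling parameter.
#' @param weights Optional precomputed [drainage_weights()] (or a single
#'   length-6 vector applied to every column).
#' @param include Integer vector of column ids to correct (default: all).
#' @return Deveined beta array with attributes `anchored` (ids of columns
#'   not anchored at depth 1) and `sign_flips` (count of voxels whose beta
#'   changed sign).
#' @export
devein_volume <- function(betamap, columns, depths, alff = NULL,
                          lambda = 0.25, weights = NULL, include = NULL) {
  ids <- if (is.null(include)) sort(unique(stats::na.omit(c(columns$id))))
         else sort(include)
  nd <- depths$n_depths
  if (is.null(weights)) {
    if (is.null(alff)) stop("supply either `alff` or `weights`")
    weights <- drainage_weights(alff, columns, depths, lambda,
                                include = ids)
  }
  if (is.numeric(weights) && is.null(dim(weights))) {
    V <- matrix(rep(weights, each = length(ids)), length(ids), nd,
                dimnames = list(ids, NULL))
  } else {
    V <- weights$v[as.character(ids), , drop = FALSE]
  }
  out <- betamap
  anchored <- integer(0)
  for (r in seq_along(ids)) {
    sel <- !is.na(columns$id) & columns$id == ids[r] & !is.na(betamap)
    if (!any(sel)) next
    db <- depths$bin[sel]
    bv <- betamap[sel]
    pop <- sort(unique(db))
    mvec <- vapply(pop, function(i) mean(bv[db == i]), 0)
    if (pop[1] != 1L) anchored <- c(anchored, ids[r])
    ## peel over the populated depths in deep-to-superficial order; the
    ## deepest populated depth is the anchor
    bhat <- spatial_deconvolve(matrix(mvec, ncol = 1), V[r, pop])
    corr <- as.numeric(bhat) - mvec
    sel_idx <- which(sel)
    for (q in seq_along(pop))
      out[sel_idx[db == pop[q]]] <- betamap[sel_idx[db == pop[q]]] + corr[q]
  }
  attr(out, "anchored") <- anchored
  flips <- !is.na(betamap) & !is.na(out) & sign(betamap) != sign(out)
  attr(out, "sign_flips") <- sum(flips)
  out
}
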