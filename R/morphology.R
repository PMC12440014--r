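## Small 3-D image utilities: separable Gaussian smoothing, 6-connected
## binary dilation, 26-connected component labelling, nearest-point
## distances. All operate on plain 3-D arrays in voxel units.

#' Gaussian smoothing of a 3-D array
#'
#' Separable Gaussian convolution with zero padding and mask
#' renormalisation, so values near the array edge are a weighted average of
#' available voxels only (no edge darkening).
#'
#' @param x 3-D numeric array.
#' @param sigma_vox Gaussian standard deviation per axis, in voxels.
#'   Recycled to length 3.
#' @return Smoothed array of the same dimension.
#' @export
gaussian_smooth3d <- function(x, sigma_vox) {
  stopifnot(length(dim(x)) == 3)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  num <- x
  den <- array(1, dim(x))
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    num <- conv_axis(num, k, ax)
    den <- conv_axis(den, k, ax)
  }
  num / den
}

## 1-D convolution of a 3-D array along one axis, zero-padded.
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  ap[] <- out
  aperm(ap, order(perm))
}

#' Binary dilation with a 6-connected (face-adjacent) structuring element
#'
#' @param mask Logical 3-D array.
#' @param n_iter Number of dilation iterations.
#' @return Dilated logical array.
#' @export
dilate6 <- function(mask, n_iter = 1) {
  stopifnot(length(dim(mask)) == 3, n_iter >= 0)
  out <- mask
  for (i in seq_len(n_iter)) out <- out | shift_or6(out)
  out
}

shift_or6 <- function(m) {
  d <- dim(m)
  acc <- array(FALSE, d)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  if (d[1] > 1) {
    acc[-d[1], , ] <- acc[-d[1], , ] | m[-1, , ]
    acc[-1, , ] <- acc[-1, , ] | m[-d[1], , ]
  }
  if (d[2] > 1) {
    acc[, -d[2], ] <- acc[, -d[2], ] | m[, -1, ]
    acc[, -1, ] <- acc[, -1, ] | m[, -d[2], ]
  }
  if (d[3] > 1) {
    acc[, , -d[3]] <- acc[, , -d[3]] | m[, , -1]
    acc[, , -1] <- acc[, , -1] | m[, , -d[3]]
  }
  acc
}

#' Label 26-connected components of a 3-D logical mask
#'
#' Breadth-first flood fill over the 26-neighbourhood (faces, edges and
#' corners), the connectivity conventionally used for suprathreshold
#' clusters in volumetric fMRI statistics.
#'
#' @param mask Logical 3-D array.
#' @return Integer array of the same dimension: 0 outside the mask,
#'   components numbered from 1 in discovery order.
#' @export
label_components26 <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  coords <- arrayInd(idx, d)
  in_mask <- array(FALSE, d); in_mask[idx] <- TRUE
  current <- 0L
  for (s in seq_along(idx)) {
    start <- idx[s]
    if (lab[start] > 0L) next
    current <- current + 1L
    lab[start] <- current
    frontier <- coords[s, , drop = FALSE]
    while (nrow(frontier) > 0) {
      nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) break
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      keep <- in_mask[lin] & lab[lin] == 0L
      lin <- unique(lin[keep])
      if (length(lin) == 0) break
      lab[lin] <- current
      frontier <- arrayInd(lin, d)
    }
  }
  lab
}

## Nearest Euclidean distance (voxel units) from each row of `from` to the
## point set `to`; both are n x 3 coordinate matrices. Chunked to bound
## memory.
nearest_dist <- function(from, to, chunk = 4096L) {
  stopifnot(ncol(from) == 3, ncol(to) == 3, nrow(to) > 0)
  n <- nrow(from)
  out <- numeric(n)
  to2 <- rowSums(to^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    f <- from[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(f^2), to2, "+") - 2 * f %*% t(to)
    out[lo:hi] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}
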