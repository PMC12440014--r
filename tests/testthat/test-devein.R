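test_that("ALFF measures eyes-closed fluctuation amplitude", {
  p <- paradigm()
  nv <- p$n_vols
  d <- c(2, 2, 1)
  mask <- array(TRUE, d)
  flat <- array(100, dim = c(d, nv))
  expect_equal(unname(compute_alff(flat, p, mask)[mask]), rep(0, 4))
  ## a sinusoid of amplitude A has within-period SD -> A/sqrt(2) when the
  ## period holds many cycles (long blocks, fast sampling)
  pl <- paradigm(block_len_s = 100, n_cycles = 2, tr_s = 1, n_vols = 404,
                 eeg_fs_hz = 100)
  t_mid <- volume_midpoints(pl)
  A <- 3
  sig <- array(rep(A * sin(2 * pi * 0.25 * t_mid), each = 4),
               dim = c(d, 404))
  a <- compute_alff(sig, pl, mask, shift_s = 0)
  expect_lt(max(abs(a[mask] - A / sqrt(2))) / (A / sqrt(2)), 0.02)
  ## eyes-open periods do not contribute
  open_vols <- condition_at(pl, t_mid) == "open"
  sig2 <- sig
  sig2[, , , open_vols] <- 1e6 * array(stats::rnorm(4 * sum(open_vols)),
                                       dim = c(d, sum(open_vols)))
  a2 <- compute_alff(sig2, pl, mask, shift_s = 0)
  expect_equal(a2[mask], a[mask])
  expect_error(compute_alff(flat[, , , 1:2, drop = FALSE],
                            paradigm(n_vols = 2, n_cycles = 1,
                                     block_len_s = 3, tr_s = 3.8)),
               "fewer than 2|no eyes-closed")
})

test_that("drainage weights normalise ALFF by its depth mean", {
  geom <- make_ribbon(10, 16, pi / 2, 4)
  dep <- compute_depths(geom)
  cols <- make_columns(geom, dep, 4, seed = 1)
  uni <- array(NA_real_, dim(geom$vol))
  uni[geom$vol == 3L] <- 7
  W <- drainage_weights(uni, cols, dep, lambda = 0.25)
  expect_equal(unname(c(W$v)), rep(0.25, 24))
  W0 <- drainage_weights(uni, cols, dep, lambda = 0)
  expect_true(all(W0$v == 0))
})

test_that("forward accumulation and deconvolution are exact inverses", {
  b <- c(-1, -1, -1, -1, -1, -1)
  m <- forward_drain(b, rep(0.25, 6))
  expect_equal(m, c(-1, -1.25, -1.5, -1.75, -2, -2.25))
  expect_equal(forward_drain(b, rep(0, 6)), b)
  expect_equal(spatial_deconvolve(m, rep(0, 6)), m)
  set.seed(42)
  for (i in 1:50) {
    bb <- stats::rnorm(6)
    vv <- stats::runif(6, 0, 0.6)
    expect_lt(max(abs(spatial_deconvolve(forward_drain(bb, vv), vv) - bb)),
              1e-12)
    expect_lt(max(abs(forward_drain(spatial_deconvolve(bb, vv), vv) - bb)),
              1e-12)
  }
  ## matrix form agrees with column-wise application
  B <- matrix(stats::rnorm(12), 6, 2)
  v <- stats::runif(6, 0, 0.5)
  expect_equal(forward_drain(B, v),
               cbind(forward_drain(B[, 1], v), forward_drain(B[, 2], v)))
  ## deveining can flip the sign of a small superficial value sitting on a
  ## large same-sign deeper sum
  m2 <- c(-2, -2, -2, -2, -2, -0.1)
  expect_lt(m2[6], 0)
  expect_gt(spatial_deconvolve(m2, rep(0.25, 6))[6], 0)
})

test_that("deveining a noise-free subject recovers the ground truth", {
  cfg <- noisefree_config("n")
  sub <- prepare_geometry(cfg, seed = 21)
  sim <- simulate_subject(cfg, sub, seed = 22)
  fit <- fit_glm(sim$bold, glm_design(sim$drive, sim$motion), sub$gm_mask)
  ## lambda = 0 leaves the map untouched
  same <- devein_volume(fit$beta, sub$columns, sub$depths,
                        weights = rep(0, 6))
  expect_equal(c(same), c(fit$beta))
  ## with the true weights the depth profile equals the implanted truth
  dev <- devein_volume(fit$beta, sub$columns, sub$depths,
                       weights = sim$drain_v)
  prof <- sapply(1:6, function(d)
    mean(dev[!is.na(dev) & sub$depths$bin == d]))
  expect_lt(max(abs(prof / sim$local_beta - 1)), 1e-6)
})

test_that("columns missing the deepest depth are anchored and flagged", {
  geom <- slab_geometry(gm_thick = 6, nx = 4, ny = 4)
  dep <- compute_depths(geom)
  cols <- make_columns(geom, dep, 2, seed = 1)
  beta <- array(NA_real_, dim(geom$vol))
  beta[geom$vol == 3L] <- -1
  ## blank out depth-1 voxels of column 1 (as if unfitted)
  beta[cols$id == 1L & dep$bin == 1L] <- NA
  dev <- devein_volume(beta, cols, dep, weights = rep(0.25, 6))
  expect_equal(attr(dev, "anchored"), 1L)
})
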