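test_that("ribbon geometry matches the brute-force lattice count", {
  geom <- make_ribbon(10, 16, pi / 2, 4)
  expect_true(all(unique(c(geom$vol)) %in% 0:3))
  ## brute-force lattice count of the quadrant annulus
  r <- geometry_radius(geom)
  th <- geometry_angle(geom)
  expected <- sum(r >= 10 & r <= 16 & th >= -1e-9 & th <= pi / 2 + 1e-9)
  expect_equal(sum(geom$vol == 3L), expected)
  ## and within 10% of the continuum area (pi/4)(16^2-10^2)*4
  expect_lt(abs(sum(geom$vol == 3L) - pi / 4 * (256 - 100) * 4),
            0.1 * pi / 4 * (256 - 100) * 4)
  expect_error(make_ribbon(10, 10), "invalid geometry")
})

test_that("veins are deterministic and perivascular shells are Chebyshev", {
  geom <- make_ribbon()
  v0 <- make_veins(geom, n_veins = 0)
  expect_false(any(v0$vein) || any(v0$peri))
  v1 <- make_veins(geom, 3, 2, seed = 7)
  v2 <- make_veins(geom, 3, 2, seed = 7)
  expect_identical(v1$vein, v2$vein)
  expect_identical(v1$peri, v2$peri)
  expect_false(any(v1$vein & v1$peri))
  ## every perivascular voxel within Chebyshev distance 2 of a vein voxel
  vc <- arrayInd(which(v1$vein), dim(v1$vein))
  pc <- arrayInd(which(v1$peri), dim(v1$peri))
  cheb <- apply(pc, 1, function(q)
    min(apply(abs(sweep(vc, 2, q)), 1, max)))
  expect_true(all(cheb <= 2))
  expect_true(all(cheb >= 1))
})

test_that("alpha timecourse reproduces the block modulation", {
  p <- paradigm()
  a0 <- make_alpha_timecourse(p, modulation_depth = 0, noise_sd = 0)
  expect_equal(stats::sd(a0$values), 0)
  expect_length(a0$values, round(run_duration(p) * p$eeg_fs_hz))
  a1 <- make_alpha_timecourse(p, modulation_depth = 1, noise_sd = 0)
  t_s <- (seq_along(a1$values) - 0.5) / p$eeg_fs_hz
  closed <- condition_at(p, t_s) == "closed"
  expect_equal(mean(a1$values[closed]) / mean(a1$values[!closed]), 2)
  ## the series spans four open+closed cycles of 30 s each
  cyc <- cycle_at(p, t_s)
  expect_equal(max(cyc, na.rm = TRUE), 4L)
  expect_equal(sum(!is.na(cyc)) / p$eeg_fs_hz, 240)
})

test_that("noise-free, drainage-free BOLD yields exact GLM recovery", {
  cfg <- noisefree_config("flat")
  cfg$noise$drain_shape <- rep(0, 6)    # no drainage at all
  sub <- prepare_geometry(cfg, seed = 3)
  sim <- simulate_subject(cfg, sub, seed = 4)
  fit <- fit_glm(sim$bold, glm_design(sim$drive, sim$motion), sub$gm_mask)
  for (d in 1:6) {
    bd <- fit$beta[!is.na(fit$beta) & sub$depths$bin == d]
    expect_lt(max(abs(bd - sim$local_beta[d])) / abs(sim$local_beta[d]),
              1e-6)
  }
  expect_true(all(fit$beta[!is.na(fit$beta)] < 0))  # negative coupling
})

test_that("drainage accumulates deeper signal toward the surface", {
  cfg <- noisefree_config("n")
  sub <- prepare_geometry(cfg, seed = 5)
  sim <- simulate_subject(cfg, sub, seed = 6)
  fit <- fit_glm(sim$bold, glm_design(sim$drive, sim$motion), sub$gm_mask)
  for (id in sort(unique(stats::na.omit(c(sub$columns$id))))) {
    sel <- !is.na(sub$columns$id) & sub$columns$id == id & !is.na(fit$beta)
    b1 <- fit$beta[sel & sub$depths$bin == 1]
    b6 <- fit$beta[sel & sub$depths$bin == 6]
    if (length(b1) && length(b6))
      expect_gt(abs(mean(b6)), abs(mean(b1)))
  }
  ## the forward model agrees with forward_drain applied to the truth
  expect_equal(sim$measured_beta,
               forward_drain(sim$local_beta, sim$drain_v))
})

test_that("subject simulation is bit-reproducible under a fixed seed", {
  cfg <- default_config(geometry = list(inner = 8, outer = 13, arc = pi / 2,
                                        thickness = 3, voxel_mm = 0.8),
                        n_columns = 4)
  sub <- prepare_geometry(cfg, seed = 11)
  s1 <- simulate_subject(cfg, sub, seed = 12)
  s2 <- simulate_subject(cfg, sub, seed = 12)
  expect_identical(s1$bold, s2$bold)
  expect_identical(s1$alpha$values, s2$alpha$values)
  expect_identical(s1$motion, s2$motion)
  s3 <- simulate_subject(cfg, sub, seed = 13)
  expect_false(identical(s1$bold, s3$bold))
})
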