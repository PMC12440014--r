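test_that("alpha band-pass keeps 10 Hz and rejects out-of-band tones", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  trim <- seq(2 * fs, length(t) - 2 * fs)
  amp_out <- function(f_hz) {
    y <- bandpass_alpha(sin(2 * pi * f_hz * t), fs)
    sqrt(2) * stats::sd(y[trim])
  }
  expect_lt(abs(amp_out(10) - 1), 0.01)
  expect_lt(amp_out(2), 10^(-40 / 20))   # >= 40 dB down
  expect_lt(amp_out(4), 10^(-40 / 20))
  expect_lt(amp_out(20), 10^(-40 / 20))
  expect_error(bandpass_alpha(sin(t), 20), "too low")
})

test_that("analytic-signal envelope recovers amplitude and modulator", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  trim <- seq(fs, length(t) - fs)
  env <- power_envelope(2 * sin(2 * pi * 10 * t), fs)
  expect_lt(max(abs(env$values[trim] - 2)) / 2, 0.01)
  expect_equal(power_envelope(rep(0, 1000), fs)$values, rep(0, 1000))
  mod <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  env2 <- power_envelope(mod * sin(2 * pi * 10 * t), fs)
  rms <- sqrt(mean((env2$values[trim] - mod[trim])^2)) / mean(mod)
  expect_lt(rms, 0.02)
})

test_that("noisy segments are repaired from neighbours or condition mean", {
  fs <- 100
  p <- paradigm(eeg_fs_hz = fs)
  seg_len <- round(3.8 / 4 * fs)
  n_seg <- 12
  vals <- rep(seq_len(n_seg), each = seg_len)   # segment i holds value i
  cond <- rep(c("open", "closed"), each = 6)
  mk <- function(noisy) alpha_series(vals, fs, noisy = noisy)
  ## all clean: identity
  s <- repair_segments(mk(rep(FALSE, n_seg)), cond)
  expect_equal(s$values, as.numeric(vals))
  ## one noisy segment with 4 clean neighbours: mean of those neighbours
  noisy <- rep(FALSE, n_seg); noisy[5] <- TRUE
  s <- repair_segments(mk(noisy), cond)
  expect_equal(unique(s$values[(4 * seg_len + 1):(5 * seg_len)]),
               mean(c(3, 4, 6, 7)))
  ## only one clean neighbour available: run-level same-condition mean
  noisy <- rep(FALSE, n_seg); noisy[6:9] <- TRUE
  s <- repair_segments(mk(noisy), cond)
  ## segment 8 (closed) has neighbours 6,7,9 noisy and 10 clean, so the
  ## fallback is the mean over all clean eyes-closed segments (10,11,12)
  clean_closed <- c(10, 11, 12)
  expect_equal(unique(s$values[(7 * seg_len + 1):(8 * seg_len)]),
               mean(vals[rep(seq_len(n_seg), each = seg_len) %in%
                           clean_closed]))
  expect_error(repair_segments(mk(rep(TRUE, n_seg)), cond), "all segments")
})

test_that("regressor construction convolves and samples at midpoints", {
  p <- paradigm(eeg_fs_hz = 100)
  n <- round(run_duration(p) * 100)
  ## constant input: demeaning gives an all-zero regressor
  s0 <- alpha_series(rep(3, n), 100)
  expect_equal(make_regressor(s0, p)$values, rep(0, p$n_vols))
  ## impulse at t=0 traces the double-gamma at volume midpoints
  x <- numeric(n); x[1] <- 1
  r <- make_regressor(alpha_series(x, 100), p)$values
  h <- hrf_double_gamma(100)
  ## within the kernel support (first 8 volumes, midpoints < 32 s) the
  ## trace is an affine image of the closed-form double gamma
  idx <- round(volume_midpoints(p)[1:8] * 100)
  expect_gt(stats::cor(r[1:8], h[idx]), 0.999)
  ## linearity in the input after demeaning
  s1 <- alpha_series(stats::rnorm(n)^2, 100)
  s2 <- alpha_series(stats::rnorm(n)^2, 100)
  s12 <- alpha_series(s1$values + 2 * s2$values, 100)
  expect_equal(make_regressor(s12, p)$values,
               make_regressor(s1, p)$values + 2 * make_regressor(s2, p)$values,
               tolerance = 1e-10)
  expect_error(make_regressor(alpha_series(rep(1, 10), 100), p), "shorter")
})

test_that("boxcar follows the midpoint rule", {
  p <- paradigm()
  b <- make_boxcar(p)$values
  ## brute force: midpoint (k-0.5)*3.8 within an eyes-closed block
  expected <- as.numeric(vapply(seq_len(p$n_vols), function(k) {
    t <- (k - 0.5) * 3.8
    blk <- min(floor(t / 30), 7)
    blk %% 2 == 1
  }, logical(1)))
  expect_equal(b, expected)
  expect_equal(sum(b[1:8]), 0)   # first ~8 volumes are eyes-open
  expect_lt(abs(sum(b) - p$n_vols / 2), 8)  # roughly balanced blocks
  ## with the condition order reversed the early volumes are eyes-closed
  p_rev <- paradigm(order = c("closed", "open"))
  expect_equal(make_boxcar(p_rev)$values[1:8], rep(1, 8))
})

test_that("orthogonalization removes the projection exactly", {
  p <- paradigm()
  box <- make_boxcar(p)
  set.seed(1)
  reg <- structure(list(values = stats::rnorm(p$n_vols), kind = "alpha"),
                   class = "regressor")
  o <- orthogonalize(reg, box)
  bd <- box$values - mean(box$values)
  expect_lt(abs(sum(o$values * bd)),
            1e-10 * sqrt(sum(reg$values^2)) * sqrt(sum(box$values^2)))
  ## self-orthogonalization annihilates; idempotence
  expect_lt(max(abs(orthogonalize(box, box)$values)), 1e-12)
  expect_equal(orthogonalize(o, box)$values, o$values, tolerance = 1e-10)
  expect_error(orthogonalize(reg, rep(1, p$n_vols)), "constant")
})

test_that("paired condition comparison detects the alpha modulation", {
  p <- paradigm()
  a0 <- make_alpha_timecourse(p, modulation_depth = 0, noise_sd = 0)
  r0 <- compare_conditions(a0, p)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  ## simulated modulation with modest noise: significant, closed > open
  hits <- 0
  for (s in 1:5) {
    a <- make_alpha_timecourse(p, modulation_depth = 0.5, noise_sd = 0.1,
                               seed = s)
    r <- compare_conditions(a, p)
    hits <- hits + (r$p_value < 0.05 && r$mean_closed > r$mean_open)
  }
  expect_gte(hits, 4)
  expect_error(compare_conditions(a0, paradigm(n_cycles = 1, n_vols = 17)),
               "at least 2")
})
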