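make_toy_maps <- function(vals, depths_of, cols_of, d = c(4, 4, 2)) {
  beta <- array(NA_real_, d)
  dep <- list(bin = array(NA_integer_, d), n_depths = 6L)
  cols <- list(id = array(NA_integer_, d))
  idx <- seq_along(vals)
  beta[idx] <- vals
  dep$bin[idx] <- depths_of
  cols$id[idx] <- cols_of
  list(beta = beta, dep = dep, cols = cols,
       retained = !is.na(beta))
}

test_that("global-mean profile pools negative voxels per depth", {
  m <- make_toy_maps(c(-2, -4, 3), c(2, 2, 3), c(1, 1, 1))
  p <- global_mean_profile(m$beta, m$cols, m$dep, m$retained, 1)
  expect_equal(p$mean[2], -3)
  expect_equal(p$sem[2], 1)
  expect_equal(p$n[3], 0L)        # positive voxel dropped
  expect_true(is.na(p$mean[3]))
  allpos <- make_toy_maps(c(1, 2), c(1, 2), c(1, 1))
  pp <- global_mean_profile(allpos$beta, allpos$cols, allpos$dep,
                            allpos$retained, 1)
  expect_true(all(is.na(pp$mean)))
})

test_that("column-profile mean weights columns, not voxels", {
  ## column 1 has three voxels at depth 3 (-1), column 2 has one (-5)
  m <- make_toy_maps(c(-1, -1, -1, -5), c(3, 3, 3, 3), c(1, 1, 1, 2))
  pc <- column_profile_mean(m$beta, m$cols, m$dep, m$retained, 1:2)
  expect_equal(pc$mean[3], -3)    # unweighted mean of -1 and -5
  pg <- global_mean_profile(m$beta, m$cols, m$dep, m$retained, 1:2)
  expect_equal(pg$mean[3], -2)    # voxel-weighted
  ## single column: the two schemes coincide
  one <- make_toy_maps(c(-2, -4, -6), c(1, 2, 3), c(1, 1, 1))
  expect_equal(column_profile_mean(one$beta, one$cols, one$dep,
                                   one$retained, 1)$mean,
               global_mean_profile(one$beta, one$cols, one$dep,
                                   one$retained, 1)$mean)
})

test_that("range normalization preserves shape and sign", {
  expect_equal(range_normalize(c(-2, -4)), c(-1, -2))
  expect_equal(range_normalize(c(-0.25, 0.75)), c(-0.25, 0.75))
  v <- c(-1, -3, -2, -5, -4, -2)
  expect_equal(range_normalize(7 * v), range_normalize(v))
  expect_equal(range_normalize(v, shift = TRUE),
               (v - min(v)) / (max(v) - min(v)))
  expect_error(range_normalize(rep(-1, 6)), "zero range")
})

test_that("ROI averaging weights by column counts", {
  expect_equal(roi_weighted_average(list(rep(-1, 6), rep(-3, 6)),
                                    c(10, 10)),
               rep(-2, 6))
  expect_equal(roi_weighted_average(list(rep(-1, 6), rep(-4, 6)),
                                    c(100, 50)),
               rep(-2, 6))
  expect_error(roi_weighted_average(list(rep(-1, 6)), 0), "zero")
})

test_that("one-way rm-ANOVA matches the sums-of-squares oracle", {
  const <- matrix(5, 4, 3)
  r0 <- rm_anova_1way(const)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:8, 1); k <- sample(3:6, 1)
    M <- matrix(stats::rnorm(n * k), n, k) +
      outer(stats::rnorm(n), stats::rnorm(k))
    got <- rm_anova_1way(M)
    want <- rm1_oracle(M)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df1, want$df1)
    expect_equal(got$df2, want$df2)
  }
  expect_error(rm_anova_1way(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("two-way rm-ANOVA matches the oracle and handles flat factors", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(3:6, 1); a <- sample(2:4, 1); b <- sample(2:4, 1)
    A <- array(stats::rnorm(n * a * b), c(n, a, b))
    got <- rm_anova_2way(A)
    want <- rm2_oracle(A)
    for (r in 1:3) {
      expect_equal(got$F[r], unname(want[r, "F"]), tolerance = 1e-10)
      expect_equal(got$p[r], unname(want[r, "p"]), tolerance = 1e-10)
    }
  }
  ## constant in the second factor: its main effect and interaction vanish
  base <- matrix(stats::rnorm(12), 4, 3)
  Aflat <- array(rep(base, 2), c(4, 3, 2))
  gf <- rm_anova_2way(Aflat)
  expect_equal(gf["B", "F"], 0)
  expect_equal(gf["A:B", "F"], 0)
  expect_equal(gf["B", "p"], 1)
})

test_that("post-hoc paired t-tests apply Bonferroni arithmetic", {
  same <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  ph <- posthoc_paired_t(same + 0)    # constant differences
  expect_true(all(is.infinite(ph$t)))
  ident <- matrix(rep(1:4, 3), 4, 3)
  ph0 <- posthoc_paired_t(ident)
  expect_true(all(ph0$t == 0))
  expect_true(all(ph0$p_adj == 1))
  ## p_raw 0.004 with family 15 -> 0.06; family defaults to the pair count
  set.seed(9)
  M <- matrix(stats::rnorm(24), 8, 3)
  ph1 <- posthoc_paired_t(M)
  expect_equal(ph1$p_adj, pmin(1, ph1$p_raw * 3))
  ph15 <- posthoc_paired_t(M, family_size = 15)
  expect_equal(ph15$p_adj, pmin(1, ph15$p_raw * 15))
  expect_equal(min(1, 0.004 * 15), 0.06)
  expect_error(posthoc_paired_t(M[1, , drop = FALSE]), ">= 2 subjects")
})
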