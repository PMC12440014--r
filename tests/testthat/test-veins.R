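test_that("unsharp-mask vein detection finds dark lines", {
  d <- c(20, 20, 4)
  roi <- array(TRUE, d)
  uni <- array(100, d)
  expect_equal(sum(make_vein_mask(uni, roi, cutoff_pct = 5)), 0)
  ## a dark line with a 40% signal drop is flagged almost completely
  img <- array(100, d)
  line <- cbind(5:16, 9, 2)
  img[line] <- 60
  vm <- make_vein_mask(img, roi, fwhm_mm = 2, cutoff_pct = 5,
                       voxdim_mm = 0.8)
  expect_gte(mean(vm[line]), 0.9)
  expect_error(make_vein_mask(uni, array(FALSE, d)), "empty ROI")
})

test_that("ring mask is a 6-connected dilation shell", {
  d <- c(11, 11, 11)
  vein <- array(FALSE, d)
  expect_equal(sum(make_ring_mask(vein, 4)$ring), 0)
  vein[6, 6, 6] <- TRUE
  rm4 <- make_ring_mask(vein, 4)
  ## brute force: Manhattan ball of radius 4 minus the centre
  co <- arrayInd(seq_len(prod(d)), d)
  manh <- rowSums(abs(sweep(co, 2, c(6, 6, 6))))
  expect_equal(which(rm4$ring), which(manh >= 1 & manh <= 4))
  expect_false(any(rm4$ring & rm4$vein))
})

test_that("profile gradient is the least-squares slope over depths", {
  expect_equal(profile_gradient(rep(2, 6)), 0)
  expect_equal(profile_gradient(-(1:6)), -1)
  expect_equal(profile_gradient(c(NA, -2, NA, -4, NA, NA)), -1)
  expect_true(is.na(profile_gradient(c(-1, NA, NA, NA, NA, NA))))
})

test_that("gradient-change classification is a 25/50/25 rank split", {
  tab <- data.frame(column = 1:8, slope_unc = 0, slope_dev = 1:8)
  cl <- classify_gradient_change(tab)
  expect_equal(as.character(cl$class[cl$column %in% 1:2]),
               rep("lower25", 2))
  expect_equal(as.character(cl$class[cl$column %in% 3:6]),
               rep("middle50", 4))
  expect_equal(as.character(cl$class[cl$column %in% 7:8]),
               rep("upper25", 2))
  ## ties resolve deterministically by rank order
  tie <- data.frame(column = 1:8, slope_unc = 0, slope_dev = 1)
  cl2 <- classify_gradient_change(tie)
  expect_equal(table(cl2$class)[["lower25"]], 2L)
  expect_equal(table(cl2$class)[["upper25"]], 2L)
  ## permutation equivariance: relabelling rows permutes classes with them
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  cl3 <- classify_gradient_change(tab[perm, ])
  m <- merge(cl[, c("column", "class")], cl3[, c("column", "class")],
             by = "column")
  expect_equal(as.character(m$class.x), as.character(m$class.y))
  expect_error(classify_gradient_change(tab[1:3, ]), "at least 4")
})

test_that("ring overlap percentages and top-column exclusion", {
  d <- c(6, 6, 1)
  cols <- list(id = array(rep(1:4, each = 9), d), n_columns = 4L)
  ring <- array(FALSE, d)
  retained <- array(TRUE, d)
  tab <- data.frame(column = 1:4, slope_unc = 0, slope_dev = c(1, 2, 3, 4))
  cl <- classify_gradient_change(tab)
  ## empty ring: all overlaps zero
  expect_equal(unname(class_ring_overlap(cl, cols, ring, retained)),
               c(0, 0, 0))
  ## put 3 of column 4's 9 voxels in the ring
  ring[which(cols$id == 4L)[1:3]] <- TRUE
  ov <- class_ring_overlap(cl, cols, ring, retained)
  expect_equal(unname(ov["upper25"]), 100 * 3 / 9)
  expect_equal(unname(ov["lower25"]), 0)
  expect_equal(exclude_top_columns(1:4, cl), 1:3)
  expect_equal(exclude_top_columns(1:4, NULL), 1:4)
})

test_that("gradient change correlates with perivascular load", {
  ## columns containing contaminated tissue should rank high in
  ## deveining-induced gradient change
  cfg <- default_config(n_columns = 10,
                        veins = list(n_veins = 2, ring_width_vox = 1))
  rho <- c()
  for (s in 1:3) {
    sub <- prepare_geometry(cfg, seed = 100 + s)
    sim <- simulate_subject(cfg, sub, seed = 200 + s)
    res <- run_subject(sim, cfg, sub, seed = 300 + s)
    k <- res$kinds$alpha
    if (is.null(k$classes)) next
    peri_frac <- vapply(k$classes$column, function(id)
      mean(sim$veins$peri[sub$gm_mask & sub$columns$id == id]), 0)
    rho <- c(rho, stats::cor(k$classes$delta, peri_frac,
                             method = "spearman"))
  }
  expect_gt(mean(rho), 0.3)
})
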