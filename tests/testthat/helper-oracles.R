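## Independent brute-force oracles used against the package implementations.

## one-way repeated-measures ANOVA from raw sums of squares
rm1_oracle <- function(M) {
  n <- nrow(M); k <- ncol(M)
  gm <- mean(M)
  ss_lev <- n * sum((colMeans(M) - gm)^2)
  ss_subj <- k * sum((rowMeans(M) - gm)^2)
  ss_tot <- sum((M - gm)^2)
  ss_err <- ss_tot - ss_lev - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_lev / df1) / (ss_err / df2)
  list(F = Fv, df1 = df1, df2 = df2, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

## two-way (both factors within subject), each effect against its own
## subject-interaction term
rm2_oracle <- function(A) {            # subjects x a x b
  n <- dim(A)[1]; a <- dim(A)[2]; b <- dim(A)[3]
  gm <- mean(A)
  mS <- apply(A, 1, mean); mA <- apply(A, 2, mean); mB <- apply(A, 3, mean)
  mSA <- apply(A, c(1, 2), mean); mSB <- apply(A, c(1, 3), mean)
  mAB <- apply(A, c(2, 3), mean)
  ss <- function(x) sum(x^2)
  ssA <- n * b * ss(mA - gm)
  ssB <- n * a * ss(mB - gm)
  ssS <- a * b * ss(mS - gm)
  ssSA <- b * ss(sweep(sweep(mSA, 1, mS), 2, mA) + gm)
  ssSB <- a * ss(sweep(sweep(mSB, 1, mS), 2, mB) + gm)
  ssAB <- n * ss(sweep(sweep(mAB, 1, mA), 2, mB) + gm)
  ssT <- ss(A - gm)
  ssSAB <- ssT - ssA - ssB - ssS - ssSA - ssSB - ssAB
  eff <- function(ssx, dfx, sse, dfe) {
    Fv <- (ssx / dfx) / (sse / dfe)
    c(F = Fv, df1 = dfx, df2 = dfe,
      p = pf(Fv, dfx, dfe, lower.tail = FALSE))
  }
  rbind(A = eff(ssA, a - 1, ssSA, (a - 1) * (n - 1)),
        B = eff(ssB, b - 1, ssSB, (b - 1) * (n - 1)),
        `A:B` = eff(ssAB, (a - 1) * (b - 1), ssSAB,
                    (a - 1) * (b - 1) * (n - 1)))
}

## quick flat-slab labelled geometry: WM below, GM ribbon, CSF above
slab_geometry <- function(gm_thick = 12, nx = 8, ny = 8) {
  nz <- gm_thick + 6
  vol <- array(0L, c(nx, ny, nz))
  vol[, , 1:3] <- 2L
  vol[, , 3 + seq_len(gm_thick)] <- 3L
  vol[, , (3 + gm_thick + 1):nz] <- 1L
  structure(list(vol = vol, voxdim = rep(0.8, 3), inner = NA, outer = NA,
                 arc = NA, center = c(1, 1),
                 labels = c(CSF = 1L, WM = 2L, GM = 3L)),
            class = "lam_geometry")
}

## tiny noise-free subject: no noise, no vasculature, no jitter
noisefree_config <- function(truth_shape = "n", thickness = 4) {
  nc <- noise_config(white_sd = 0, lf_sd = rep(0, 6), peri_gain = 0,
                     subject_jitter = 0, lambda_jitter = 0,
                     truth_jitter = 0, lf_jitter = 0)
  default_config(noise = nc, truth_shape = truth_shape,
                 veins = list(n_veins = 0, ring_width_vox = 1),
                 n_columns = 4,
                 geometry = list(inner = 10, outer = 16, arc = pi / 2,
                                 thickness = thickness, voxel_mm = 0.8))
}
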