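## Alpha-power regressor construction: band-pass filtering, Hilbert
## envelope, noisy-segment repair, double-gamma convolution, boxcar and
## orthogonalized regressors, and the eyes-open/closed power comparison.

#' Alpha power series container
#'
#' A nonnegative power value per EEG sample plus per-segment quality flags.
#' Segments are windows of TR/4 seconds (the unit in which EEG quality was
#' marked); a trailing partial segment inherits the last full segment's
#' flag.
#'
#' @param values Nonnegative numeric vector.
#' @param fs_hz Sampling rate in Hz.
#' @param noisy Optional logical vector, one flag per segment (TRUE =
#'   noisy). Defaults to all clean.
#' @param tr_s Volume TR used to define the segment length (seg_len =
#'   round(tr_s/4 * fs_hz) samples).
#' @return An `alpha_series` list with `values`, `fs_hz`, `seg_len`,
#'   `noisy`.
#' @export
alpha_series <- function(values, fs_hz, noisy = NULL, tr_s = 3.8) {
  stopifnot(fs_hz > 0, is.numeric(values))
  seg_len <- max(1L, round(tr_s / 4 * fs_hz))
  n_seg <- ceiling(length(values) / seg_len)
  if (is.null(noisy)) noisy <- rep(FALSE, n_seg)
  stopifnot(length(noisy) == n_seg)
  structure(list(values = as.numeric(values), fs_hz = fs_hz,
                 seg_len = as.integer(seg_len), noisy = noisy),
            class = "alpha_series")
}

n_segments <- function(series) length(series$noisy)

segment_index <- function(series) {
  pmin(((seq_along(series$values) - 1L) %/% series$seg_len) + 1L,
       n_segments(series))
}

#' Zero-phase alpha band-pass filter
#'
#' 4th-order Butterworth, 8-13 Hz, applied forward and backward
#' (`signal::filtfilt`) for zero phase distortion.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling rate; must exceed 26 Hz (twice the upper band
#'   edge).
#' @param band Passband edges in Hz.
#' @param order Butterworth order (of the analogue prototype).
#' @return Filtered signal, same length.
#' @export
bandpass_alpha <- function(x, fs_hz, band = c(8, 13), order = 4) {
  if (fs_hz <= 2 * band[2])
    stop("sampling rate ", fs_hz, " Hz too low for a ", band[2],
         " Hz band edge")
  bf <- signal::butter(order, band / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Instantaneous power envelope via the analytic signal
#'
#' Magnitude of the analytic signal (FFT half-spectrum method): for a
#' demeaned narrow-band input this is the instantaneous amplitude envelope.
#'
#' @param x Demeaned, band-passed numeric signal.
#' @param fs_hz Sampling rate.
#' @param tr_s Volume TR used for segmenting the resulting series.
#' @return An [alpha_series()] with the (nonnegative) envelope.
#' @export
power_envelope <- function(x, fs_hz, tr_s = 3.8) {
  n <- length(x)
  stopifnot(n > 1)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  alpha_series(env, fs_hz, tr_s = tr_s)
}

#' Repair noisy segments of an alpha power series
#'
#' Each noisy segment is replaced by the mean over clean segments among its
#' four nearest neighbours (two either side) when at least two of those are
#' clean; otherwise by the mean over all clean segments of the same
#' condition in the run.
#'
#' @param series An [alpha_series()] with `noisy` flags set.
#' @param condition_labels Character vector, one condition per segment.
#' @return Repaired [alpha_series()] (flags preserved).
#' @export
repair_segments <- function(series, condition_labels) {
  ns <- n_segments(series)
  stopifnot(length(condition_labels) == ns)
  if (all(series$noisy)) stop("all segments are noisy; nothing to average")
  if (!any(series$noisy)) return(series)
  seg_of <- segment_index(series)
  vals <- series$values
  seg_mean <- function(i) mean(series$values[seg_of == i])
  clean <- !series$noisy
  for (i in which(series$noisy)) {
    nb <- setdiff(intersect((i - 2):(i + 2), seq_len(ns)), i)
    nb_clean <- nb[clean[nb]]
    if (length(nb_clean) >= 2) {
      repl <- mean(series$values[seg_of %in% nb_clean])
    } else {
      same <- which(clean & condition_labels == condition_labels[i])
      if (length(same) == 0)
        stop("no clean segment of condition '", condition_labels[i],
             "' available for fallback repair")
      repl <- mean(series$values[seg_of %in% same])
    }
    vals[seg_of == i] <- repl
  }
  out <- series
  out$values <- vals
  out
}

#' Double-gamma haemodynamic response kernel
#'
#' Canonical double-gamma HRF: a positive gamma peaking near `peak_s` minus
#' an undershoot gamma near `under_s`, each parameterised by its mean delay
#' and dispersion (gamma SD), normalised to unit peak.
#'
#' @param fs_hz Sampling rate of the kernel.
#' @param duration_s Kernel support in seconds.
#' @param peak_s,under_s Delays of response and undershoot (gamma means).
#' @param disp_peak_s,disp_under_s Dispersions (gamma SDs).
#' @param ratio Undershoot amplitude relative to the peak gamma.
#' @return Numeric kernel sampled at `fs_hz`.
#' @export
hrf_double_gamma <- function(fs_hz, duration_s = 32, peak_s = 6,
                             under_s = 16, disp_peak_s = 3,
                             disp_under_s = 3, ratio = 1 / 6) {
  t <- seq(0, duration_s, by = 1 / fs_hz)
  g <- function(delay, disp)
    stats::dgamma(t, shape = (delay / disp)^2, rate = delay / disp^2)
  h <- g(peak_s, disp_peak_s) - ratio * g(under_s, disp_under_s)
  h / max(h)
}

#' Build a haemodynamic regressor from an alpha power series
#'
#' Demeans the full-run series, convolves it (causally) with the
#' double-gamma HRF sampled at the EEG rate, and samples the result at the
#' temporal midpoint of each fMRI volume.
#'
#' @param series A repaired [alpha_series()] covering the full run.
#' @param p A [paradigm()].
#' @param hrf_params Optional list of [hrf_double_gamma()] arguments.
#' @param sample_at "midpoint" (default) or "onset" volume sampling.
#' @return A `regressor` list: `values` (length `n_vols`), `kind`.
#' @export
make_regressor <- function(series, p, hrf_params = list(),
                           sample_at = c("midpoint", "onset")) {
  sample_at <- match.arg(sample_at)
  fs <- series$fs_hz
  n <- length(series$values)
  n_need <- floor(run_duration(p) * fs)
  if (n < n_need)
    stop("alpha series (", n, " samples) shorter than the run (",
         n_need, " samples)")
  x <- series$values - mean(series$values)
  h <- do.call(hrf_double_gamma, c(list(fs_hz = fs), hrf_params))
  y <- causal_convolve(x, h) / fs
  t_s <- if (sample_at == "midpoint") volume_midpoints(p)
         else (seq_len(p$n_vols) - 1) * p$tr_s
  idx <- pmin(pmax(round(t_s * fs), 1L), n)
  structure(list(values = y[idx], kind = "alpha"), class = "regressor")
}

## linear causal convolution, first length(x) samples
causal_convolve <- function(x, h) {
  n <- length(x)
  m <- length(h)
  nf <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, numeric(nf - n)))
  H <- stats::fft(c(h, numeric(nf - m)))
  Re(stats::fft(X * H, inverse = TRUE) / nf)[seq_len(n)]
}

#' Boxcar task regressor
#'
#' 1 for volumes whose temporal midpoint falls in an eyes-closed period,
#' 0 otherwise.
#'
#' @param p A [paradigm()].
#' @return A `regressor` with kind "boxcar".
#' @export
make_boxcar <- function(p) {
  vals <- as.numeric(condition_at(p, volume_midpoints(p)) == "closed")
  structure(list(values = vals, kind = "boxcar"), class = "regressor")
}

#' Orthogonalize a regressor against another
#'
#' Residual of the least-squares projection of `reg` onto `against` and a
#' constant, removing the mean task effect from the alpha regressor.
#'
#' @param reg,against `regressor` objects (or numeric vectors) of equal
#'   length.
#' @return A `regressor` with kind "alpha_orth".
#' @export
orthogonalize <- function(reg, against) {
  rv <- if (inherits(reg, "regressor")) reg$values else as.numeric(reg)
  av <- if (inherits(against, "regressor")) against$values
        else as.numeric(against)
  stopifnot(length(rv) == length(av))
  if (stats::sd(av) < 1e-12 * max(1, abs(mean(av))))
    stop("cannot orthogonalize against a constant regressor")
  X <- cbind(1, av)
  res <- rv - X %*% qr.solve(X, rv)
  structure(list(values = as.numeric(res), kind = "alpha_orth"),
            class = "regressor")
}

#' Paired comparison of alpha power between conditions
#'
#' Mean alpha power per eyes-open and eyes-closed block, paired by cycle,
#' compared with a two-sided paired Student's t-test.
#'
#' @param series An [alpha_series()].
#' @param p A [paradigm()].
#' @return A list: `t`, `p_value`, `mean_open`, `mean_closed`, `n_pairs`,
#'   and the per-cycle means.
#' @export
compare_conditions <- function(series, p) {
  if (p$n_cycles < 2) stop("need at least 2 cycles for a paired test")
  t_s <- (seq_along(series$values) - 0.5) / series$fs_hz
  cond <- condition_at(p, t_s)
  cyc <- cycle_at(p, t_s)
  keep <- !is.na(cyc)
  open <- tapply(series$values[keep & cond == "open"],
                 cyc[keep & cond == "open"], mean)
  closed <- tapply(series$values[keep & cond == "closed"],
                   cyc[keep & cond == "closed"], mean)
  if (length(open) < 2 || length(closed) < 2)
    stop("need at least 2 pairs for a paired test")
  dd <- closed - open
  if (stats::sd(dd) == 0) {
    tt <- list(statistic = if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf,
               p.value = if (mean(dd) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(closed, open, paired = TRUE)
  }
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_open = mean(open), mean_closed = mean(closed),
       n_pairs = length(open), open_by_cycle = open,
       closed_by_cycle = closed)
}
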