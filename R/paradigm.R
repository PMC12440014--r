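#' Eyes-open / eyes-closed block paradigm
#'
#' Describes the timing of the alternating eyes-open/eyes-closed task and of
#' the fMRI acquisition: 30 s blocks repeated over four cycles, sampled with
#' a volume TR of 3.8 s over 68 volumes, with the EEG-derived alpha power
#' series sampled at 500 Hz. Volumes acquired after the last block inherit
#' the final block's condition.
#'
#' @param block_len_s Block length in seconds.
#' @param n_cycles Number of open+closed cycles.
#' @param order Condition order within a cycle; first element is the
#'   starting condition.
#' @param tr_s Volume repetition time in seconds.
#' @param n_vols Number of fMRI volumes per run.
#' @param eeg_fs_hz Sampling rate of the alpha power series in Hz.
#' @return An object of class `paradigm`.
#' @export
paradigm <- function(block_len_s = 30, n_cycles = 4,
                     order = c("open", "closed"),
                     tr_s = 3.8, n_vols = 68, eeg_fs_hz = 500) {
  stopifnot(n_vols >= 1, tr_s > 0, block_len_s > 0, n_cycles >= 1,
            eeg_fs_hz > 0)
  order <- match.arg(order, c("open", "closed"), several.ok = TRUE)
  if (length(order) != 2 || anyDuplicated(order))
    stop("`order` must be a permutation of c(\"open\", \"closed\")")
  if (block_len_s * 2 * n_cycles > n_vols * tr_s + tr_s)
    stop("paradigm longer than the fMRI run: ",
         block_len_s * 2 * n_cycles, " s of blocks vs ",
         n_vols * tr_s, " s of volumes")
  structure(list(block_len_s = block_len_s, n_cycles = n_cycles,
                 order = order, tr_s = tr_s, n_vols = n_vols,
                 eeg_fs_hz = eeg_fs_hz),
            class = "paradigm")
}

#' Condition at given times
#'
#' @param p A [paradigm()].
#' @param t_s Numeric vector of times in seconds from run start.
#' @return Character vector, "open" or "closed" per time point. Times past
#'   the end of the last block take the last block's condition.
#' @export
condition_at <- function(p, t_s) {
  blk <- floor(t_s / p$block_len_s)
  blk <- pmin(pmax(blk, 0), 2 * p$n_cycles - 1)
  p$order[(blk %% 2) + 1]
}

#' Temporal midpoints of the fMRI volumes
#' @param p A [paradigm()].
#' @return Numeric vector of length `n_vols`, in seconds.
#' @export
volume_midpoints <- function(p) (seq_len(p$n_vols) - 0.5) * p$tr_s

#' Total run duration in seconds
#' @param p A [paradigm()].
#' @export
run_duration <- function(p) p$n_vols * p$tr_s

## Index of the cycle (1-based) each time belongs to; NA past the blocks.
cycle_at <- function(p, t_s) {
  cyc <- floor(t_s / (2 * p$block_len_s)) + 1
  cyc[t_s >= 2 * p$block_len_s * p$n_cycles | t_s < 0] <- NA_integer_
  as.integer(cyc)
}
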