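#' Analysis-window schedule
#'
#' The set of window lengths the adaptive loop may use: 150 ms base, growing
#' in 50 ms steps to a 350 ms maximum (300, 400, 500, 600, 700 samples at
#' 2000 Hz). Every size must convert to a whole number of samples at `fs`.
#'
#' @param base_ms,step_ms,max_ms schedule in milliseconds.
#' @param fs sampling rate in Hz.
#' @return a `window_schedule`: list with `sizes_ms`, `lengths` (samples per
#'   size), `step_len` (anchor step in samples), `fs`.
#' @export
window_schedule <- function(base_ms = 150, step_ms = 50, max_ms = 350,
                            fs = 2000) {
  if (!(base_ms > 0 && step_ms > 0 && max_ms >= base_ms)) {
    stop("invalid schedule bounds")
  }
  sizes_ms <- seq(base_ms, max_ms, by = step_ms)
  lengths <- sizes_ms * fs / 1000
  step_len <- step_ms * fs / 1000
  if (any(abs(lengths - round(lengths)) > 1e-9) ||
      abs(step_len - round(step_len)) > 1e-9) {
    stop("window sizes must be whole numbers of samples at fs")
  }
  structure(list(sizes_ms = sizes_ms, lengths = as.integer(round(lengths)),
                 step_len = as.integer(round(step_len)), fs = fs,
                 base_ms = base_ms, step_ms = step_ms, max_ms = max_ms),
            class = "window_schedule")
}

#' Band-pass filter a trial
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied independently
#' to each channel. The default 20-450 Hz band is the usual surface-EMG
#' analysis band: it removes motion artefact and baseline drift below 20 Hz
#' and out-of-band noise above 450 Hz.
#'
#' @param trial an `emg_trial`.
#' @param low_hz,high_hz band edges in Hz.
#' @param order Butterworth prototype order (the band-pass doubles it).
#' @return the trial with filtered `signal`, same shape.
#' @export
bandpass <- function(trial, low_hz = 20, high_hz = 450, order = 4) {
  stopifnot(inherits(trial, "emg_trial"))
  if (trial$fs <= 2 * high_hz) {
    stop("fs must exceed twice the upper band edge")
  }
  if (!all(is.finite(trial$signal))) stop("signal must be finite")
  bf <- signal::butter(order, c(low_hz, high_hz) / (trial$fs / 2),
                       type = "pass")
  out <- trial
  out$signal <- t(apply(trial$signal, 1,
                        function(x) signal::filtfilt(bf, x)))
  out
}

#' Band-pass filter every trial of a dataset
#' @param dataset an `emg_dataset`.
#' @inheritParams bandpass
#' @return the dataset with all trials filtered.
#' @export
bandpass_dataset <- function(dataset, low_hz = 20, high_hz = 450, order = 4) {
  stopifnot(inherits(dataset, "emg_dataset"))
  dataset$trials <- lapply(dataset$trials, bandpass, low_hz = low_hz,
                           high_hz = high_hz, order = order)
  dataset
}

#' Enumerate decision anchors of a trial
#'
#' An anchor is a window start position. Anchors begin at sample 1 and
#' advance by the 50 ms step; only starts that can host the full maximal
#' window (350 ms) are enumerated, so every threshold is compared over an
#' identical decision set. Count = floor((n - max_len) / step) + 1 when
#' non-negative, else 0.
#'
#' @param trial a (filtered) `emg_trial`.
#' @param schedule a `window_schedule`.
#' @return a data.frame with one row per anchor: `start` (1-based sample),
#'   `true_class`, `trial_id`, `subject_id`.
#' @export
enumerate_anchors <- function(trial, schedule) {
  stopifnot(inherits(trial, "emg_trial"), inherits(schedule, "window_schedule"))
  n <- ncol(trial$signal)
  max_len <- max(schedule$lengths)
  if (n < max_len) {
    return(data.frame(start = integer(0), true_class = integer(0),
                      trial_id = integer(0), subject_id = character(0)))
  }
  starts <- seq(1L, n - max_len + 1L, by = schedule$step_len)
  data.frame(start = starts, true_class = trial$class_id,
             trial_id = trial$trial_id, subject_id = trial$subject_id,
             stringsAsFactors = FALSE)
}

#' Materialize one window at a scheduled size
#'
#' Slices `[start, start + L)` from the trial, where `L` is the sample length
#' of `size_ms`. The start is fixed and the end moves forward in time, so
#' larger sizes at the same anchor are temporal extensions of smaller ones:
#' growing the window means waiting for more future samples, and the decision
#' latency equals the final window size.
#'
#' @param trial a (filtered) `emg_trial`.
#' @param start 1-based start sample.
#' @param size_ms one of the schedule's sizes.
#' @param schedule a `window_schedule`.
#' @return numeric matrix, n_channels x L.
#' @export
materialize <- function(trial, start, size_ms, schedule) {
  idx <- match(size_ms, schedule$sizes_ms)
  if (is.na(idx)) {
    stop(sprintf("size %s ms is not in the schedule {%s}", size_ms,
                 paste(schedule$sizes_ms, collapse = ", ")))
  }
  len <- schedule$lengths[idx]
  if (start < 1L || start + len - 1L > ncol(trial$signal)) {
    stop("window exceeds trial bounds")
  }
  trial$signal[, start:(start + len - 1L), drop = FALSE]
}
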