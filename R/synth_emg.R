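# Per-trial RNG substreams: a small integer hash of (master seed, class, trial)
# so that generation order is irrelevant. Kept below 2^31 - 1.
.substream_seed <- function(seed, class_id, trial_id) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  s <- (s * 69069 + 1234567) %% m
  s <- (s + (class_id + 1) * 1000003) %% m
  s <- (s + (trial_id + 1) * 7919) %% m
  as.integer(s)
}

#' Per-class, per-channel activation gains for the synthetic EMG generator
#'
#' Builds the amplitude pattern that distinguishes movement classes: one row
#' per class, one column per channel, entries are non-negative gains applied
#' to a band-limited noise carrier. Row 1 is the "rest" class and carries
#' zero gain (rest trials contain only the sensor noise floor). Active rows
#' scale linearly with `separability`, so the pairwise Euclidean distance
#' between class rows -- and hence downstream class separation -- grows
#' monotonically with it; at `separability = 0` every class collapses onto
#' rest and a classifier can only perform at chance.
#'
#' @param n_classes number of movement classes (>= 2), including rest.
#' @param n_channels number of EMG channels (>= 1).
#' @param separability non-negative scalar scaling between-class distance.
#' @param seed integer seed; the matrix is deterministic given it.
#' @return an object of class `activation_matrix`: the gain matrix with
#'   attributes `separability`, `seed` and `rest_class` (always 1).
#' @export
make_activation_matrix <- function(n_classes, n_channels, separability = 1,
                                   seed = 1L) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (n_channels < 1L) stop("n_channels must be >= 1")
  if (separability < 0) stop("separability must be >= 0")
  set.seed(.substream_seed(seed, 0L, 0L))
  # distinct per-class channel patterns around unit mean gain
  pat <- matrix(abs(stats::rnorm(n_classes * n_channels, mean = 1, sd = 0.45)),
                nrow = n_classes, ncol = n_channels)
  gains <- separability * pat
  gains[1L, ] <- 0 # rest: noise floor only
  structure(gains,
            class = c("activation_matrix", "matrix"),
            separability = separability, seed = seed, rest_class = 1L,
            unit_gain = mean(pat[-1L, ]))
}

#' Generate one synthetic EMG trial
#'
#' Each channel is an independent zero-mean Gaussian carrier, band-pass
#' filtered to 20-450 Hz (4th-order Butterworth, zero phase) and normalized
#' to unit RMS, scaled by the class/channel gain from `profile`, plus a white
#' sensor-noise floor. This emulates the stationary holding phase of a
#' constant, non-fatiguing contraction; it deliberately omits force drift,
#' posture change and electrode shift.
#'
#' @param profile an `activation_matrix`.
#' @param class_id class in `1..n_classes` (1 = rest).
#' @param duration_s trial length in seconds; must exceed 0.35 s so at least
#'   one maximal analysis window fits.
#' @param fs sampling rate in Hz; must exceed 900 Hz so the 20-450 Hz band is
#'   representable.
#' @param seed master seed; the trial substream is derived from
#'   (seed, class_id, trial_id).
#' @param trial_id integer trial index within the class.
#' @param subject_id subject label stored in the trial.
#' @param noise_floor standard deviation of the white sensor noise, on the
#'   same scale as the gains. The default, 5% of the mean active-channel gain
#'   of `profile` at unit separability (floored at 0.01), makes rest
#'   learnable but non-trivial and is independent of `separability`.
#' @param drift slow-amplitude-drift knob: the carrier amplitude ramps
#'   linearly from (1 - drift/2) to (1 + drift/2) over the trial. Off (0) by
#'   default, matching a constant, non-fatiguing hold.
#' @param gain_jitter SD of the lognormal per-trial, per-channel gain
#'   multiplier exp(gain_jitter * N(0,1)), emulating repetition-to-repetition
#'   amplitude variability of a voluntary contraction. Default 0.2 (about
#'   20% rep-to-rep variability); set 0 for perfectly repeatable trials.
#' @return an `emg_trial`: list with `signal` (n_channels x n_samples matrix,
#'   mV scale), `fs`, `class_id`, `trial_id`, `subject_id`.
#' @export
generate_trial <- function(profile, class_id, duration_s, fs = 2000,
                           seed = 1L, trial_id = 1L, subject_id = "S1",
                           noise_floor = NULL, drift = 0, gain_jitter = 0.2) {
  stopifnot(inherits(profile, "activation_matrix"))
  n_classes <- nrow(profile)
  n_channels <- ncol(profile)
  if (class_id < 1L || class_id > n_classes) stop("invalid class_id")
  if (duration_s <= 0.35) {
    stop("duration_s must exceed 0.35 s to host one maximal window")
  }
  if (fs <= 2 * 450) stop("fs must exceed 900 Hz for the 20-450 Hz band")
  if (is.null(noise_floor)) noise_floor <- .default_noise_floor(profile)
  n <- round(duration_s * fs)
  set.seed(.substream_seed(seed, class_id, trial_id))
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  sig <- matrix(0, nrow = n_channels, ncol = n)
  ramp <- 1 + drift * (seq_len(n) / n - 0.5)
  jit <- exp(gain_jitter * stats::rnorm(n_channels))
  for (ch in seq_len(n_channels)) {
    carrier <- signal::filtfilt(bf, stats::rnorm(n))
    carrier <- carrier / sqrt(mean(carrier^2))
    sig[ch, ] <- profile[class_id, ch] * jit[ch] * ramp * carrier +
      noise_floor * stats::rnorm(n)
  }
  structure(list(signal = sig, fs = fs, class_id = as.integer(class_id),
                 trial_id = as.integer(trial_id),
                 subject_id = as.character(subject_id)),
            class = "emg_trial")
}

# 5% of the mean active-channel gain at unit separability. Anchoring the
# floor to the unit-separability scale (not the scaled gains) keeps it an
# absolute sensor property, so lowering `separability` genuinely sinks the
# classes into the noise instead of rescaling signal and noise together.
.default_noise_floor <- function(profile) {
  max(0.05 * attr(profile, "unit_gain"), 0.01)
}

#' Generate a labelled synthetic EMG dataset
#'
#' Draws `trials_per_class` trials for every class of a fresh activation
#' matrix, with durations uniform in `duration_range_s`. All randomness flows
#' from `seed`; per-trial substreams are derived by counter, so the dataset
#' is reproducible bit-for-bit.
#'
#' @param n_classes,n_channels,separability,seed passed to
#'   [make_activation_matrix()].
#' @param trials_per_class trials per class; >= 5 recommended so the
#'   2 training / 2 validation / rest split is possible.
#' @param duration_range_s length-2 numeric, trial duration bounds in
#'   seconds.
#' @param fs sampling rate in Hz.
#' @param noise_floor optional sensor-noise SD override (see
#'   [generate_trial()]).
#' @param drift,gain_jitter nonstationarity knobs, see [generate_trial()].
#' @param subject_id subject label.
#' @return an `emg_dataset`: list of `emg_trial`s plus `n_classes`,
#'   `n_channels` and a `manifest` recording every generator parameter.
#' @export
generate_dataset <- function(n_classes = 9, n_channels = 7,
                             trials_per_class = 6,
                             duration_range_s = c(8, 12), fs = 2000,
                             separability = 1, seed = 1L,
                             noise_floor = NULL, drift = 0,
                             gain_jitter = 0.2, subject_id = "S1") {
  profile <- make_activation_matrix(n_classes, n_channels, separability, seed)
  if (is.null(noise_floor)) noise_floor <- .default_noise_floor(profile)
  trials <- vector("list", n_classes * trials_per_class)
  i <- 0L
  for (cl in seq_len(n_classes)) {
    for (tr in seq_len(trials_per_class)) {
      set.seed(.substream_seed(seed, cl, 100000L + tr))
      dur <- stats::runif(1, duration_range_s[1], duration_range_s[2])
      i <- i + 1L
      trials[[i]] <- generate_trial(profile, cl, dur, fs, seed = seed,
                                    trial_id = tr, subject_id = subject_id,
                                    noise_floor = noise_floor, drift = drift,
                                    gain_jitter = gain_jitter)
    }
  }
  structure(list(
    trials = trials, n_classes = as.integer(n_classes),
    n_channels = as.integer(n_channels),
    manifest = list(n_classes = n_classes, n_channels = n_channels,
                    trials_per_class = trials_per_class,
                    duration_range_s = duration_range_s, fs = fs,
                    separability = separability, seed = seed,
                    noise_floor = noise_floor, drift = drift,
                    gain_jitter = gain_jitter, subject_id = subject_id)),
    class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("emg_dataset: %d trials, %d classes, %d channels, fs = %g Hz\n",
              length(x$trials), x$n_classes, x$n_channels,
              x$manifest$fs))
  invisible(x)
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf(
    "emg_trial: class %d, trial %d, %d channels x %d samples (%.2f s @ %g Hz)\n",
    x$class_id, x$trial_id, nrow(x$signal), ncol(x$signal),
    ncol(x$signal) / x$fs, x$fs))
  invisible(x)
}

#' Write / read a trial as plain CSV plus a JSON manifest
#'
#' The on-disk dialect is one trial per file: numeric CSV with one column per
#' channel (header `ch1..chK`) and a side-car `<path>.json` manifest holding
#' `subject_id`, `class_id`, `trial_id` and `fs`.
#'
#' @param trial an `emg_trial`.
#' @param path CSV file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns the reconstructed `emg_trial`.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "emg_trial"))
  df <- as.data.frame(t(trial$signal))
  names(df) <- paste0("ch", seq_len(nrow(trial$signal)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = trial$subject_id, class_id = trial$class_id,
               trial_id = trial$trial_id, fs = trial$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(signal = t(as.matrix(df)), fs = meta$fs,
                 class_id = as.integer(meta$class_id),
                 trial_id = as.integer(meta$trial_id),
                 subject_id = as.character(meta$subject_id)),
            class = "emg_trial")
}
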