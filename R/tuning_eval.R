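#' The default confidence-threshold grid
#'
#' Sixteen candidate thresholds: 0.70 to 0.98 in steps of 0.02, plus 0.99.
#'
#' @return strictly increasing numeric vector of length 16.
#' @export
threshold_grid <- function() {
  c(seq(0.70, 0.98, by = 0.02), 0.99)
}

.accepted <- function(log) {
  log$decisions[log$decisions$status == "ACCEPTED", , drop = FALSE]
}

#' Classification error rate of a decision log
#'
#' 100 x (incorrect accepted decisions) / (accepted decisions). Rejected
#' decisions are excluded from both numerator and denominator; report the
#' rejection rate separately so no information is lost.
#'
#' @param log a `decision_log`.
#' @return error rate in percent.
#' @export
error_rate <- function(log) {
  acc <- .accepted(log)
  if (nrow(acc) == 0L) {
    stop("error rate undefined: no accepted decisions in the log")
  }
  100 * mean(acc$predicted != acc$true_class)
}

#' Percentage of increased (extended) windows
#'
#' 100 x (decisions whose final window exceeds the base size) / (all
#' decisions, rejected ones included -- a rejected window was extended to the
#' maximum).
#'
#' @param log a `decision_log`.
#' @return percentage in `[0, 100]`.
#' @export
pct_increased <- function(log) {
  d <- log$decisions
  if (nrow(d) == 0L) stop("percentage undefined: empty decision log")
  100 * mean(d$final_size_ms > log$schedule$base_ms)
}

#' Rejection rate of a decision log
#' @param log a `decision_log`.
#' @return percentage of decisions rejected, over all decisions.
#' @export
rejection_rate <- function(log) {
  d <- log$decisions
  if (nrow(d) == 0L) stop("rate undefined: empty decision log")
  100 * mean(d$status == "REJECTED")
}

#' Mean (and SD) of the final window size
#' @param log a `decision_log`.
#' @return named vector `mean_ms`, `sd_ms` over all decisions.
#' @export
mean_final_window <- function(log) {
  d <- log$decisions
  if (nrow(d) == 0L) stop("undefined: empty decision log")
  c(mean_ms = mean(d$final_size_ms), sd_ms = stats::sd(d$final_size_ms))
}

#' Confusion matrix over accepted decisions
#' @param log a `decision_log`.
#' @param classes class labels to index rows/columns.
#' @return matrix, true class x predicted class.
#' @export
confusion_matrix <- function(log, classes = NULL) {
  acc <- .accepted(log)
  if (is.null(classes)) {
    classes <- sort(unique(c(acc$true_class, acc$predicted)))
  }
  table(factor(acc$true_class, levels = classes),
        factor(acc$predicted, levels = classes), dnn = c("true", "predicted"))
}

#' Per-class accuracy over accepted decisions
#' @param log a `decision_log`.
#' @param classes class labels.
#' @return named vector of accuracies in percent (NA for classes with no
#'   accepted decision).
#' @export
per_class_accuracy <- function(log, classes = NULL) {
  cm <- confusion_matrix(log, classes)
  n <- rowSums(cm)
  100 * ifelse(n > 0, diag(cm) / n, NA_real_)
}

#' Sweep the threshold grid over a validation split
#'
#' Runs the adaptive loop at every grid threshold (sharing the posterior
#' traces across thresholds) and collects validation error rate, percentage
#' of increased windows, rejection rate and mean final window size -- the
#' performance curves from which the trade-off threshold is chosen.
#'
#' @param trials validation trials (filtered), or a precomputed
#'   `posterior_traces` object.
#' @param proj,lda models trained on the training split only.
#' @param grid threshold grid (default [threshold_grid()]).
#' @param schedule,family,cfg as in [run_session()].
#' @return a `threshold_curves` data.frame with columns `theta`,
#'   `error_pct`, `pct_increased`, `rejection_pct`, `mean_final_ms`.
#' @export
sweep_thresholds <- function(trials, proj, lda, grid = threshold_grid(),
                             schedule = window_schedule(),
                             family = "TDPSD", cfg = feature_config()) {
  tr <- if (inherits(trials, "posterior_traces")) trials else
    posterior_traces(trials, proj, lda, schedule, family, cfg)
  rows <- lapply(grid, function(theta) {
    log <- apply_threshold(tr, theta)
    err <- tryCatch(error_rate(log), error = function(e) NA_real_)
    data.frame(theta = theta, error_pct = err,
               pct_increased = pct_increased(log),
               rejection_pct = rejection_rate(log),
               mean_final_ms = mean_final_window(log)[["mean_ms"]])
  })
  curves <- do.call(rbind, rows)
  class(curves) <- c("threshold_curves", "data.frame")
  curves
}

#' Select the trade-off threshold from the performance curves
#'
#' Mirrors a dual-axis reading of the curves: the error curve and the
#' %-increased-windows curve are each min-max normalized to `[0, 1]` (the
#' axis ranges), the first crossing of the two piecewise-linear curves is
#' located, and the smallest grid value strictly greater than the crossing
#' abscissa is returned. If the curves never cross, the grid value
#' minimizing the normalized gap |error - %increased| is returned; if either
#' curve is constant (zero range), the midpoint of the grid is returned with
#' a warning.
#'
#' @param curves a `threshold_curves` data.frame.
#' @param grid the threshold grid the curves were computed on.
#' @return one grid value.
#' @export
select_tradeoff_threshold <- function(curves, grid = threshold_grid()) {
  e <- curves$error_pct
  w <- curves$pct_increased
  if (anyNA(e)) {
    # error undefined where everything was rejected; treat as worst case
    e[is.na(e)] <- max(e, na.rm = TRUE)
  }
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) <= 0) return(NULL)
    (v - r[1]) / diff(r)
  }
  ne <- norm01(e)
  nw <- norm01(w)
  if (is.null(ne) || is.null(nw)) {
    warning("constant performance curve; falling back to the grid midpoint")
    return(grid[ceiling(length(grid) / 2)])
  }
  diffc <- nw - ne
  cross <- NULL
  for (i in seq_len(length(grid) - 1L)) {
    if (diffc[i] == 0) { cross <- grid[i]; break }
    if (diffc[i] < 0 && diffc[i + 1L] >= 0) {
      # linear interpolation of the crossing abscissa inside [g_i, g_{i+1}]
      t <- diffc[i] / (diffc[i] - diffc[i + 1L])
      cross <- grid[i] + t * (grid[i + 1L] - grid[i])
      break
    }
  }
  if (is.null(cross)) {
    if (diffc[length(grid)] == 0) {
      cross <- grid[length(grid)]
    } else {
      return(grid[which.min(abs(diffc))])
    }
  }
  after <- grid[grid > cross + 1e-12]
  if (length(after) == 0L) return(grid[length(grid)])
  after[1L]
}

#' Majority vote over a decision stream
#'
#' Smooths a stream of accepted class labels: each output is the modal class
#' of the current and up to `span - 1` previous labels (fewer at stream
#' start). Ties are broken toward the most recently seen class among those
#' tied.
#'
#' @param labels integer vector of class labels, in stream order.
#' @param span vote window including the current label (default 9: the
#'   current and 8 previous decisions).
#' @return integer vector of smoothed labels, same length.
#' @export
majority_vote <- function(labels, span = 9) {
  stopifnot(span >= 1)
  n <- length(labels)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  for (i in seq_len(n)) {
    w <- labels[max(1L, i - span + 1L):i]
    tab <- table(w)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) {
      out[i] <- top
    } else {
      # most recent among the tied classes
      out[i] <- w[max(vapply(top, function(k) max(which(w == k)), 0L))]
    }
  }
  out
}

#' Bayesian fusion of a posterior stream
#'
#' Combines the current and up to `span - 1` previous posterior vectors by
#' summing log posteriors (each probability floored at 1e-12 before the
#' log), renormalizing, and emitting the argmax class.
#'
#' @param P posterior matrix, one row per stream position, columns named by
#'   class.
#' @param span fusion window including the current position (default 9).
#' @return integer vector of fused class labels.
#' @export
bayes_fusion <- function(P, span = 9) {
  stopifnot(span >= 1)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  n <- nrow(P)
  if (n == 0L) return(integer(0))
  if (any(abs(rowSums(P) - 1) > 1e-6) || any(P < -1e-12)) {
    stop("rows of P must be probability vectors summing to 1")
  }
  L <- log(pmax(P, 1e-12))
  cls <- as.integer(colnames(P))
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- colSums(L[max(1L, i - span + 1L):i, , drop = FALSE])
    out[i] <- cls[which.max(s)]
  }
  out
}

# classical fixed-base-window decisions: posteriors at the base size only,
# argmax with no confidence gate. Streams are kept per trial.
.classical_streams <- function(trials, proj, lda, schedule, family, cfg) {
  lapply(trials, function(trial) {
    anchors <- enumerate_anchors(trial, schedule)
    if (nrow(anchors) == 0L) return(NULL)
    X <- .trial_feature_matrix(trial, anchors, schedule$sizes_ms[1],
                               schedule, family, cfg)
    P <- posteriors(lda, project(proj, X))
    pm <- pr_max(P)
    list(true = anchors$true_class, labels = pm$class, posteriors = P)
  })
}

.stream_error <- function(streams, transform = function(s) s$labels) {
  wrong <- 0L; total <- 0L
  for (s in streams) {
    if (is.null(s)) next
    lab <- transform(s)
    wrong <- wrong + sum(lab != s$true)
    total <- total + length(lab)
  }
  if (total == 0L) stop("no decisions in any stream")
  100 * wrong / total
}

#' Configuration for a full adaptive-windowing experiment
#'
#' @param n_classes,n_channels,trials_per_class,duration_range_s,fs,separability,noise_floor,gain_jitter
#'   synthetic-data parameters, see [generate_dataset()].
#' @param family feature family.
#' @param class_subset,channel_subset optional integer vectors restricting
#'   the experiment to a subset of the generated classes / channels (e.g.,
#'   first 7 of 9 classes, first 5 of 7 channels).
#' @param grid threshold grid.
#' @param schedule a `window_schedule` (must match `fs`).
#' @param cfg a [feature_config()].
#' @param sr_alpha,lda_gamma model regularization.
#' @param mv_bf_span post-processing span (current + 8 previous by default).
#' @param seed master seed for everything.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_classes = 9, n_channels = 7,
                              trials_per_class = 6,
                              duration_range_s = c(8, 12), fs = 2000,
                              separability = 1, noise_floor = NULL,
                              gain_jitter = 0.2,
                              family = "TDPSD", class_subset = NULL,
                              channel_subset = NULL,
                              grid = threshold_grid(),
                              schedule = window_schedule(fs = fs),
                              cfg = feature_config(), sr_alpha = 0.01,
                              lda_gamma = 1e-6, mv_bf_span = 9,
                              seed = 1L) {
  structure(as.list(environment()), class = "experiment_config")
}

#' Split a dataset's trials into training / validation / test sets
#'
#' Per class: the first 2 trials (by trial id) train the design-phase
#' classifier, the next 2 form the validation set for threshold tuning, and
#' the remaining trials are the held-out test set for the evaluation phase.
#'
#' @param dataset an `emg_dataset`.
#' @param n_train,n_validation trials per class in the first two sets.
#' @return list of trial lists: `training`, `validation`, `test`.
#' @export
split_dataset <- function(dataset, n_train = 2, n_validation = 2) {
  cls <- vapply(dataset$trials, function(t) t$class_id, 0L)
  ids <- vapply(dataset$trials, function(t) t$trial_id, 0L)
  tr <- list(); va <- list(); te <- list()
  for (k in sort(unique(cls))) {
    idx <- which(cls == k)[order(ids[cls == k])]
    if (length(idx) < n_train + n_validation + 1L) {
      stop(sprintf(
        "class %d has %d trials; need at least %d for the %d/%d/rest split",
        k, length(idx), n_train + n_validation + 1L, n_train, n_validation))
    }
    tr <- c(tr, dataset$trials[idx[seq_len(n_train)]])
    va <- c(va, dataset$trials[idx[n_train + seq_len(n_validation)]])
    te <- c(te, dataset$trials[idx[-seq_len(n_train + n_validation)]])
  }
  list(training = tr, validation = va, test = te)
}

.subset_trial <- function(trial, channel_subset) {
  if (is.null(channel_subset)) return(trial)
  trial$signal <- trial$signal[channel_subset, , drop = FALSE]
  trial
}

#' Run the full two-phase adaptive-windowing experiment
#'
#' Generates (or accepts) a dataset, band-pass filters it, and executes the
#' complete protocol. Design phase: train projection + LDA on the training
#' split (2 trials per class, features pooled over all window sizes), sweep
#' the threshold grid on the validation split, select the trade-off
#' threshold. Evaluation phase: retrain on training + validation (4 trials
#' per class) and run the adaptive loop on the unseen test split at the
#' selected threshold. Classical fixed-150 ms LDA, majority-vote and
#' Bayesian-fusion baselines are computed on the same test decisions.
#'
#' @param config an [experiment_config()].
#' @param dataset optional pre-generated `emg_dataset`; by default one is
#'   generated from the config's synthetic parameters.
#' @return an `experiment_report` list: selected `theta`, design-phase
#'   `curves`, test-set metrics (`error_pct`, `rejection_pct`,
#'   `pct_increased`, `final_window_ms` mean/sd, `per_class_accuracy`,
#'   `confusion`), baseline errors (`classical_error_pct`, `mv_error_pct`,
#'   `bf_error_pct`), the test `log`, and a `config` echo.
#' @export
run_experiment <- function(config = experiment_config(), dataset = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(dataset)) {
    dataset <- generate_dataset(
      n_classes = config$n_classes, n_channels = config$n_channels,
      trials_per_class = config$trials_per_class,
      duration_range_s = config$duration_range_s, fs = config$fs,
      separability = config$separability, seed = config$seed,
      noise_floor = config$noise_floor, gain_jitter = config$gain_jitter)
  }
  trials <- dataset$trials
  if (!is.null(config$class_subset)) {
    trials <- Filter(function(t) t$class_id %in% config$class_subset, trials)
  }
  trials <- lapply(trials, .subset_trial, config$channel_subset)
  trials <- lapply(trials, bandpass)
  ds <- dataset
  ds$trials <- trials
  split <- split_dataset(ds)

  sched <- config$schedule
  fam <- config$family
  cfg <- config$cfg

  # design phase: tune theta on the validation split
  d_train <- assemble_multiwindow_training(split$training, sched, fam, cfg)
  d_proj <- fit_sr(d_train$X, d_train$y, alpha = config$sr_alpha)
  d_lda <- fit_lda(project(d_proj, d_train$X), d_train$y,
                   gamma = config$lda_gamma)
  curves <- sweep_thresholds(split$validation, d_proj, d_lda,
                             grid = config$grid, schedule = sched,
                             family = fam, cfg = cfg)
  theta <- select_tradeoff_threshold(curves, config$grid)

  # evaluation phase: retrain on training + validation, test unseen trials
  e_train <- assemble_multiwindow_training(
    c(split$training, split$validation), sched, fam, cfg)
  e_proj <- fit_sr(e_train$X, e_train$y, alpha = config$sr_alpha)
  e_lda <- fit_lda(project(e_proj, e_train$X), e_train$y,
                   gamma = config$lda_gamma)
  log <- run_session(split$test, e_proj, e_lda, theta, sched, fam, cfg)

  streams <- .classical_streams(split$test, e_proj, e_lda, sched, fam, cfg)
  span <- config$mv_bf_span
  classes <- sort(unique(vapply(trials, function(t) t$class_id, 0L)))

  report <- list(
    theta = theta, curves = curves,
    error_pct = tryCatch(error_rate(log), error = function(e) NA_real_),
    rejection_pct = rejection_rate(log),
    pct_increased = pct_increased(log),
    final_window_ms = mean_final_window(log),
    per_class_accuracy = per_class_accuracy(log, classes),
    confusion = confusion_matrix(log, classes),
    classical_error_pct = .stream_error(streams),
    mv_error_pct = .stream_error(
      streams, function(s) majority_vote(s$labels, span)),
    bf_error_pct = .stream_error(
      streams, function(s) bayes_fusion(s$posteriors, span)),
    log = log,
    models = list(proj = e_proj, lda = e_lda),
    config = config)
  class(report) <- "experiment_report"
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Adaptive-windowing experiment report\n")
  cat(sprintf("  trade-off threshold (theta): %.2f\n", x$theta))
  cat(sprintf("  adaptive error rate:         %.1f%%\n", x$error_pct))
  cat(sprintf("  classical LDA (150 ms):      %.1f%%\n",
              x$classical_error_pct))
  cat(sprintf("  LDA + majority vote:         %.1f%%\n", x$mv_error_pct))
  cat(sprintf("  LDA + Bayesian fusion:       %.1f%%\n", x$bf_error_pct))
  cat(sprintf("  rejection rate:              %.1f%%\n", x$rejection_pct))
  cat(sprintf("  increased windows:           %.1f%%\n", x$pct_increased))
  cat(sprintf("  final window size:           %.1f +/- %.1f ms\n",
              x$final_window_ms[["mean_ms"]], x$final_window_ms[["sd_ms"]]))
  invisible(x)
}

#' Write an experiment report and its artifacts to a directory
#'
#' Writes `report.json` (scalar metrics + config echo), `curves.csv`,
#' `decisions.csv` and `confusion.csv`.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  cfg$schedule <- unclass(cfg$schedule)
  cfg$cfg <- unclass(cfg$cfg)
  scalars <- list(
    theta = report$theta, error_pct = report$error_pct,
    rejection_pct = report$rejection_pct,
    pct_increased = report$pct_increased,
    mean_final_window_ms = report$final_window_ms[["mean_ms"]],
    sd_final_window_ms = report$final_window_ms[["sd_ms"]],
    classical_error_pct = report$classical_error_pct,
    mv_error_pct = report$mv_error_pct,
    bf_error_pct = report$bf_error_pct,
    per_class_accuracy = as.list(report$per_class_accuracy),
    config = cfg)
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(report$curves, file.path(dir, "curves.csv"),
                   row.names = FALSE)
  write_decision_log(report$log, file.path(dir, "decisions.csv"))
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   file.path(dir, "confusion.csv"))
  invisible(dir)
}
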