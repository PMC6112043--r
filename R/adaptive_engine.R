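# Core loop mechanics on a posterior trace: given the per-size posterior
# matrix of one anchor (rows = scheduled sizes in increasing order), accept
# at the first size whose largest posterior reaches theta, else reject at
# the maximal size. Separated out so the mechanics can be exercised with
# stubbed posteriors, independently of any signal.
.threshold_trace <- function(P, theta, sizes_ms) {
  prm <- apply(P, 1, max)
  hit <- which(prm >= theta)
  if (length(hit) == 0L) {
    list(status = "REJECTED", predicted = NA_integer_,
         final_size_ms = sizes_ms[length(sizes_ms)],
         n_extensions = length(sizes_ms) - 1L, attempted = nrow(P))
  } else {
    i <- hit[1L]
    k <- which.max(P[i, ])
    list(status = "ACCEPTED",
         predicted = as.integer(colnames(P)[k]),
         final_size_ms = sizes_ms[i], n_extensions = i - 1L, attempted = i)
  }
}

#' Full posterior traces for every anchor of a trial set
#'
#' Computes, for every enumerated anchor and every scheduled window size, the
#' class posterior vector of the trained chain (features -> projection ->
#' LDA). The traces are the sufficient statistic of the adaptive loop: any
#' confidence threshold can then be applied to them without re-extracting
#' features, which is what the threshold sweep exploits.
#'
#' @param trials list of (filtered) `emg_trial`s.
#' @param proj a `projection_model`.
#' @param lda an `lda_model`.
#' @param schedule a `window_schedule`.
#' @param family,cfg feature family and config the models were trained with.
#' @return a `posterior_traces` object: `anchors` data.frame and `traces`,
#'   a list (one per anchor) of n_sizes x n_classes posterior matrices with
#'   sizes as rownames and class labels as colnames.
#' @export
posterior_traces <- function(trials, proj, lda, schedule, family = "TDPSD",
                             cfg = feature_config()) {
  stopifnot(inherits(proj, "projection_model"), inherits(lda, "lda_model"))
  anc_list <- list()
  traces <- list()
  for (trial in trials) {
    anchors <- enumerate_anchors(trial, schedule)
    if (nrow(anchors) == 0L) next
    per_size <- lapply(schedule$sizes_ms, function(size_ms) {
      X <- .trial_feature_matrix(trial, anchors, size_ms, schedule, family,
                                 cfg)
      posteriors(lda, project(proj, X))
    })
    for (a in seq_len(nrow(anchors))) {
      P <- do.call(rbind, lapply(per_size, function(M) M[a, , drop = FALSE]))
      rownames(P) <- schedule$sizes_ms
      traces[[length(traces) + 1L]] <- P
    }
    anc_list[[length(anc_list) + 1L]] <- anchors
  }
  anchors <- if (length(anc_list)) do.call(rbind, anc_list) else
    data.frame(start = integer(0), true_class = integer(0),
               trial_id = integer(0), subject_id = character(0))
  structure(list(anchors = anchors, traces = traces, schedule = schedule),
            class = "posterior_traces")
}

#' One adaptive decision at a single anchor
#'
#' Iterates the schedule from the base size: materialize the window, extract
#' features, project, compute posteriors; stop at the first size whose
#' largest posterior Pr_Max reaches the confidence threshold `theta`
#' (ACCEPT with that argmax class), or reject once the maximal window has
#' been evaluated without reaching it. Features are recomputed from scratch
#' at every size. The returned trace holds exactly the attempted sizes.
#'
#' @param trial a (filtered) `emg_trial`.
#' @param start anchor start sample (1-based).
#' @param proj,lda trained models.
#' @param theta confidence threshold in (0, 1].
#' @param schedule a `window_schedule`.
#' @param family,cfg feature family and config.
#' @return a `decision` list: `status` ("ACCEPTED"/"REJECTED"), `predicted`
#'   (NA when rejected), `final_size_ms`, `n_extensions`, `trace`
#'   (attempted sizes x classes posterior matrix), `true_class`, `theta`.
#' @export
decide <- function(trial, start, proj, lda, theta, schedule,
                   family = "TDPSD", cfg = feature_config()) {
  if (!(theta > 0 && theta <= 1)) stop("theta must lie in (0, 1]")
  rows <- list()
  res <- NULL
  for (i in seq_along(schedule$sizes_ms)) {
    size_ms <- schedule$sizes_ms[i]
    p <- tryCatch({
      w <- materialize(trial, start, size_ms, schedule)
      posteriors(lda, project(proj, extract_features(w, family, cfg)))
    }, error = function(e) {
      stop(sprintf("anchor at sample %d, size %d ms: %s", start, size_ms,
                   conditionMessage(e)))
    })
    rows[[i]] <- p
    if (max(p) >= theta) {
      res <- list(status = "ACCEPTED",
                  predicted = as.integer(colnames(p)[which.max(p)]),
                  final_size_ms = size_ms, n_extensions = i - 1L)
      break
    }
  }
  if (is.null(res)) {
    res <- list(status = "REJECTED", predicted = NA_integer_,
                final_size_ms = schedule$sizes_ms[length(schedule$sizes_ms)],
                n_extensions = length(schedule$sizes_ms) - 1L)
  }
  P <- do.call(rbind, rows)
  rownames(P) <- schedule$sizes_ms[seq_along(rows)]
  structure(c(res, list(trace = P, true_class = trial$class_id,
                        start = start, theta = theta)),
            class = "decision")
}

#' Apply a confidence threshold to precomputed traces
#'
#' @param tr a `posterior_traces` object.
#' @param theta confidence threshold in (0, 1].
#' @return a `decision_log` (see [run_session()]).
#' @export
apply_threshold <- function(tr, theta) {
  stopifnot(inherits(tr, "posterior_traces"))
  if (!(theta > 0 && theta <= 1)) stop("theta must lie in (0, 1]")
  sizes_ms <- tr$schedule$sizes_ms
  n <- length(tr$traces)
  status <- character(n); predicted <- integer(n)
  final <- numeric(n); next_ <- integer(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    r <- .threshold_trace(tr$traces[[i]], theta, sizes_ms)
    status[i] <- r$status; predicted[i] <- r$predicted
    final[i] <- r$final_size_ms; next_[i] <- r$n_extensions
    traces[[i]] <- tr$traces[[i]][seq_len(r$attempted), , drop = FALSE]
  }
  log_df <- cbind(tr$anchors,
                  data.frame(status = status, predicted = predicted,
                             final_size_ms = final, n_extensions = next_,
                             theta = rep(theta, n)))
  structure(list(decisions = log_df, traces = traces,
                 schedule = tr$schedule, theta = theta),
            class = "decision_log")
}

#' Run the adaptive loop over a whole split
#'
#' Applies [decide()] to every enumerated anchor of every trial, in trial
#' and time order. Implemented by computing the full posterior traces once
#' and thresholding them, which yields decisions identical to the
#' size-by-size loop.
#'
#' @inheritParams posterior_traces
#' @param theta confidence threshold in (0, 1].
#' @return a `decision_log`: `decisions` data.frame (one row per anchor:
#'   anchor provenance, status, predicted, final_size_ms, n_extensions,
#'   theta) plus the per-decision posterior `traces` of attempted sizes.
#' @export
run_session <- function(trials, proj, lda, theta, schedule,
                        family = "TDPSD", cfg = feature_config()) {
  apply_threshold(
    posterior_traces(trials, proj, lda, schedule, family, cfg), theta)
}

#' @export
print.decision_log <- function(x, ...) {
  d <- x$decisions
  cat(sprintf(
    "decision_log: %d decisions (theta = %g), %d rejected, %.1f%% extended\n",
    nrow(d), x$theta, sum(d$status == "REJECTED"),
    if (nrow(d)) 100 * mean(d$final_size_ms > x$schedule$base_ms) else 0))
  invisible(x)
}

#' Export a decision log to CSV
#'
#' One row per decision: anchor provenance, status, predicted and true
#' class, final window size, number of extensions, and Pr_Max at every
#' attempted size (columns `pr_max_<size>`; NA for sizes never attempted).
#'
#' @param log a `decision_log`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_log <- function(log, path) {
  stopifnot(inherits(log, "decision_log"))
  sizes <- log$schedule$sizes_ms
  prm <- t(vapply(log$traces, function(P) {
    v <- rep(NA_real_, length(sizes))
    v[seq_len(nrow(P))] <- apply(P, 1, max)
    v
  }, numeric(length(sizes))))
  colnames(prm) <- paste0("pr_max_", sizes)
  utils::write.csv(cbind(log$decisions, prm), path, row.names = FALSE)
  invisible(path)
}
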