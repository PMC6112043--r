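# Feature matrix for all anchors of one trial at one window size, rows in
# anchor order. Used by training assembly and by the decision engine.
.trial_feature_matrix <- function(trial, anchors, size_ms, schedule, family,
                                  cfg) {
  if (nrow(anchors) == 0L) return(NULL)
  rows <- lapply(anchors$start, function(s) {
    extract_features(materialize(trial, s, size_ms, schedule), family, cfg)
  })
  do.call(rbind, rows)
}

#' Assemble the pooled multi-window training set
#'
#' For every anchor of every trial and every window size in the schedule,
#' one feature row labelled with the trial's class. Rows from all sizes are
#' stacked into a single training set, so the classifier is trained
#' simultaneously with features from every window length it may encounter at
#' decision time.
#'
#' @param trials list of (filtered) `emg_trial`s.
#' @param schedule a `window_schedule`.
#' @param family feature family, see [extract_features()].
#' @param cfg a [feature_config()].
#' @return list with `X` (features, one row per anchor x size) and `y`
#'   (integer class labels).
#' @export
assemble_multiwindow_training <- function(trials, schedule,
                                          family = "TDPSD",
                                          cfg = feature_config()) {
  if (length(trials) == 0L) stop("empty trial set")
  Xs <- list()
  ys <- list()
  for (trial in trials) {
    anchors <- enumerate_anchors(trial, schedule)
    if (nrow(anchors) == 0L) next
    for (size_ms in schedule$sizes_ms) {
      M <- .trial_feature_matrix(trial, anchors, size_ms, schedule, family,
                                 cfg)
      Xs[[length(Xs) + 1L]] <- M
      ys[[length(ys) + 1L]] <- rep(trial$class_id, nrow(M))
    }
  }
  if (length(Xs) == 0L) stop("no trial can host the maximal window")
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

#' Fit the spectral-regression discriminant projection
#'
#' Reduces the feature space to c - 1 dimensions (c = number of classes) by
#' spectral regression: features are z-scored on the training set,
#' c - 1 class-indicator response vectors orthogonalized against the constant
#' vector are built, and one ridge-regularized least-squares problem per
#' response yields the projection directions. For small ridge penalties the
#' spanned subspace coincides with the Fisher discriminant subspace.
#'
#' @param X training feature matrix (rows = windows).
#' @param y integer class labels.
#' @param alpha ridge penalty (default 0.01; stabilizes collinear features
#'   such as neighbouring wavelet-band energies).
#' @return a `projection_model`: projection `W` (d x (c-1)), standardization
#'   `center`/`scale`, kept-column index, class labels.
#' @export
fit_sr <- function(X, y, alpha = 0.01) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  c_n <- length(classes)
  if (c_n < 2L) stop("need at least 2 classes")
  tab <- table(y)
  if (any(tab < 2L)) {
    stop(sprintf("class %s has fewer than 2 training rows",
                 names(tab)[which.min(tab)]))
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  keep <- which(scale_ > 0)
  if (length(keep) < ncol(X)) {
    warning(sprintf("dropping %d zero-variance feature column(s)",
                    ncol(X) - length(keep)))
  }
  if (length(keep) < c_n - 1L) stop("fewer informative features than c - 1")
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2,
             scale_[keep], "/")
  n <- nrow(Z)
  # responses: class indicators orthogonalized against the constant vector
  Y <- outer(y, classes, "==") * 1
  Q <- qr.Q(qr(cbind(rep(1, n), Y)))[, 2:c_n, drop = FALSE]
  G <- crossprod(Z) + alpha * diag(length(keep))
  W <- solve(G, crossprod(Z, Q))
  colnames(W) <- paste0("sr", seq_len(ncol(W)))
  structure(list(W = W, center = center, scale = scale_, keep = keep,
                 classes = classes, alpha = alpha, d = ncol(X)),
            class = "projection_model")
}

#' Project feature vectors into the reduced discriminant space
#'
#' @param model a `projection_model` from [fit_sr()].
#' @param x a feature vector or matrix (rows = windows) of the width the
#'   model was fitted on.
#' @return matrix of reduced coordinates, one row per input row, c - 1
#'   columns.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "projection_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$d) {
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(x), model$d))
  }
  k <- model$keep
  Z <- sweep(sweep(x[, k, drop = FALSE], 2, model$center[k]), 2,
             model$scale[k], "/")
  Z %*% model$W
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf(
    "projection_model: %d features -> %d discriminant dims (%d classes, ridge %g)\n",
    x$d, ncol(x$W), length(x$classes), x$alpha))
  invisible(x)
}

#' Serialize / restore a projection + classifier pair as JSON
#'
#' Flat-text round-trip of the trained models for command-line workflows.
#'
#' @param proj a `projection_model`.
#' @param lda an `lda_model`.
#' @param path output JSON file.
#' @return `write_models` returns `path` invisibly; `read_models` the
#'   restored list with elements `proj` and `lda`.
#' @export
write_models <- function(proj, lda, path) {
  obj <- list(
    proj = list(W = proj$W, center = proj$center, scale = proj$scale,
                keep = proj$keep, classes = proj$classes,
                alpha = proj$alpha, d = proj$d),
    lda = list(means = lda$means, cov = lda$cov, priors = lda$priors,
               gamma = lda$gamma, classes = lda$classes))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  proj <- structure(list(W = as.matrix(obj$proj$W),
                         center = obj$proj$center, scale = obj$proj$scale,
                         keep = obj$proj$keep, classes = obj$proj$classes,
                         alpha = obj$proj$alpha, d = obj$proj$d),
                    class = "projection_model")
  lda <- structure(list(means = as.matrix(obj$lda$means),
                        cov = as.matrix(obj$lda$cov),
                        priors = obj$lda$priors, gamma = obj$lda$gamma,
                        classes = obj$lda$classes),
                   class = "lda_model")
  list(proj = proj, lda = lda)
}
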