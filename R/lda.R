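#' Fit a Gaussian linear discriminant classifier with posterior output
#'
#' Classes are modelled as Gaussians with per-class means and a pooled
#' within-class covariance, shrunk towards its diagonal as
#' (1 - gamma) S + gamma diag(S) to guarantee positive definiteness. Priors
#' are uniform by default (the synthetic design is class-balanced).
#'
#' @param Z reduced training matrix (rows = windows, c - 1 columns).
#' @param y integer class labels.
#' @param gamma diagonal shrinkage in `[0, 1]`; the default 1e-6 is a
#'   numerical floor only.
#' @param priors optional prior vector (one per class, sums to 1).
#' @return an `lda_model`: class `means`, pooled `cov`, `priors`, `classes`.
#' @export
fit_lda <- function(Z, y, gamma = 1e-6, priors = NULL) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("non-finite training rows")
  classes <- sort(unique(y))
  c_n <- length(classes)
  tab <- table(factor(y, levels = classes))
  if (any(tab < 2L)) stop("every class needs at least 2 rows")
  p <- ncol(Z)
  means <- t(vapply(classes, function(k) colMeans(Z[y == k, , drop = FALSE]),
                    numeric(p)))
  S <- matrix(0, p, p)
  for (k in seq_along(classes)) {
    Zk <- Z[y == classes[k], , drop = FALSE]
    Zk <- sweep(Zk, 2, means[k, ])
    S <- S + crossprod(Zk)
  }
  S <- S / (nrow(Z) - c_n)
  S <- (1 - gamma) * S + gamma * diag(diag(S), p)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop("pooled covariance is singular; increase the shrinkage gamma")
  }
  if (is.null(priors)) priors <- rep(1 / c_n, c_n)
  stopifnot(length(priors) == c_n, abs(sum(priors) - 1) < 1e-8)
  structure(list(means = means, cov = S, chol = ch, priors = priors,
                 gamma = gamma, classes = classes),
            class = "lda_model")
}

#' Class posterior probabilities under the LDA model
#'
#' Pr(class k | z) is proportional to prior_k N(z; mu_k, S), evaluated in log
#' space (via the Cholesky factor of the pooled covariance, with the largest
#' log density subtracted before exponentiation) so that extreme inputs do
#' not overflow.
#'
#' @param model an `lda_model`.
#' @param z a reduced vector, or a matrix of rows to score.
#' @return matrix of posteriors (rows sum to 1), one row per input row; the
#'   per-class columns are named by class label.
#' @export
posteriors <- function(model, z) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (!all(is.finite(z))) stop("non-finite query vector")
  if (ncol(z) != ncol(model$means)) {
    stop("query length must equal the reduced dimension")
  }
  ch <- model$chol
  if (is.null(ch)) ch <- chol(model$cov)
  # log N(z; mu_k, S) up to the shared constant: -0.5 ||L^-T (z - mu_k)||^2
  logp <- vapply(seq_along(model$classes), function(k) {
    d <- sweep(z, 2, model$means[k, ])
    u <- backsolve(ch, t(d), transpose = TRUE)
    -0.5 * colSums(u^2) + log(model$priors[k])
  }, numeric(nrow(z)))
  logp <- matrix(logp, nrow = nrow(z))
  m <- apply(logp, 1, max)
  p <- exp(logp - m)
  p <- p / rowSums(p)
  colnames(p) <- as.character(model$classes)
  p
}

#' Largest posterior and its class
#'
#' @param p a posterior matrix from [posteriors()].
#' @return data.frame with `pr_max` and the winning `class` per row.
#' @export
pr_max <- function(p) {
  idx <- max.col(p, ties.method = "first")
  data.frame(pr_max = p[cbind(seq_len(nrow(p)), idx)],
             class = as.integer(colnames(p))[idx])
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: %d classes in %d dims (shrinkage %g)\n",
              length(x$classes), ncol(x$means), x$gamma))
  invisible(x)
}
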