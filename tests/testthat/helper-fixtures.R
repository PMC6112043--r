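# Shared fixtures, built once per test run and memoized: generating EMG and
# training the chain is the expensive part of almost every test.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but non-trivial 4-class, 3-channel dataset: short trials keep the
# anchor count (and runtime) down while every stage still has work to do.
tiny_dataset <- function() {
  with_cache("tiny_dataset", generate_dataset(
    n_classes = 4, n_channels = 3, trials_per_class = 5,
    duration_range_s = c(1.2, 1.8), separability = 0.4, seed = 7L))
}

tiny_filtered <- function() {
  with_cache("tiny_filtered", bandpass_dataset(tiny_dataset()))
}

# Chain trained on the tiny dataset's first-2-trials split (TD family).
tiny_models <- function() {
  with_cache("tiny_models", {
    split <- split_dataset(tiny_filtered())
    sched <- window_schedule()
    tr <- assemble_multiwindow_training(split$training, sched, family = "TD")
    proj <- fit_sr(tr$X, tr$y)
    lda <- fit_lda(project(proj, tr$X), tr$y)
    list(split = split, schedule = sched, proj = proj, lda = lda,
         family = "TD")
  })
}

# Posterior traces of the tiny validation split, shared by threshold tests.
tiny_traces <- function() {
  with_cache("tiny_traces", {
    m <- tiny_models()
    posterior_traces(m$split$validation, m$proj, m$lda, m$schedule, m$family)
  })
}

# A random stochastic trace matrix (sizes x classes) for stubbed-loop tests.
random_trace <- function(n_sizes = 5, n_classes = 5) {
  P <- matrix(stats::rexp(n_sizes * n_classes), n_sizes)
  P <- P / rowSums(P)
  colnames(P) <- seq_len(n_classes)
  rownames(P) <- seq(150, by = 50, length.out = n_sizes)
  P
}
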