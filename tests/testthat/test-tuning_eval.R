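# hand-built decision log for metric arithmetic tests
.fake_log <- function(status, predicted, true, final_size) {
  structure(list(
    decisions = data.frame(start = seq_along(status), true_class = true,
                           trial_id = 1L, subject_id = "t", status = status,
                           predicted = predicted, final_size_ms = final_size,
                           n_extensions = (final_size - 150) / 50,
                           theta = 0.9),
    traces = vector("list", length(status)),
    schedule = window_schedule(), theta = 0.9), class = "decision_log")
}

test_that("error rate follows the incorrect/total rule, rejects excluded", {
  l1 <- .fake_log(rep("ACCEPTED", 10), c(rep(1, 9), 2), rep(1, 10), 150)
  expect_equal(error_rate(l1), 10.0)
  l2 <- .fake_log(rep("ACCEPTED", 6), rep(3, 6), rep(3, 6), 150)
  expect_equal(error_rate(l2), 0.0)
  # 5 accepted (1 wrong) + 5 rejected -> 20%, not 10%
  l3 <- .fake_log(c(rep("ACCEPTED", 5), rep("REJECTED", 5)),
                  c(2, 1, 1, 1, 1, rep(NA, 5)), rep(1, 10),
                  c(rep(150, 5), rep(350, 5)))
  expect_equal(error_rate(l3), 20.0)
  expect_equal(rejection_rate(l3), 50.0)
  l4 <- .fake_log(rep("REJECTED", 3), rep(NA, 3), rep(1, 3), 350)
  expect_error(error_rate(l4), "no accepted")
})

test_that("percentage of increased windows counts every decision", {
  l1 <- .fake_log(rep("ACCEPTED", 10), rep(1, 10), rep(1, 10), 150)
  expect_equal(pct_increased(l1), 0.0)
  l2 <- .fake_log(rep("ACCEPTED", 10), rep(1, 10), rep(1, 10),
                  c(rep(150, 8), 200, 350))
  expect_equal(pct_increased(l2), 20.0)
  # a fully-rejecting run extended every window to the maximum
  l3 <- .fake_log(rep("REJECTED", 4), rep(NA, 4), rep(1, 4), 350)
  expect_equal(pct_increased(l3), 100.0)
  expect_equal(mean_final_window(l3)[["mean_ms"]], 350)
})

test_that("error rate always equals its own confusion matrix", {
  log <- apply_threshold(tiny_traces(), 0.85)
  cm <- confusion_matrix(log, classes = 1:4)
  expect_equal(error_rate(log), 100 * (1 - sum(diag(cm)) / sum(cm)))
  acc <- per_class_accuracy(log, classes = 1:4)
  expect_length(acc, 4)
  expect_true(all(acc >= 0 & acc <= 100, na.rm = TRUE))
})

test_that("the threshold sweep produces 16 consistent, monotone curve points", {
  grid <- threshold_grid()
  expect_length(grid, 16)
  expect_equal(grid[1:3], c(0.70, 0.72, 0.74))
  expect_equal(grid[15:16], c(0.98, 0.99))

  m <- tiny_models()
  curves <- sweep_thresholds(tiny_traces(), m$proj, m$lda, grid,
                             m$schedule, m$family)
  expect_equal(nrow(curves), 16)
  expect_true(all(diff(curves$pct_increased) >= 0))
  expect_true(all(diff(curves$mean_final_ms) >= 0))
  expect_true(all(curves$pct_increased >= 0 & curves$pct_increased <= 100))
  # first entry equals an independent direct run at theta = 0.70
  direct <- apply_threshold(tiny_traces(), 0.70)
  expect_equal(curves$error_pct[1], error_rate(direct))
  expect_equal(curves$pct_increased[1], pct_increased(direct))
})

test_that("trade-off selection returns the first grid value after the crossing", {
  grid <- threshold_grid()
  mk_curves <- function(err, inc) {
    structure(data.frame(theta = grid, error_pct = err, pct_increased = inc,
                         rejection_pct = 0, mean_final_ms = 150),
              class = c("threshold_curves", "data.frame"))
  }
  # strictly decreasing error, strictly increasing extensions
  err <- seq(30, 5, length.out = 16)
  inc <- seq(0, 40, length.out = 16)
  theta <- select_tradeoff_threshold(mk_curves(err, inc), grid)
  ne <- (err - min(err)) / diff(range(err))
  ni <- (inc - min(inc)) / diff(range(inc))
  expect_equal(theta, grid[which(ni >= ne)[1]]) # brute-force scan oracle

  # curves crafted so the normalized curves touch exactly at grid point
  # 0.90 (index 11): the rule returns the next grid value, 0.92
  ne2 <- c(seq(1, 0.3, length.out = 10), 0.25, seq(0.2, 0, length.out = 5))
  nw2 <- c(seq(0, 0.2, length.out = 10), 0.25, seq(0.5, 1, length.out = 5))
  expect_equal(
    select_tradeoff_threshold(mk_curves(5 + 25 * ne2, 40 * nw2), grid), 0.92)

  # error always above extensions: no crossing, min-gap fallback
  err3 <- seq(50, 30, length.out = 16)
  inc3 <- seq(0, 10, length.out = 16)
  ne3 <- (err3 - 30) / 20
  ni3 <- inc3 / 10
  expect_equal(select_tradeoff_threshold(mk_curves(err3, inc3), grid),
               grid[which.min(abs(ne3 - ni3))])

  # constant curve: midpoint fallback with a warning
  expect_warning(
    theta_c <- select_tradeoff_threshold(mk_curves(rep(10, 16), inc), grid),
    "constant")
  expect_equal(theta_c, grid[8])
})

test_that("majority vote smooths isolated errors with recency tie-breaks", {
  expect_equal(majority_vote(c(2, 1, 2, 2, 1), span = 1), c(2, 1, 2, 2, 1))
  s <- c(1, 1, 2, 1, 1, 1, 2, 1)
  expect_equal(majority_vote(s, span = 3), c(1, 1, 1, 1, 1, 1, 1, 1))
  # tie between classes 1 and 2 in the window: most recent tied class wins
  expect_equal(majority_vote(c(1, 2), span = 2)[2], 2)
  expect_equal(majority_vote(c(2, 1, 1, 2), span = 4)[4], 2)
  expect_equal(majority_vote(integer(0)), integer(0))
  # hand-simulated 9-span vote
  s2 <- c(rep(1, 8), 2, rep(1, 4))
  expect_equal(majority_vote(s2, span = 9), rep(1, 13))
})

test_that("Bayesian fusion pools log posteriors over the span", {
  P <- matrix(rep(c(0.7, 0.2, 0.1), 5), ncol = 3, byrow = TRUE)
  colnames(P) <- 1:3
  expect_equal(bayes_fusion(P), rep(1L, 5)) # repetition never flips argmax
  # eight confident class-1 vectors then one weak class-2 vector
  P2 <- rbind(matrix(rep(c(0.9, 0.05, 0.05), 8), ncol = 3, byrow = TRUE),
              c(0.3, 0.4, 0.3))
  colnames(P2) <- 1:3
  out <- bayes_fusion(P2, span = 9)
  expect_equal(out[9], 1L)
  # span 1 is the plain argmax
  expect_equal(bayes_fusion(P2, span = 1)[9], 2L)
  expect_error(bayes_fusion(matrix(c(0.5, 0.2), 1), span = 9), "summing")
})

test_that("MV and BF with span 1 equal the classical label stream", {
  m <- tiny_models()
  streams <- emgadapt:::.classical_streams(m$split$test, m$proj, m$lda,
                                           m$schedule, m$family,
                                           feature_config())
  for (s in streams) {
    expect_equal(majority_vote(s$labels, 1), s$labels)
    expect_equal(bayes_fusion(s$posteriors, 1), s$labels)
  }
})

test_that("the dataset split follows the 2/2/rest protocol", {
  split <- split_dataset(tiny_filtered())
  count_by_class <- function(trials) {
    table(factor(vapply(trials, function(t) t$class_id, 0L), levels = 1:4))
  }
  expect_true(all(count_by_class(split$training) == 2))
  expect_true(all(count_by_class(split$validation) == 2))
  expect_true(all(count_by_class(split$test) == 1))
  # training/validation take the earliest trials, test the remainder
  ids <- sort(vapply(split$training, function(t) t$trial_id, 0L))
  expect_equal(unique(ids), 1:2)
  small <- tiny_filtered()
  small$trials <- small$trials[vapply(small$trials, function(t)
    t$trial_id, 0L) <= 4]
  expect_error(split_dataset(small), "split")
})
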