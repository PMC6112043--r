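test_that("stubbed loop accepts at the first confident size and rejects at the max", {
  # crafted trace: Pr_Max 0.80 at 150 ms, 0.95 at 200 ms; theta 0.90
  P <- rbind(c(0.80, 0.15, 0.05), c(0.95, 0.03, 0.02),
             c(0.50, 0.30, 0.20), c(0.60, 0.30, 0.10), c(0.70, 0.20, 0.10))
  colnames(P) <- 1:3
  sizes <- seq(150, 350, by = 50)
  r <- emgadapt:::.threshold_trace(P, 0.90, sizes)
  expect_equal(r$status, "ACCEPTED")
  expect_equal(r$final_size_ms, 200)
  expect_equal(r$n_extensions, 1L)
  expect_equal(r$predicted, 1L)
  expect_equal(r$attempted, 2L)
})

test_that("trace invariants hold on 1000 randomized stub runs", {
  set.seed(11)
  sizes <- seq(150, 350, by = 50)
  for (i in 1:1000) {
    P <- random_trace()
    theta <- runif(1, 0.2, 1)
    r <- emgadapt:::.threshold_trace(P, theta, sizes)
    prm <- apply(P, 1, max)
    first <- which(prm >= theta)[1]
    if (is.na(first)) {
      expect_equal(r$status, "REJECTED")
      expect_equal(r$final_size_ms, 350)
      expect_true(all(prm < theta))
      expect_equal(r$attempted, 5L)
      expect_true(is.na(r$predicted))
    } else {
      expect_equal(r$status, "ACCEPTED")
      expect_equal(r$final_size_ms, sizes[first]) # first confident size
      expect_equal(r$n_extensions, first - 1L)
      expect_true(all(prm[seq_len(first - 1)] < theta))
      expect_gte(prm[first], theta)
      expect_equal(r$predicted, as.integer(which.max(P[first, ])))
    }
  }
})

test_that("the lazy per-anchor loop agrees with trace thresholding", {
  m <- tiny_models()
  trial <- m$split$test[[3]]
  tr <- posterior_traces(list(trial), m$proj, m$lda, m$schedule, m$family)
  for (theta in c(0.5, 0.8, 0.95, 0.999)) {
    log <- apply_threshold(tr, theta)
    for (i in c(1, 3, nrow(log$decisions))) {
      d <- decide(trial, log$decisions$start[i], m$proj, m$lda, theta,
                  m$schedule, m$family)
      expect_equal(d$status, log$decisions$status[i])
      expect_equal(d$final_size_ms, log$decisions$final_size_ms[i])
      if (d$status == "ACCEPTED") {
        expect_equal(d$predicted, log$decisions$predicted[i])
      }
      expect_equal(d$trace, log$traces[[i]], tolerance = 1e-12)
      # trace sizes strictly increase from the base in 50 ms steps
      expect_equal(as.numeric(rownames(d$trace)),
                   seq(150, by = 50, length.out = nrow(d$trace)))
    }
  }
  expect_error(decide(trial, 1, m$proj, m$lda, 1.5, m$schedule, m$family),
               "theta")
})

test_that("theta at or below 1/c reduces to plain base-window LDA", {
  m <- tiny_models()
  log <- run_session(m$split$test, m$proj, m$lda, theta = 1 / 4,
                     m$schedule, m$family)
  expect_true(all(log$decisions$status == "ACCEPTED"))
  expect_true(all(log$decisions$final_size_ms == 150))
  expect_true(all(log$decisions$n_extensions == 0))
  # decision-for-decision equality with the fixed-150 ms argmax
  for (trial in m$split$test[1:2]) {
    anchors <- enumerate_anchors(trial, m$schedule)
    X <- emgadapt:::.trial_feature_matrix(trial, anchors, 150, m$schedule,
                                          m$family, feature_config())
    plain <- pr_max(posteriors(m$lda, project(m$proj, X)))$class
    sub <- log$decisions[log$decisions$trial_id == trial$trial_id &
                           log$decisions$true_class == trial$class_id, ]
    expect_equal(sub$predicted, plain)
  }
})

test_that("theta = 1 rejects everything when posteriors stay below 1", {
  set.seed(21)
  stub <- structure(list(
    anchors = data.frame(start = seq(1, 2000, 100)[1:20], true_class = 1L,
                         trial_id = 1L, subject_id = "t"),
    traces = replicate(20, random_trace(), simplify = FALSE),
    schedule = window_schedule()), class = "posterior_traces")
  log <- apply_threshold(stub, theta = 1)
  expect_true(all(log$decisions$status == "REJECTED"))
  expect_true(all(log$decisions$final_size_ms == 350))
  expect_true(all(is.na(log$decisions$predicted)))
  expect_equal(pct_increased(log), 100)
})

test_that("sessions are deterministic and empty splits give empty logs", {
  m <- tiny_models()
  l1 <- run_session(m$split$test[1:2], m$proj, m$lda, 0.9, m$schedule,
                    m$family)
  l2 <- run_session(m$split$test[1:2], m$proj, m$lda, 0.9, m$schedule,
                    m$family)
  expect_identical(l1, l2)
  l0 <- run_session(list(), m$proj, m$lda, 0.9, m$schedule, m$family)
  expect_equal(nrow(l0$decisions), 0)
})

test_that("per-anchor final size is pathwise non-decreasing in theta", {
  tr <- tiny_traces()
  thetas <- c(0.5, 0.7, 0.85, 0.95, 0.99)
  finals <- vapply(thetas, function(th) {
    apply_threshold(tr, th)$decisions$final_size_ms
  }, numeric(length(tr$traces)))
  for (a in seq_len(nrow(finals))) {
    expect_true(all(diff(finals[a, ]) >= 0))
  }
})

test_that("accepted decisions never contradict their own trace", {
  log <- apply_threshold(tiny_traces(), 0.9)
  d <- log$decisions
  for (i in seq_len(nrow(d))) {
    P <- log$traces[[i]]
    prm <- apply(P, 1, max)
    if (d$status[i] == "ACCEPTED") {
      expect_gte(prm[length(prm)], 0.9)
      expect_equal(d$predicted[i],
                   as.integer(colnames(P)[which.max(P[nrow(P), ])]))
      if (nrow(P) > 1) expect_true(all(prm[-length(prm)] < 0.9))
    } else {
      expect_true(all(prm < 0.9))
      expect_equal(nrow(P), 5)
    }
    # never beyond the maximal size, never skipping a scheduled size
    expect_lte(nrow(P), 5)
  }
})

test_that("decision logs export with per-size Pr_Max columns", {
  log <- apply_threshold(tiny_traces(), 0.9)
  path <- file.path(tempdir(), "decisions.csv")
  write_decision_log(log, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), nrow(log$decisions))
  expect_true(all(paste0("pr_max_", seq(150, 350, 50)) %in% names(df)))
  # rejected rows carry all five sizes; accepted rows NA past the final one
  i <- which(df$status == "ACCEPTED" & df$final_size_ms == 150)[1]
  if (!is.na(i)) expect_true(is.na(df$pr_max_200[i]))
  unlink(path)
})
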