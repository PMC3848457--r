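test_that("smooth_loss is a centered moving average with shrunken edges", {
  expect_equal(smooth_loss(1:5, 5)[3], 3)
  expect_equal(smooth_loss(rep(7, 10), 5), rep(7, 10))
  s <- smooth_loss(c(0, 0, 10, 0, 0), 5)
  expect_equal(s[3], 2)                       # isolated spike attenuated 5x
  expect_equal(s[1], 10 / 3)                  # shrunken edge window (3 pts)
  expect_error(smooth_loss(1:3, 5), "exceeds")
  expect_error(smooth_loss(1:10, 4), "odd")
})

test_that("threshold_events extracts half-open above-threshold runs", {
  tr <- loss_trace(c(0, 0, 5, 5, 0), fs = 1, window = 1L)
  ev <- threshold_events(tr, 1)
  expect_equal(ev$onset, 2)
  expect_equal(ev$offset, 4)

  expect_equal(nrow(threshold_events(loss_trace(rep(0, 50), fs = 10,
                                                window = 1L), 0.1)), 0L)
  # tau below the global minimum flags the whole trace
  tr2 <- loss_trace(runif(40) + 1, fs = 10, window = 1L)
  ev2 <- threshold_events(tr2, 0.5)
  expect_equal(nrow(ev2), 1L)
  expect_equal(c(ev2$onset, ev2$offset), c(0, 4))
})

test_that("vote_channels counts channels against a ceiling quorum", {
  n <- 10L
  masks <- matrix(FALSE, n, 6)
  masks[3, 1:2] <- TRUE                        # 2 of 6 channels agree
  v <- vote_channels(masks, 1 / 3)             # quorum = ceil(2) = 2
  expect_true(v[3])
  expect_false(any(v[-3]))
  # unanimity is a logical AND
  masks2 <- cbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(vote_channels(masks2, 1), c(TRUE, FALSE, FALSE))
  expect_error(vote_channels(list()), "no channel masks")
})

test_that("voting is monotone in the required fraction", {
  set.seed(31)
  masks <- matrix(runif(500) > 0.6, 100, 5)
  prev <- rep(TRUE, 100)
  for (f in c(0.2, 0.4, 0.6, 0.8, 1)) {
    v <- vote_channels(masks, f)
    expect_true(all(v <= prev))                # raising f never adds samples
    prev <- v
  }
})

test_that("postprocess_events merges close events then prunes short ones", {
  # 100 ms gap -> merged
  ev <- event_list(c(1.0, 1.5), c(1.4, 1.9))
  out <- postprocess_events(ev)
  expect_equal(out$onset, 1.0)
  expect_equal(out$offset, 1.9)
  # isolated 200 ms -> removed
  expect_equal(nrow(postprocess_events(event_list(3.0, 3.2))), 0L)
  # 300 ms isolated -> untouched
  out3 <- postprocess_events(event_list(5.0, 5.3))
  expect_equal(out3$onset, 5.0)
  # merge happens before pruning: a 200 ms fragment 100 ms from a long
  # event survives via the merge
  ev4 <- event_list(c(1.0, 2.1), c(2.0, 2.3))
  out4 <- postprocess_events(ev4)
  expect_equal(nrow(out4), 1L)
  expect_equal(out4$offset, 2.3)
})

test_that("postprocess_events is idempotent and keeps intervals disjoint", {
  set.seed(32)
  for (i in 1:25) {
    ev <- random_event_list(30, 128)
    out <- postprocess_events(ev)
    again <- postprocess_events(out)
    expect_equal(out$onset, again$onset)
    expect_equal(out$offset, again$offset)
    if (nrow(out) > 1L)
      expect_true(all(out$onset[-1L] >= out$offset[-nrow(out)]))
  }
})

test_that("above-threshold sample sets shrink as the threshold rises", {
  set.seed(33)
  tr <- loss_trace(rexp(400), fs = 100)
  taus <- sort(runif(10, 0, 3))
  prev <- rep(TRUE, 400)
  for (tau in taus) {
    m <- tr$psi_smooth > tau
    expect_true(all(m <= prev))
    prev <- m
  }
})

test_that("optimize_threshold attains F = 1 on separable traces", {
  truth <- event_list(c(5, 12, 20), c(6, 13.5, 20.5), source = "truth")
  traces <- separable_traces(truth, total_s = 30, fs = 64)
  opt <- optimize_threshold(traces, truth, beta = 2, fuzzy_s = 0)
  expect_equal(opt$fbeta, 1)
  expect_gt(opt$tau, 0.01)                    # above the background loss
  expect_lte(opt$tau, 10)
  expect_equal(opt$events$onset, truth$onset)
  expect_equal(opt$events$offset, truth$offset)
  expect_error(optimize_threshold(traces, event_list(), beta = 2),
               "empty")
})

test_that("recall equals flagged time fraction when truth covers all time", {
  fs <- 50; total <- 20
  truth <- event_list(0, total, source = "truth")
  set.seed(34)
  tr <- loss_trace(rexp(total * fs), fs = fs, window = 1L)
  tau <- 1
  det <- postprocess_events(threshold_events(tr, tau),
                            merge_gap_s = 0, min_dur_s = 0)
  cmp <- compare_labels(truth, det, total_dur_s = total, fs = fs)
  detected_time <- sum(det$offset - det$onset)
  expect_equal(cmp$recall, detected_time / total)
  expect_equal(cmp$precision, 1)              # everything flagged is true
})
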