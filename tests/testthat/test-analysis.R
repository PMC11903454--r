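test_that("detector finds a lone noise-free transient and ignores linear trends", {
  par <- trace_params(noise_sd = 0, drift_amp = 0)
  tr <- events_to_trace(100, par, 600)
  for (mode in c("linear", "segmented")) {
    d <- detect_contractions(tr, detector_params(detrend = mode))
    expect_equal(length(d[[1]]), 1)
    expect_lt(abs(d[[1]] - 100), 3)
    # adding an arbitrary linear ramp changes nothing
    tr2 <- tr
    tr2$values[, 1] <- tr2$values[, 1] + 0.05 * tr2$times_s - 7
    expect_equal(detect_contractions(tr2, detector_params(detrend = mode)), d)
  }
  expect_error(detect_contractions(
    structure(list(times_s = c(0, 1), values = matrix(0, 2, 1),
                   region_labels = "R", fs_hz = 1),
              class = "intensity_trace")), "3 samples")
})

test_that("72-event fragment round-trips exactly through the detector at default SNR", {
  cfg <- make_chain(50)
  s <- simulate_chain(cfg, 3600)
  tr <- events_to_trace(s$events$time_s, trace_params(seed = 5), 3610)
  d <- detect_contractions(tr)[[1]]
  expect_equal(length(d), 72)
  expect_true(all(vapply(s$events$time_s,
                         function(t0) any(abs(d - t0) <= 3), TRUE)))
})

test_that("wave assignment chains adjacent-region events and classifies kinds", {
  # a lone firing is an active singleton
  asg <- assign_waves(list(A = 100, B = numeric(0)), 1, 0.5)
  expect_equal(nrow(asg$waves), 1)
  expect_equal(asg$waves$range, 1)
  expect_equal(asg$events$kind, "active")
  # a 3-region chain with 1-s lags is one wave, origin first region
  asg2 <- assign_waves(list(A = 100, B = 101, C = 102), 1, 0.5)
  expect_equal(nrow(asg2$waves), 1)
  expect_equal(asg2$waves$origin_label, "A")
  expect_equal(asg2$waves$range, 3)
  expect_equal(sum(asg2$events$kind == "passive"), 2)
  # events outside the lag tolerance stay separate
  asg3 <- assign_waves(list(A = 100, B = 104), 1, 0.5)
  expect_equal(nrow(asg3$waves), 2)
})

test_that("pipeline recovers rates, labels and origins from an intact bundle", {
  b <- generate_bundle("intact", "e10", seed = 3, duration_h = 1)
  det <- detect_contractions(b$trace)
  truth_counts <- table(factor(b$truth$events$region_label,
                               levels = b$trace$region_labels))
  expect_equal(unname(vapply(det, length, 0L)),
               unname(as.integer(truth_counts)))
  asg <- assign_waves(det)
  sc <- score_assignment(asg, b$truth)
  expect_equal(sc$matched, sc$n_events)      # no false positives
  expect_gte(sc$label_accuracy, 0.95)
  expect_gte(sc$origin_accuracy, 0.90)
  # recovered per-region totals within 2 events/h of ground truth
  rr <- summarize_rates(asg$events, c(0, 3600), labels = b$trace$region_labels)
  tt <- summarize_rates(b$truth$events, c(0, 3600),
                        labels = b$trace$region_labels)
  expect_true(all(abs(rr$total_per_h - tt$total_per_h) <= 2))
})

test_that("rate summaries count by kind over the window", {
  ev <- data.frame(time_s = seq(50, 3600, by = 50),
                   region_label = "R1", kind = "active")
  rs <- summarize_rates(ev, c(0, 3600))
  expect_equal(rs$active_per_h, 72)
  expect_equal(rs$total_per_h, 72)
  half <- summarize_rates(ev, c(0, 1800))
  expect_equal(half$active_per_h, 72)
  expect_error(summarize_rates(ev, c(100, 100)), "empty")
})

test_that("range census summarizes per-origin range and per-region exposure", {
  # single source, survival 1: all waves span the whole 5-chain
  cfg <- make_chain(c(60, rep(5000, 4)))
  s <- simulate_chain(cfg, 3610)  # margin lets the final wave complete
  rc <- range_census(s)
  expect_equal(rc$by_origin$mean_range[1], 5)
  expect_equal(rc$by_origin$n_waves[1], 60)
  # origin excluded from its own exposure count
  expect_equal(rc$exposure$n_passing, c(0, 60, 60, 60, 60))
  # detector-side census: all-singleton assignment has mean range 1
  asg <- assign_waves(list(A = c(100, 300), B = 500), 1, 0.5)
  rca <- range_census(asg)
  expect_true(all(rca$by_origin$mean_range == 1))
})

test_that("interruption delay is recovered from event times", {
  est <- estimate_delay(c(-100, -50, 0, 80.75), tap_time_s = 40)
  expect_equal(est$T_s, 50)
  expect_equal(est$tau_s, 80.75)
  expect_equal(est$delay_s, 30.75)
  # zero-efficacy fragment: unchanged interval
  est0 <- estimate_delay(c(-100, -50, 0, 50), tap_time_s = 40)
  expect_equal(est0$delay_s, 0)
  # the forced transient itself is excluded around the tap time
  est2 <- estimate_delay(c(-100, -50, 0, 40.2, 80.75), tap_time_s = 40)
  expect_equal(est2$delay_s, 30.75)
  expect_error(estimate_delay(c(0, 30), 40), "bracketed")
})

test_that("end-to-end tap trace analysis matches the simulated delay", {
  bt <- generate_bundle("tap", "e12", seed = 4)
  d <- detect_contractions(bt$trace)[[1]]
  est <- estimate_delay(d, bt$tap$tap_time_s)
  # 1-Hz sampling quantizes each event time to the nearest second
  expect_lt(abs(est$delay_s - bt$tap$delay_s), 2.5)
})

test_that("paired t statistic matches the classical formula and conventions", {
  expect_equal(paired_t(1:5, 1:5), list(t = 0, p = 1, df = 4, mean_diff = 0))
  res <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_identical(res$t, Inf)
  expect_identical(res$p, 0)
  x <- c(3, 1, 5, 2, 4, 6); y <- x - c(2, -1, 3, 0, 1, 1)
  res2 <- paired_t(x, y)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(res2$t, unname(ref$statistic))
  expect_equal(res2$p, ref$p.value)
  expect_equal(res2$df, unname(ref$parameter))
  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(1:3, 1:4), "equal length")
})
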