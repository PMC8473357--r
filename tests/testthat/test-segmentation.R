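test_that("heel strikes are found at the maxima of heel minus pelvis", {
  fs <- 200
  t <- seq(0, 11 - 1 / fs, by = 1 / fs)
  d <- sin(2 * pi * t / 1.1)          # period 1.1 s, 10 full cycles
  hs <- detect_heel_strikes(d, numeric(length(d)), fs)
  expect_length(hs, 10)
  expected <- 1.1 * (seq_len(10) - 1) + 1.1 / 4   # sinusoid maxima
  expect_lte(max(abs(hs - expected)), 1 / fs)
})

test_that("constant traces yield no events and short traces are safe", {
  expect_identical(detect_heel_strikes(rep(1, 500), rep(0, 500), 100), numeric(0))
  expect_identical(detect_heel_strikes(1, 0, 100), numeric(0))
  expect_error(detect_heel_strikes(1:10, 1:9, 100), "equal length")
})

test_that("the refractory interval suppresses close secondary peaks", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  d <- sin(2 * pi * t) + 0.4 * sin(2 * pi * 3 * t)  # secondary humps
  hs <- detect_heel_strikes(d, numeric(length(d)), fs, refractory_s = 0.6)
  expect_true(all(diff(hs) >= 0.6))
})

test_that("cycles are labelled steady or transition by their label span", {
  fs <- 100
  events <- (0:5) * 1.0
  labels <- rep("LW", 601)
  cyc <- segment_cycles(events, labels, fs)
  expect_identical(nrow(cyc), 5L)
  expect_true(all(cyc$label == "LW"))
  expect_true(all(is.na(cyc$next_mode)))

  # switch strictly inside the third cycle -> that cycle is a transition
  labels2 <- c(rep("LW", 250), rep("SA", 351))
  cyc2 <- segment_cycles(events, labels2, fs)
  expect_identical(cyc2$label, c("LW", "LW", "TRANSITION", "SA", "SA"))
  expect_identical(cyc2$next_mode[3], "SA")

  # switch exactly on a heel strike -> half-open cycles stay steady
  labels3 <- c(rep("LW", 300), rep("SA", 301))
  cyc3 <- segment_cycles(events, labels3, fs)
  expect_false(any(cyc3$label == "TRANSITION"))
  expect_identical(cyc3$label, c("LW", "LW", "LW", "SA", "SA"))

  expect_identical(nrow(segment_cycles(1.0, labels, fs)), 0L)
})

test_that("cycles tile the walking span and transitions count the switches", {
  fs <- 100
  set.seed(7)
  for (rep in 1:20) {
    n_ev <- sample(4:9, 1)
    events <- cumsum(c(0, runif(n_ev - 1, 0.8, 1.4)))
    events <- round(events * fs) / fs
    n <- round(max(events) * fs) + 1
    # random legal-ish label track with switches strictly inside cycles
    n_switch <- sample(1:3, 1)
    switch_at <- sort(sample(which((0:(n - 1)) / fs > 0.1 &
                                     (0:(n - 1)) / fs < max(events) - 0.1), n_switch))
    switch_at <- switch_at[!((switch_at - 1) / fs) %in% events]
    modes <- sample(locomotion_modes(), length(switch_at) + 1)
    labels <- rep(modes[1], n)
    for (k in seq_along(switch_at)) labels[switch_at[k]:n] <- modes[k + 1]
    cyc <- segment_cycles(events, labels, fs)
    # tiling: consecutive cycles share boundaries, no overlap
    expect_identical(cyc$start_s[-1], cyc$end_s[-nrow(cyc)])
    # a cycle is a transition iff a label switch falls strictly inside it
    expected <- vapply(seq_len(nrow(cyc)), function(k) {
      start_i <- round(cyc$start_s[k] * fs) + 1
      end_i <- round(cyc$end_s[k] * fs) + 1
      any(switch_at > start_i & switch_at <= end_i - 1)
    }, logical(1))
    expect_identical(cyc$label == "TRANSITION", expected)
  }
})

test_that("detected events match simulator truth on synthetic trials", {
  trial <- fixture_trial()
  hs <- detect_heel_strikes(trial$markers[, "heel"], trial$markers[, "pelvis"],
                            trial$fs)
  truth <- trial$truth_events$time_s[trial$truth_events$kind == "heel_strike"]
  expect_length(hs, length(truth))       # recall and precision both 1
  expect_lte(max(abs(hs - truth)) * 1000, 5)
})

test_that("steady mask excises exactly the cycle before each onset", {
  trial <- fixture_trial()
  mask <- steady_state_mask(trial)
  tw <- transition_windows(trial)
  expect_identical(nrow(tw), sum(trial$truth_events$kind == "mode_onset"))
  fs <- trial$fs
  for (k in seq_len(nrow(tw))) {
    pre <- round(tw$prev_hs_s[k] * fs) + 1
    on <- round(tw$onset_s[k] * fs) + 1
    expect_true(all(!mask[pre:(on - 1)]))
    expect_true(mask[on])
    # the transition window is one gait cycle wide
    expect_lt(tw$onset_s[k] - tw$prev_hs_s[k], 1.5 * trial$config$cycle_duration_s)
  }
})
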