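test_that("perfect agreement scores 100 on all steady metrics", {
  truth <- as_mode(rep(locomotion_modes(), each = 20))
  rep <- score_steady(truth, truth)
  expect_equal(rep$CA, 100)
  expect_equal(rep$SE_mean, 100)
  expect_equal(rep$SP_mean, 100)
  expect_equal(sum(rep$confusion), 140)
})

test_that("binary toy counts reproduce the SE/SP definitions", {
  # class A: TP = 8, FN = 2; class B as rest: TN = 9, FP = 1
  truth <- factor(c(rep("A", 10), rep("B", 10)), levels = c("A", "B"))
  pred <- factor(c(rep("A", 8), rep("B", 2), rep("B", 9), "A"),
                 levels = c("A", "B"))
  rep <- score_steady(pred, truth)
  expect_equal(unname(rep$SE_per_class["A"]), 80)
  expect_equal(unname(rep$SP_per_class["A"]), 90)
  expect_equal(rep$CA, 100 * 17 / 20)
})

test_that("a constant predictor on balanced truth scores CA = 100/7", {
  truth <- as_mode(rep(locomotion_modes(), each = 10))
  pred <- as_mode(rep("LW", 70))
  rep <- score_steady(pred, truth)
  expect_equal(rep$CA, 100 / 7)
})

test_that("steady metrics match an independent tally on random labels", {
  modes <- locomotion_modes()
  set.seed(30)
  for (rep_i in 1:20) {
    n <- 1000
    truth <- as_mode(sample(modes, n, replace = TRUE))
    pred <- as_mode(sample(modes, n, replace = TRUE))
    rep <- score_steady(pred, truth)
    oracle <- tally_metrics(truth, pred, modes)
    expect_equal(rep$CA, oracle$CA)
    expect_equal(unname(rep$SE_per_class), oracle$SE)
    expect_equal(unname(rep$SP_per_class), oracle$SP)
    # conservation: row sums are the per-class truth counts
    expect_equal(as.integer(rowSums(rep$confusion)),
                 as.integer(table(truth)))
    expect_equal(rep$CA, 100 * sum(diag(rep$confusion)) / sum(rep$confusion))
  }
})

test_that("the steady mask is honoured and cannot be empty", {
  truth <- as_mode(rep("LW", 10))
  pred <- as_mode(c(rep("SA", 5), rep("LW", 5)))
  rep <- score_steady(pred, truth, steady_mask = c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(rep$CA, 100)
  expect_error(score_steady(pred, truth, steady_mask = rep(FALSE, 10)),
               "no samples")
  expect_error(score_steady(pred, truth[1:5]), "equal length")
})

make_transitions <- function(onset, prev_hs, next_mode, steady_end) {
  data.frame(onset_s = onset, prev_hs_s = prev_hs, next_mode = next_mode,
             steady_end_s = steady_end, stringsAsFactors = FALSE)
}

test_that("an early, held prediction yields a negative response time", {
  fs <- 1000
  # LW until 1.7 s, SA output from 1.7 s; true onset at 2.0 s
  out <- c(rep("LW", 1700), rep("SA", 1300))
  trace <- manual_trace(out, fs)
  tw <- make_transitions(2.0, 1.0, "SA", 3.0)
  rep <- score_transitions(trace, tw)
  expect_equal(rep$PA, 100)
  expect_equal(rep$outcomes$RT_ms, -300, tolerance = 1e-6)
  expect_true(rep$outcomes$predicted_before)
})

test_that("a transient flicker cannot claim an early prediction", {
  fs <- 1000
  out <- c(rep("LW", 1200), rep("SA", 100), rep("LW", 500),  # flicker
           rep("SA", 1200))                                  # real switch at 1.8 s
  trace <- manual_trace(out, fs)
  tw <- make_transitions(2.0, 1.0, "SA", 3.0)
  rep <- score_transitions(trace, tw)
  # prediction time is the start of the run that persists until onset
  expect_equal(rep$outcomes$RT_ms, -200, tolerance = 1e-6)
})

test_that("late but correct recognition counts with positive RT", {
  fs <- 1000
  out <- c(rep("LW", 2300), rep("SA", 700))
  trace <- manual_trace(out, fs)
  tw <- make_transitions(2.0, 1.0, "SA", 3.0)
  rep <- score_transitions(trace, tw)
  expect_equal(rep$PA, 100)
  expect_equal(rep$outcomes$RT_ms, 300, tolerance = 1e-6)
  expect_false(rep$outcomes$predicted_before)
})

test_that("a never-recognised transition is excluded from PA and RT", {
  fs <- 1000
  out <- rep("LW", 3000)
  trace <- manual_trace(out, fs)
  tw <- make_transitions(c(1.0, 2.0), c(0.2, 1.0), c("SA", "LW"), c(2.0, 3.0))
  rep <- score_transitions(trace, tw)
  expect_equal(rep$PA, 50)                     # only the LW return "predicted"
  expect_true(is.na(rep$outcomes$RT_ms[1]))
  # and with no transitions at all PA is absent, not zero
  empty <- score_transitions(trace, make_transitions(numeric(0), numeric(0),
                                                     character(0), numeric(0)))
  expect_true(is.na(empty$PA))
})
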