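test_that("mode templates are deterministic, mode-distinct and well-shaped", {
  s <- mode_templates("S", 100)
  expect_true(all(s$emg >= 0))
  expect_true(all(s$emg <= 0.1))               # sitting: near-baseline EMG
  expect_equal(apply(s$accel, 2, stats::sd), rep(0, 21),
               ignore_attr = TRUE)             # quasi-static acceleration
  lw <- mode_templates("LW", 100)
  sa <- mode_templates("SA", 100)
  expect_gt(max(abs(lw$emg - sa$emg)), 0)
  expect_identical(mode_templates("LW", 100), mode_templates("LW", 100))
  expect_error(mode_templates("XX", 100), "unknown")
  expect_error(mode_templates("LW", 4), ">= 8")
})

test_that("every mode pair is separated beyond the default noise level", {
  modes <- locomotion_modes()
  tpl <- lapply(modes, mode_templates, n_points = 64)
  names(tpl) <- modes
  for (i in 1:6) for (j in (i + 1):7) {
    emg_margin <- max(abs(tpl[[i]]$emg - tpl[[j]]$emg))
    acc_margin <- max(abs(tpl[[i]]$accel - tpl[[j]]$accel))
    expect_gt(emg_margin, 0.05)   # > additive EMG noise SD (0.005)
    expect_gt(acc_margin, 0.05)   # > accel noise SD (0.05)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(task = 1, n_cycles_per_mode = 2, seed = 11)
  a <- simulate_trial(cfg)
  b <- simulate_trial(cfg)
  expect_identical(a$emg, b$emg)
  expect_identical(a$accel, b$accel)
  expect_identical(a$markers, b$markers)
  expect_identical(a$truth_labels, b$truth_labels)
  expect_identical(a$truth_events, b$truth_events)
})

test_that("trial structure is internally consistent", {
  trial <- fixture_trial()
  n <- nrow(trial$emg)
  expect_identical(dim(trial$emg), c(n, 14L))
  expect_identical(dim(trial$accel), c(n, 21L))
  expect_identical(dim(trial$markers), c(n, 3L))
  expect_length(trial$truth_labels, n)
  ev <- trial$truth_events
  hs <- ev$time_s[ev$kind == "heel_strike"]
  n_cycles <- length(trial$config$script) * trial$config$n_cycles_per_mode
  expect_length(hs, n_cycles + 1L)  # strikes at both ends of the cycle chain
  # labels change only at mode onsets, and onsets fall on heel strikes
  onsets <- ev$time_s[ev$kind == "mode_onset"]
  switches <- which(diff(as.integer(trial$truth_labels)) != 0)
  expect_equal(switches / trial$fs, onsets, tolerance = 1e-9)
  expect_true(all(vapply(onsets, function(o) any(abs(hs - o) < 1e-9), logical(1))))
})

test_that("EMG envelope switches lead the mode onset by emg_lead_ms", {
  trial <- fixture_trial()  # emg_lead_ms = 300 at fs = 2000
  fs <- trial$fs
  script <- trial$config$script
  ev <- trial$truth_events
  onsets <- ev[ev$kind == "mode_onset", ]
  phase <- trial$phase %% 1
  for (k in seq_len(nrow(onsets))) {
    onset_i <- round(onsets$time_s[k] * fs) + 1L
    old_mode <- script[k]
    look <- seq.int(onset_i - round(0.45 * fs), onset_i)
    counterfactual <- gaitfusion:::emg_envelope(old_mode, phase[look])
    dev <- rowSums(abs(trial$emg_envelope[look, ] - counterfactual)) > 1e-8
    first_dev <- look[which(dev)[1]]
    expect_lte(abs(onset_i - first_dev - 600), 1)
  }
})

test_that("a zero EMG lead makes the EMG and kinematic switches coincide", {
  trial <- simulate_trial(sim_config(task = 1, n_cycles_per_mode = 2,
                                     emg_lead_ms = 0, seed = 5,
                                     keep_envelope = TRUE))
  fs <- trial$fs
  ev <- trial$truth_events
  onsets <- ev[ev$kind == "mode_onset", ]
  phase <- trial$phase %% 1
  for (k in seq_len(nrow(onsets))) {
    onset_i <- round(onsets$time_s[k] * fs) + 1L
    old_mode <- trial$config$script[k]
    look <- seq.int(onset_i - round(0.3 * fs), min(onset_i + round(0.3 * fs), nrow(trial$emg)))
    counterfactual <- gaitfusion:::emg_envelope(old_mode, phase[look])
    dev <- rowSums(abs(trial$emg_envelope[look, ] - counterfactual)) > 1e-8
    first_dev <- look[which(dev)[1]]
    expect_lte(abs(first_dev - onset_i), 1)
  }
})

test_that("the EMG carrier concentrates its power in the 30-300 Hz band", {
  trial <- simulate_trial(sim_config(script = "S", n_cycles_per_mode = 4,
                                     emg_noise_snr = Inf, seed = 9))
  # sitting keeps the envelope tonic, so channel 1 is a scaled carrier
  x <- trial$emg[, 1]
  spec <- stats::spec.pgram(x, taper = 0, plot = FALSE)
  freq_hz <- spec$freq * trial$fs
  in_band <- freq_hz >= 30 & freq_hz <= 300
  expect_gte(sum(spec$spec[in_band]) / sum(spec$spec), 0.9)
})

test_that("marker traces peak at the true heel strikes", {
  trial <- fixture_trial()
  hs <- detect_heel_strikes(trial$markers[, "heel"], trial$markers[, "pelvis"],
                            trial$fs)
  truth <- trial$truth_events$time_s[trial$truth_events$kind == "heel_strike"]
  expect_length(hs, length(truth))
  expect_lte(max(abs(hs - truth)), 0.005)
})

test_that("illegal scripts and invalid configs are rejected", {
  expect_error(sim_config(script = c("S", "SA")), "S -> SA")
  expect_error(sim_config(task = 1, fs = 0), "fs")
  expect_error(sim_config(task = 1, emg_lead_ms = -5), "emg_lead_ms")
  expect_error(sim_config(task = 1, emg_lead_ms = 2000),
               "fit inside one gait cycle")
})
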