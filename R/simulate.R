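#' @name simulate
#' @title Synthetic gait-trial generator
#'
#' @description
#' Seedable generator of multi-channel locomotion trials with the
#' statistical structure the recognition pipeline assumes: 14 sEMG
#' channels modelled as a phase-locked activation envelope riding on
#' band-limited (30-300 Hz) carrier noise, 21 linear-acceleration
#' channels (7 tri-axial placements) modelled as smooth gait-periodic
#' waveforms with per-mode gravity offsets, and three anterior marker
#' traces (heel, toe, pelvis) whose heel-minus-pelvis coordinate peaks at
#' every heel strike.  At each scripted mode transition the EMG envelopes
#' switch to the next mode's pattern a configurable interval *before* the
#' acceleration waveforms and the ground-truth mode label do, emulating
#' the electromechanical lead of muscle activation over limb movement
#' that makes pre-onset locomotion prediction possible.
NULL

emg_channel_names <- function() {
  muscles <- c("RF", "VL", "BF", "Sem", "TA", "MG", "LG")
  c(paste0(muscles, "_R"), paste0(muscles, "_L"))
}

accel_channel_names <- function() {
  segs <- c("pelvis", "thigh_R", "thigh_L", "shank_R", "shank_L",
            "foot_R", "foot_L")
  paste0(rep(segs, each = 3), "_", rep(c("x", "y", "z"), times = 7))
}

# Per-mode 2-D "posture coordinates" used to grade the accelerometer
# gravity offsets: distinct for every mode, deliberately close for modes
# adjacent in the legality graph so that acceleration separates modes more
# weakly than the EMG tonic code does.
mode_coords <- function() {
  cbind(
    u = c(S = -1.0, ST = -0.6, LW = -0.2, SA = 0.2, SD = 0.2,
          RA = 0.6, RD = 0.6),
    v = c(S = 0.0, ST = 0.0, LW = 0.0, SA = 0.3, SD = -0.3,
          RA = 0.15, RD = -0.15)
  )
}

# Wrapped raised-cosine burst centred at phase `centre` with full width
# `width`; zero outside the burst, peak 1 at the centre.
raised_cosine <- function(phase, centre, width) {
  d <- (phase - centre) %% 1
  d <- pmin(d, 1 - d)
  ifelse(d < width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

# EMG activation envelopes (mV) for one mode at the given cycle phases.
# The proximal channels of each leg (1-3 right, 8-10 left) carry a tonic
# 3-bit postural code (bits of mode code + 1), mirrored bilaterally as
# postural co-activation is; it distinguishes every mode pair, including
# the quasi-static S and ST.  The remaining channels carry phase-locked
# raised-cosine bursts for the five ambulation modes.
emg_envelope <- function(mode, phase) {
  m <- mode_code(mode)
  n <- length(phase)
  env <- matrix(0.02, n, 14, dimnames = list(NULL, emg_channel_names()))
  for (j in 1:3) {
    if (bitwAnd(m + 1L, bitwShiftL(1L, j - 1L)) > 0L) {
      env[, j] <- env[, j] + 0.06
      env[, j + 7L] <- env[, j + 7L] + 0.06
    }
  }
  if (m >= 2L) {  # ambulation modes have phasic bursts
    for (j in c(4:7, 11:14)) {
      amp <- 0.35 + 0.25 * sin(0.9 * j + 1.7 * m)
      ctr <- (0.07 * j + 0.15 * m) %% 1
      wid <- 0.25 + 0.15 * ((0.31 * j + 0.17 * m) %% 1)
      env[, j] <- env[, j] + amp * raised_cosine(phase, ctr, wid)
    }
  }
  env
}

# Linear-acceleration templates (m/s^2) for one mode: per-channel constant
# gravity/posture offset plus, for ambulation modes, a fundamental and a
# second harmonic locked to the gait cycle.
accel_template <- function(mode, phase) {
  m <- mode_code(mode)
  uv <- mode_coords()[m + 1L, ]
  n <- length(phase)
  acc <- matrix(0, n, 21, dimnames = list(NULL, accel_channel_names()))
  for (a in 1:21) {
    offset <- 3 * cos(0.7 * a) +
      0.4 * (uv[["u"]] * cos(0.6 * a) + uv[["v"]] * sin(0.8 * a))
    col <- rep(offset, n)
    if (m >= 2L) {
      amp <- 0.6 + 0.3 * sin(0.5 * a + 1.3 * m)
      col <- col + amp * cos(2 * pi * phase + 0.4 * a + 0.9 * m) +
        0.35 * amp * cos(4 * pi * phase + 1.1 * a + 0.5 * m)
    }
    acc[, a] <- col
  }
  acc
}

#' Per-mode channel templates over one normalized gait cycle
#'
#' Deterministic, mode-distinct envelope curves: nonnegative EMG
#' activation envelopes (14 channels, mV) and signed acceleration
#' waveforms (21 channels, m/s^2) sampled at `n_points` evenly spaced
#' phases of one gait cycle.  Distinct modes differ in at least one
#' channel by a margin exceeding the generator's default noise levels.
#'
#' @param mode a locomotion mode code (see [locomotion_modes()]).
#' @param n_points number of phase samples, at least 8.
#' @return List with `phase` (length `n_points`), `emg`
#'   (`n_points` x 14) and `accel` (`n_points` x 21).
#' @export
#' @examples
#' tpl <- mode_templates("LW", 100)
#' matplot(tpl$phase, tpl$emg, type = "l")
mode_templates <- function(mode, n_points) {
  mode <- as.character(as_mode(mode))
  if (length(mode) != 1L || is.na(mode)) stop("mode must be a single code")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 8L) stop("n_points must be >= 8")
  phase <- seq(0, 1, length.out = n_points + 1L)[seq_len(n_points)]
  list(phase = phase,
       emg = emg_envelope(mode, phase),
       accel = accel_template(mode, phase))
}

#' Simulation configuration
#'
#' Parameters of one synthetic locomotion trial.  Defaults are the
#' package's study conditions: 2000 Hz sampling, 1.1 s gait cycles with
#' 5% duration jitter, 3 cycles per steady segment, a 300 ms EMG
#' activation lead over the kinematic change at each transition, and a
#' 100 ms cross-fade ramp at every template switch.
#'
#' @param task scripted task number 1-5 (see [task_script()]); ignored
#'   when `script` is supplied.
#' @param script ordered character vector of mode codes; consecutive
#'   modes must be legal under `rules`.
#' @param fs sampling rate in Hz.
#' @param cycle_duration_s mean gait-cycle duration in seconds.
#' @param cycle_jitter SD of per-cycle duration jitter, as a fraction of
#'   `cycle_duration_s`.
#' @param n_cycles_per_mode full gait cycles per steady segment.
#' @param emg_lead_ms interval (ms) by which the EMG envelope switch
#'   precedes the acceleration/label switch at each transition.
#' @param transition_ramp_ms duration (ms) of the linear cross-fade that
#'   starts at each switch instant.
#' @param emg_noise_snr ratio of the nominal envelope scale (0.1 mV) to
#'   the additive wide-band noise SD; `Inf` disables the additive noise.
#' @param accel_noise_sd SD (m/s^2) of additive Gaussian noise on the
#'   acceleration channels.
#' @param seed RNG seed.
#' @param keep_envelope store the noise-free EMG envelope matrix in the
#'   trial (useful for timing diagnostics; off by default to save memory).
#' @param rules transition-legality table used to validate the script.
#' @return A `sim_config` list.
#' @export
sim_config <- function(task = 2L, script = task_script(task), fs = 2000,
                       cycle_duration_s = 1.1, cycle_jitter = 0.05,
                       n_cycles_per_mode = 3L, emg_lead_ms = 300,
                       transition_ramp_ms = 100, emg_noise_snr = 20,
                       accel_noise_sd = 0.05, seed = 1L,
                       keep_envelope = FALSE, rules = default_rules()) {
  stopifnot_scalar_num(fs, "fs")
  stopifnot_scalar_num(cycle_duration_s, "cycle_duration_s")
  stopifnot_scalar_num(emg_lead_ms, "emg_lead_ms", positive = FALSE)
  if (emg_lead_ms < 0) stop("emg_lead_ms must be >= 0")
  stopifnot_scalar_num(transition_ramp_ms, "transition_ramp_ms", positive = FALSE)
  if (transition_ramp_ms < 0) stop("transition_ramp_ms must be >= 0")
  if (n_cycles_per_mode < 1) stop("n_cycles_per_mode must be >= 1")
  script <- as.character(as_mode(script))
  check_script_legal(script, rules)
  min_cycle <- cycle_duration_s * (1 - 2 * cycle_jitter)
  if ((emg_lead_ms + transition_ramp_ms) / 1000 >= min_cycle) {
    stop("emg_lead_ms + transition_ramp_ms must fit inside one gait cycle")
  }
  structure(list(
    script = script, fs = fs, cycle_duration_s = cycle_duration_s,
    cycle_jitter = cycle_jitter, n_cycles_per_mode = as.integer(n_cycles_per_mode),
    emg_lead_ms = emg_lead_ms, transition_ramp_ms = transition_ramp_ms,
    emg_noise_snr = emg_noise_snr, accel_noise_sd = accel_noise_sd,
    seed = as.integer(seed), keep_envelope = isTRUE(keep_envelope)
  ), class = "sim_config")
}

# Blend per-segment template tracks with a linear cross-fade of duration
# ramp_s starting at each switch time.  eval_fun(mode, phase) returns a
# samples x channels matrix.
blend_segments <- function(t, phase, script, switch_times, ramp_s, eval_fun) {
  n_seg <- length(script)
  region <- findInterval(t, switch_times) + 1L  # 1..n_seg
  out <- NULL
  for (s in seq_len(n_seg)) {
    idx <- which(region == s)
    if (!length(idx)) next
    block <- eval_fun(script[s], phase[idx])
    if (is.null(out)) {
      out <- matrix(0, length(t), ncol(block), dimnames = list(NULL, colnames(block)))
    }
    if (s > 1L && ramp_s > 0) {
      t0 <- switch_times[s - 1L]
      fade <- which(t[idx] < t0 + ramp_s)
      if (length(fade)) {
        w <- (t[idx][fade] - t0) / ramp_s
        old <- eval_fun(script[s - 1L], phase[idx][fade])
        block[fade, ] <- (1 - w) * old + w * block[fade, ]
      }
    }
    out[idx, ] <- block
  }
  out
}

#' Simulate one locomotion trial
#'
#' Generates a synchronized multi-channel trial following the scripted
#' mode sequence of `config`.  EMG channels are the mode's activation
#' envelope multiplied by band-limited (30-300 Hz) unit-variance carrier
#' noise plus a small wide-band component; acceleration channels are the
#' mode's waveform template plus Gaussian noise.  At each scripted
#' transition the EMG envelopes begin their cross-fade to the next mode's
#' pattern `emg_lead_ms` before the acceleration templates and the
#' ground-truth label switch at the mode-onset heel strike.  Identical
#' configurations (including seed) produce bit-identical trials.
#'
#' @param config a [sim_config()] object.
#' @return A `gait_trial`: list with `emg` (T x 14), `accel` (T x 21),
#'   `markers` (T x 3: heel, toe, pelvis anterior positions), `fs`,
#'   `truth_labels` (length-T mode factor), `truth_events` (data frame of
#'   heel_strike / mode_onset events), `phase` (continuous cycle phase)
#'   and the originating `config`.
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(task = 1, n_cycles_per_mode = 2, seed = 7))
#' trial
simulate_trial <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config object")
  with_seed(config$seed, {
    fs <- config$fs
    script <- config$script
    n_seg <- length(script)
    ncpm <- config$n_cycles_per_mode
    n_cyc <- n_seg * ncpm

    jit <- function(k) {
      z <- pmax(pmin(stats::rnorm(k), 2), -2)
      config$cycle_duration_s * (1 + config$cycle_jitter * z)
    }
    lead_in <- 0.5 * jit(1L)
    durations <- jit(n_cyc)
    lead_out <- 0.5 * jit(1L)

    hs_t <- lead_in + c(0, cumsum(durations))        # n_cyc + 1 strikes
    total_s <- hs_t[n_cyc + 1L] + lead_out
    n_samp <- floor(total_s * fs) + 1L
    t <- (seq_len(n_samp) - 1L) / fs
    # snap heel strikes onto the sample grid
    hs_idx <- pmin(round(hs_t * fs) + 1L, n_samp)
    hs_t <- (hs_idx - 1L) / fs

    # continuous cycle phase: integer at each heel strike
    knots_t <- c(0, hs_t, t[n_samp])
    knots_p <- c(-lead_in / durations[1L], seq(0, n_cyc),
                 n_cyc + lead_out / durations[n_cyc])
    phase_c <- stats::approx(knots_t, knots_p, xout = t, rule = 2)$y
    phase <- phase_c %% 1

    # mode onsets: first heel strike of each segment after the first
    onset_t <- hs_t[((seq_len(n_seg) - 1L) * ncpm) + 1L][-1L]
    ramp_s <- config$transition_ramp_ms / 1000
    emg_switch_t <- onset_t - config$emg_lead_ms / 1000

    labels <- script[findInterval(t, onset_t) + 1L]
    truth_labels <- as_mode(labels)

    env <- blend_segments(t, phase, script, emg_switch_t, ramp_s, emg_envelope)
    acc_clean <- blend_segments(t, phase, script, onset_t, ramp_s, accel_template)

    carrier <- matrix(stats::rnorm(n_samp * 14L), n_samp, 14L)
    bp <- filter_spec("bandpass", order = 8L, band_hz = c(30, 300), fs = fs)
    for (j in 1:14) {
      col <- zero_lag_filter(carrier[, j], bp)
      carrier[, j] <- col / stats::sd(col)
    }
    wb_sd <- if (is.finite(config$emg_noise_snr)) 0.1 / config$emg_noise_snr else 0
    emg <- env * carrier
    if (wb_sd > 0) emg <- emg + wb_sd * matrix(stats::rnorm(n_samp * 14L), n_samp, 14L)
    colnames(emg) <- emg_channel_names()

    accel <- acc_clean
    if (config$accel_noise_sd > 0) {
      accel <- accel + config$accel_noise_sd * matrix(stats::rnorm(n_samp * 21L), n_samp, 21L)
    }
    colnames(accel) <- accel_channel_names()

    pelvis <- 0.02 * sin(2 * pi * phase_c + 1)
    heel <- pelvis + 0.3 * cos(2 * pi * phase_c)
    toe <- pelvis + 0.25 * cos(2 * pi * phase_c - 2)
    markers <- cbind(heel = heel, toe = toe, pelvis = pelvis)

    seg_of_hs <- pmin((seq_len(n_cyc + 1L) - 1L) %/% ncpm + 1L, n_seg)
    events <- rbind(
      data.frame(time_s = hs_t, kind = "heel_strike",
                 mode = script[seg_of_hs], stringsAsFactors = FALSE),
      if (n_seg > 1L) data.frame(time_s = onset_t, kind = "mode_onset",
                                 mode = script[-1L], stringsAsFactors = FALSE)
    )
    events <- events[order(events$time_s, events$kind), , drop = FALSE]
    rownames(events) <- NULL

    trial <- structure(list(
      emg = emg, accel = accel, markers = markers, fs = fs,
      truth_labels = truth_labels, truth_events = events,
      phase = phase_c, config = config
    ), class = "gait_trial")
    if (config$keep_envelope) trial$emg_envelope <- env
    trial
  })
}

#' @export
print.gait_trial <- function(x, ...) {
  n <- nrow(x$emg)
  onsets <- sum(x$truth_events$kind == "mode_onset")
  cat(sprintf(
    "<gait_trial> %d samples (%.1f s @ %g Hz), script %s\n  %d heel strikes, %d mode onsets%s\n",
    n, n / x$fs, x$fs, paste(x$config$script, collapse = "-"),
    sum(x$truth_events$kind == "heel_strike"), onsets,
    if (isTRUE(attr(x, "preprocessed"))) ", preprocessed" else ""
  ))
  invisible(x)
}
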