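#' Coordinate-based heel-strike detection
#'
#' Detects heel strikes as local maxima of the heel-minus-pelvis anterior
#' coordinate (the coordinate-based event detection method of Zeni et
#' al.), keeping peaks whose height exceeds a threshold fraction of the
#' coordinate's range and enforcing a refractory interval between events.
#'
#' @param heel_anterior,pelvis_anterior equal-length anterior position
#'   traces.
#' @param fs sampling rate in Hz.
#' @param prominence_frac height threshold as a fraction of the
#'   (heel - pelvis) range above its minimum; default 0.25.
#' @param refractory_s minimum separation between events in seconds.
#' @return Sorted numeric vector of event times (s); empty on constant
#'   input.
#' @export
detect_heel_strikes <- function(heel_anterior, pelvis_anterior, fs,
                                prominence_frac = 0.25, refractory_s = 0.4) {
  if (length(heel_anterior) != length(pelvis_anterior)) {
    stop("heel and pelvis traces must have equal length")
  }
  stopifnot_scalar_num(fs, "fs")
  d <- as.numeric(heel_anterior) - as.numeric(pelvis_anterior)
  n <- length(d)
  if (n < 3L) return(numeric(0))
  rng <- range(d)
  if (diff(rng) == 0) return(numeric(0))
  i <- 2L:(n - 1L)
  cand <- i[d[i] > d[i - 1L] & d[i] >= d[i + 1L]]
  thr <- rng[1L] + prominence_frac * diff(rng)
  cand <- cand[d[cand] >= thr]
  if (!length(cand)) return(numeric(0))
  # greedy refractory suppression, strongest peaks first
  ord <- cand[order(d[cand], decreasing = TRUE)]
  keep <- integer(0)
  gap <- refractory_s * fs
  for (idx in ord) {
    if (!length(keep) || all(abs(keep - idx) >= gap)) keep <- c(keep, idx)
  }
  sort((keep - 1L) / fs)
}

#' Partition a trial into labelled gait cycles
#'
#' One gait cycle spans two consecutive heel strikes of the same limb;
#' cycles are half-open intervals `[start, end)` so that every sample of
#' the walking span belongs to exactly one cycle.  A cycle whose samples
#' carry a single mode label is steady-state with that label; a cycle in
#' which the label switches is a gait transition, with `next_mode` the
#' label at the cycle's last sample.  A label switch falling exactly on a
#' heel strike therefore produces no transition cycle.
#'
#' @param events heel-strike times (s), ascending.
#' @param labels per-sample mode track for the whole trial.
#' @param fs sampling rate in Hz.
#' @return Data frame with `start_s`, `end_s`, `label` (a mode code or
#'   `"TRANSITION"`) and `next_mode` (`NA` for steady cycles); empty for
#'   fewer than two events.
#' @export
segment_cycles <- function(events, labels, fs) {
  stopifnot_scalar_num(fs, "fs")
  events <- sort(as.numeric(events))
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0), next_mode = character(0),
                      stringsAsFactors = FALSE)
  if (length(events) < 2L) return(empty)
  labels <- as.character(labels)
  n <- length(labels)
  out <- vector("list", length(events) - 1L)
  for (k in seq_len(length(events) - 1L)) {
    start_i <- round(events[k] * fs) + 1L
    end_i <- round(events[k + 1L] * fs) + 1L  # exclusive
    idx <- seq.int(max(1L, start_i), min(n, end_i - 1L))
    span <- unique(labels[idx])
    if (length(span) == 1L) {
      out[[k]] <- data.frame(start_s = events[k], end_s = events[k + 1L],
                             label = span, next_mode = NA_character_,
                             stringsAsFactors = FALSE)
    } else {
      out[[k]] <- data.frame(start_s = events[k], end_s = events[k + 1L],
                             label = "TRANSITION",
                             next_mode = labels[idx[length(idx)]],
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Transition windows of a trial
#'
#' For each ground-truth mode onset, returns the transition gait cycle
#' preceding it (from the last heel strike in the old mode to the onset
#' heel strike) together with the extent of the following steady
#' segment.  These windows drive the steady-state training mask and the
#' prediction scoring.
#'
#' @param trial a `gait_trial` (or any list with `truth_events` and a
#'   sample count).
#' @return Data frame with `onset_s`, `prev_hs_s`, `next_mode`,
#'   `steady_end_s`; zero rows when the trial has no transitions.
#' @export
transition_windows <- function(trial) {
  ev <- trial$truth_events
  onsets <- ev[ev$kind == "mode_onset", , drop = FALSE]
  hs <- ev$time_s[ev$kind == "heel_strike"]
  t_end <- (nrow(trial$emg) - 1L) / trial$fs
  n <- nrow(onsets)
  if (n == 0L) {
    return(data.frame(onset_s = numeric(0), prev_hs_s = numeric(0),
                      next_mode = character(0), steady_end_s = numeric(0),
                      stringsAsFactors = FALSE))
  }
  prev_hs <- vapply(onsets$time_s, function(o) {
    before <- hs[hs < o - 1e-9]
    if (length(before)) max(before) else 0
  }, numeric(1))
  steady_end <- c(onsets$time_s[-1L], t_end)
  data.frame(onset_s = onsets$time_s, prev_hs_s = prev_hs,
             next_mode = as.character(onsets$mode),
             steady_end_s = steady_end, stringsAsFactors = FALSE)
}

#' Steady-state sample mask
#'
#' Logical mask over a trial's samples that is `FALSE` inside every
#' transition gait cycle (the cycle ending at each mode onset), i.e. the
#' samples where muscle activation may already reflect the upcoming mode
#' while the label still carries the old one.  Used both to restrict
#' training to steady-state data and to score steady-state recognition.
#'
#' @param trial a `gait_trial`.
#' @return Logical vector, one element per sample.
#' @export
steady_state_mask <- function(trial) {
  n <- nrow(trial$emg)
  mask <- rep(TRUE, n)
  tw <- transition_windows(trial)
  if (nrow(tw)) {
    for (k in seq_len(nrow(tw))) {
      from <- round(tw$prev_hs_s[k] * trial$fs) + 1L
      to <- round(tw$onset_s[k] * trial$fs)  # last sample before onset
      mask[seq.int(max(1L, from), min(n, to))] <- FALSE
    }
  }
  mask
}
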