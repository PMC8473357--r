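#' Butterworth filter specification
#'
#' Describes a zero-lag (forward-backward) Butterworth filter by its
#' *total effective order*: the filter is designed at `order/2` and
#' applied once forward and once backward, the convention used for
#' "fourth-order zero-lag" filters in the gait literature.
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param order total effective order; even and positive.
#' @param band_hz one corner frequency (lowpass) or two ascending corner
#'   frequencies (bandpass), strictly inside (0, fs/2).
#' @param fs sampling rate in Hz.
#' @return A `filter_spec` list.
#' @export
#' @examples
#' filter_spec("bandpass", 4, c(30, 300), fs = 2000)
filter_spec <- function(kind = c("bandpass", "lowpass"), order, band_hz, fs) {
  kind <- match.arg(kind)
  stopifnot_scalar_num(fs, "fs")
  order <- as.integer(order)
  if (is.na(order) || order <= 0L || order %% 2L != 0L) {
    stop("order must be a positive even integer (total effective order)")
  }
  band_hz <- as.numeric(band_hz)
  n_corner <- if (kind == "bandpass") 2L else 1L
  if (length(band_hz) != n_corner) {
    stop(kind, " filter needs ", n_corner, " corner frequencies")
  }
  if (any(band_hz <= 0) || any(band_hz >= fs / 2)) {
    stop("corner frequencies must lie strictly inside (0, fs/2)")
  }
  if (n_corner == 2L && band_hz[1] >= band_hz[2]) {
    stop("bandpass corners must be ascending")
  }
  structure(list(kind = kind, order = order, band_hz = band_hz, fs = fs),
            class = "filter_spec")
}

# Direct-form IIR filtering with zero initial conditions, via two
# compiled stats::filter passes (FIR convolution then AR recursion).
lfilter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  v <- stats::filter(x, b, method = "convolution", sides = 1)
  v <- as.numeric(v)
  nb <- length(b)
  if (nb > 1L) {
    for (k in seq_len(nb - 1L)) v[k] <- sum(b[seq_len(k)] * x[k:1])
  }
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

#' Zero-lag Butterworth filtering
#'
#' Applies the Butterworth filter described by `spec` forward and
#' backward, so the output has zero phase shift and the combined
#' magnitude response has the spec's total order.  The signal is extended
#' at both ends by odd reflection before filtering (padding length three
#' times the filter's characteristic length, bounded by the lowest corner
#' period) to suppress boundary transients; the output has the same
#' length as the input.
#'
#' @param x numeric signal.
#' @param spec a [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
zero_lag_filter <- function(x, spec) {
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  x <- as.numeric(x)
  n <- length(x)
  norder <- spec$order %/% 2L
  warmup <- 3L * (norder + 1L)
  if (n <= warmup) {
    stop("signal too short for the filter warm-up (need > ", warmup, " samples)")
  }
  wn <- spec$band_hz / (spec$fs / 2)
  bt <- signal::butter(norder, wn, type = if (spec$kind == "bandpass") "pass" else "low")
  b <- bt$b
  a <- bt$a
  padlen <- min(n - 1L, max(3L * length(a), ceiling(3 * spec$fs / min(spec$band_hz))))
  xl <- 2 * x[1L] - x[(padlen + 1L):2L]
  xr <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xx <- c(xl, x, xr)
  y <- lfilter(b, a, xx)
  y <- rev(lfilter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Preprocess a trial's raw signals
#'
#' Band-passes every EMG channel (default 30-300 Hz, total order 4) and
#' low-passes every acceleration channel (default 25 Hz, total order 6)
#' with zero-lag Butterworth filters.  Labels, events, markers and
#' channel counts are untouched.
#'
#' @param trial a `gait_trial`.
#' @param emg_band_hz,emg_order EMG band-pass corners and total order.
#' @param accel_cutoff_hz,accel_order acceleration low-pass corner and
#'   total order.
#' @return The trial with filtered `emg` and `accel`, flagged with
#'   `attr(, "preprocessed")`.
#' @export
preprocess_trial <- function(trial, emg_band_hz = c(30, 300), emg_order = 4L,
                             accel_cutoff_hz = 25, accel_order = 6L) {
  if (!inherits(trial, "gait_trial")) stop("trial must be a gait_trial")
  if (is.null(trial$emg) || ncol(trial$emg) == 0L ||
      is.null(trial$accel) || ncol(trial$accel) == 0L) {
    stop("trial has empty signal channels")
  }
  emg_spec <- filter_spec("bandpass", emg_order, emg_band_hz, trial$fs)
  acc_spec <- filter_spec("lowpass", accel_order, accel_cutoff_hz, trial$fs)
  for (j in seq_len(ncol(trial$emg))) {
    trial$emg[, j] <- zero_lag_filter(trial$emg[, j], emg_spec)
  }
  for (j in seq_len(ncol(trial$accel))) {
    trial$accel[, j] <- zero_lag_filter(trial$accel[, j], acc_spec)
  }
  attr(trial, "preprocessed") <- TRUE
  trial
}
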