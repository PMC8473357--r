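#' Causal sliding-window RMS
#'
#' Root mean square over a window *ending* at each output instant, so a
#' decision at time t uses only samples at or before t.  With `step = 1`
#' the k-th output summarises samples `k .. k + window - 1` of the input,
#' i.e. the window ending at sample `k + window - 1`.
#'
#' @param x numeric signal.
#' @param window_samples window length in samples (>= 1, <= length(x)).
#' @param step output stride in samples.
#' @return Numeric vector of length `floor((length(x) - window) / step) + 1`.
#' @export
#' @examples
#' sliding_rms(c(3, 4), 2)  # sqrt((9 + 16) / 2)
sliding_rms <- function(x, window_samples, step = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  w <- as.integer(window_samples)
  step <- as.integer(step)
  if (is.na(w) || w < 1L) stop("window_samples must be >= 1")
  if (w > n) stop("window_samples exceeds signal length")
  if (is.na(step) || step < 1L) stop("step must be >= 1")
  cs <- c(0, cumsum(x^2))
  ends <- seq.int(w, n, by = step)
  sqrt(pmax(cs[ends + 1L] - cs[ends - w + 1L], 0) / w)
}

#' Min-max normalization bounds
#'
#' Learns per-column minima and maxima on training data.  Columns with no
#' spread are flagged (they normalize to 0) with a warning.
#'
#' @param X numeric training matrix.
#' @return List with `min` and `max` vectors, class `norm_bounds`.
#' @export
fit_norm_bounds <- function(X) {
  X <- as.matrix(X)
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  flat <- maxs <= mins
  if (any(flat)) {
    warning(sum(flat), " constant feature column(s) will normalize to 0")
  }
  structure(list(min = mins, max = maxs, flat = flat), class = "norm_bounds")
}

#' Apply min-max normalization
#'
#' Maps each column through `(x - min) / (max - min)` using bounds learned
#' on training data; values outside the training range (possible on test
#' data) are clipped to `[-0.5, 1.5]` to bound extrapolation.  Constant
#' training columns map to 0.
#'
#' @param X numeric matrix with the same columns as the training data.
#' @param bounds a [fit_norm_bounds()] result.
#' @param clip two-element clipping range.
#' @return Normalized matrix.
#' @export
apply_norm <- function(X, bounds, clip = c(-0.5, 1.5)) {
  X <- as.matrix(X)
  if (ncol(X) != length(bounds$min)) {
    stop("column count mismatch: got ", ncol(X), ", bounds have ",
         length(bounds$min))
  }
  span <- bounds$max - bounds$min
  span[bounds$flat] <- 1
  out <- sweep(sweep(X, 2L, bounds$min, "-"), 2L, span, "/")
  out[, bounds$flat] <- 0
  pmin(pmax(out, clip[1L]), clip[2L])
}

#' Build the fused RMS feature matrix of a trial
#'
#' Computes the causal sliding-window RMS of every channel and assembles
#' the 35-element fused feature vector per sample instant: 14 EMG
#' channels followed by 21 acceleration channels.  The label of each row
#' is the ground-truth mode at the window's end.
#'
#' @param trial a (preprocessed) `gait_trial`.
#' @param window_ms window length in milliseconds.
#' @param step output stride in samples; 1 for online evaluation, larger
#'   strides thin training rows without changing the feature definition.
#' @return A `gait_features` list: `X` (rows x 35, unnormalized), `y`
#'   (mode factor), `t` (window-end times, s), `sample_index`
#'   (window-end sample of each row), `window_ms`, `fs`, `truth_events`.
#' @export
build_features <- function(trial, window_ms, step = 1L) {
  if (!inherits(trial, "gait_trial")) stop("trial must be a gait_trial")
  stopifnot_scalar_num(window_ms, "window_ms")
  w <- as.integer(max(1, round(window_ms / 1000 * trial$fs)))
  n <- nrow(trial$emg)
  if (w > n) stop("window longer than trial")
  sig <- cbind(trial$emg, trial$accel)
  if (ncol(sig) != 35L) {
    stop("expected 14 EMG + 21 acceleration channels, got ", ncol(sig))
  }
  X <- vapply(seq_len(ncol(sig)),
              function(j) sliding_rms(sig[, j], w, step),
              numeric(length(seq.int(w, n, by = step))))
  colnames(X) <- colnames(sig)
  idx <- seq.int(w, n, by = as.integer(step))
  structure(list(
    X = X, y = trial$truth_labels[idx], t = (idx - 1L) / trial$fs,
    sample_index = idx, window_ms = window_ms, fs = trial$fs,
    truth_events = trial$truth_events,
    initial_mode = as.character(trial$truth_labels[1L])
  ), class = "gait_features")
}

#' Feature columns of a sensing modality
#'
#' @param modality `"fusion"` (all 35 columns), `"emg_only"` (14) or
#'   `"accel_only"` (21).
#' @return Integer column indices into the fused feature matrix.
#' @export
modality_columns <- function(modality = c("fusion", "emg_only", "accel_only")) {
  switch(match.arg(modality),
         fusion = 1:35, emg_only = 1:14, accel_only = 15:35)
}
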