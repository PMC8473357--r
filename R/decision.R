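#' Online decision configuration
#'
#' @param agreement_n number of consecutive agreeing raw labels required
#'   before the output may update (default 100, i.e. 50 ms at 2000 Hz).
#' @param initial_mode the mode the output starts in (normally the first
#'   scripted mode; trials start seated or standing).
#' @return A `decision_config` list.
#' @export
decision_config <- function(agreement_n = 100L, initial_mode = "ST") {
  agreement_n <- as.integer(agreement_n)
  if (is.na(agreement_n) || agreement_n < 1L) stop("agreement_n must be >= 1")
  initial_mode <- as.character(as_mode(initial_mode))
  structure(list(agreement_n = agreement_n, initial_mode = initial_mode),
            class = "decision_config")
}

#' Minimum decision-update latency
#'
#' The agreement vote imposes a floor on how quickly the output can react
#' to a change in the raw stream: `agreement_n / fs` seconds.
#'
#' @param config a [decision_config()].
#' @param fs sampling rate in Hz.
#' @return Latency in milliseconds (50 ms for 100 windows at 2000 Hz).
#' @export
update_latency_ms <- function(config, fs) {
  stopifnot_scalar_num(fs, "fs")
  config$agreement_n / fs * 1000
}

#' Stabilize a raw label stream with the agreement vote and legality rules
#'
#' Converts the per-sample classifier stream into the online output mode.
#' Starting from `initial_mode`, the output switches to mode m at sample
#' k if and only if the last `agreement_n` raw labels (including sample
#' k) all equal m, m differs from the current output, and the transition
#' from the current output to m is allowed by the rule table; otherwise
#' the output holds.  Agreement is counted purely on the raw-stream
#' suffix, so a candidate blocked by the rules neither updates the output
#' nor resets any state.
#'
#' @param raw_labels factor/character stream of raw classifier outputs.
#' @param config a [decision_config()].
#' @param rules transition-legality table, default [default_rules()].
#' @param t optional per-sample times (s) for the update log.
#' @return A `decision_trace`: `output` (per-sample mode factor), `raw`,
#'   `updates` (data frame: index, time_s, from, to) and `config`.
#' @export
decide_stream <- function(raw_labels, config = decision_config(),
                          rules = default_rules(), t = NULL) {
  raw <- as_mode(raw_labels)
  if (!length(raw)) stop("raw_labels must be nonempty")
  if (anyNA(raw)) stop("raw stream contains missing labels")
  rules <- validate_rules(rules)
  n_agree <- config$agreement_n
  modes <- locomotion_modes()
  runs <- rle(as.integer(raw))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  current <- match(config$initial_mode, modes)
  out_code <- integer(length(raw))
  upd_index <- integer(0)
  upd_from <- character(0)
  upd_to <- character(0)
  pos <- 1L
  for (r in seq_along(runs$lengths)) {
    m <- runs$values[r]
    if (m != current && runs$lengths[r] >= n_agree && rules[current, m]) {
      k <- starts[r] + n_agree - 1L  # first sample with full agreement
      if (k > pos) out_code[pos:(k - 1L)] <- current
      upd_index <- c(upd_index, k)
      upd_from <- c(upd_from, modes[current])
      upd_to <- c(upd_to, modes[m])
      current <- m
      pos <- k
    }
  }
  out_code[pos:length(raw)] <- current
  updates <- data.frame(
    index = upd_index,
    time_s = if (!is.null(t)) t[upd_index] else (upd_index - 1L),
    from = upd_from, to = upd_to, stringsAsFactors = FALSE
  )
  structure(list(output = factor(modes[out_code], levels = modes),
                 raw = raw, updates = updates, config = config,
                 t = t), class = "decision_trace")
}

#' @export
print.decision_trace <- function(x, ...) {
  cat(sprintf("<decision_trace> %d samples, %d updates (agreement_n = %d)\n",
              length(x$output), nrow(x$updates), x$config$agreement_n))
  if (nrow(x$updates)) {
    print(utils::head(x$updates, 10L))
    if (nrow(x$updates) > 10L) cat("  ...\n")
  }
  invisible(x)
}
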