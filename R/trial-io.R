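#' Write / read a trial as TSV plus JSON sidecar
#'
#' The signal tracks (14 EMG, 21 acceleration, 3 marker columns) are
#' written as tab-separated text with a header row of channel names; the
#' sampling rate, channel map, run-length-encoded label track, event list
#' and simulation configuration go to a JSON sidecar next to the TSV
#' (same path with a `.json` extension).  The round trip is lossless to
#' within float printing precision.
#'
#' @param trial a `gait_trial`.
#' @param path TSV file path.
#' @return `read_trial()` returns a `gait_trial`; `write_trial()` the
#'   path, invisibly.
#' @export
write_trial <- function(trial, path) {
  if (!inherits(trial, "gait_trial")) stop("trial must be a gait_trial")
  dt <- data.table::as.data.table(cbind(trial$emg, trial$accel, trial$markers))
  data.table::fwrite(dt, path, sep = "\t")
  lab <- rle(as.character(trial$truth_labels))
  sidecar <- list(
    fs = trial$fs,
    channels = list(emg = colnames(trial$emg),
                    accel = colnames(trial$accel),
                    markers = colnames(trial$markers)),
    labels = list(lengths = lab$lengths, values = lab$values),
    events = trial$truth_events,
    config = unclass(trial$config)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) stop("trial sidecar not found: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  needed <- c("fs", "channels", "labels", "events")
  missing <- setdiff(needed, names(sc))
  if (length(missing)) {
    stop("trial sidecar missing required key(s): ", paste(missing, collapse = ", "))
  }
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  ch <- sc$channels
  if (length(ch$emg) != 14L) {
    stop("expected 14 EMG channels, sidecar lists ", length(ch$emg))
  }
  if (length(ch$accel) != 21L) {
    stop("expected 21 acceleration channels, sidecar lists ", length(ch$accel))
  }
  absent <- setdiff(c(ch$emg, ch$accel, ch$markers), names(dt))
  if (length(absent)) {
    stop("TSV is missing channel column(s): ", paste(absent, collapse = ", "))
  }
  labels <- inverse.rle(structure(list(lengths = sc$labels$lengths,
                                       values = sc$labels$values), class = "rle"))
  if (length(labels) != nrow(dt)) {
    stop("label track length (", length(labels), ") does not match sample count (",
         nrow(dt), ")")
  }
  config <- sc$config
  if (!is.null(config)) class(config) <- "sim_config"
  structure(list(
    emg = as.matrix(dt[, ch$emg, drop = FALSE]),
    accel = as.matrix(dt[, ch$accel, drop = FALSE]),
    markers = as.matrix(dt[, ch$markers, drop = FALSE]),
    fs = as.numeric(sc$fs),
    truth_labels = as_mode(labels),
    truth_events = as.data.frame(sc$events),
    phase = NULL,
    config = config
  ), class = "gait_trial")
}
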