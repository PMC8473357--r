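#' Locomotion mode codes
#'
#' The seven locomotion modes handled by the pipeline, in their stable
#' order: sit (S), stand (ST), level walk (LW), stair ascent (SA), stair
#' descent (SD), ramp ascent (RA) and ramp descent (RD).  Integer encoding
#' is positional, 0 for S through 6 for RD.
#'
#' @return Character vector of the seven mode codes.
#' @export
#' @examples
#' locomotion_modes()
locomotion_modes <- function() {
  c("S", "ST", "LW", "SA", "SD", "RA", "RD")
}

#' Coerce labels to a locomotion-mode factor
#'
#' @param x character vector, factor or integer codes (0-6).
#' @return Factor with the seven mode levels in stable order.
#' @export
as_mode <- function(x) {
  modes <- locomotion_modes()
  if (is.numeric(x)) {
    if (any(x < 0 | x > 6 | x != floor(x), na.rm = TRUE)) {
      stop("integer mode codes must lie in 0..6")
    }
    x <- modes[x + 1L]
  }
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), modes)
  if (length(bad)) {
    stop("unknown locomotion mode code(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = modes)
}

#' Integer encoding of locomotion modes
#'
#' @param x vector coercible by [as_mode()].
#' @return Integer codes, 0 (S) through 6 (RD).
#' @export
mode_code <- function(x) {
  as.integer(as_mode(x)) - 1L
}

#' The five scripted locomotion tasks
#'
#' Ordered mode sequences of the five scripted transition tasks:
#' (1) S-ST-LW-ST; (2) ST-LW-SA-LW-ST; (3) ST-LW-SD-LW-ST;
#' (4) ST-LW-RA-LW-ST; (5) ST-LW-RD-LW-ST.
#'
#' @param task integer in 1..5.
#' @return Character vector of mode codes for that task.
#' @export
#' @examples
#' task_script(2)
task_script <- function(task) {
  task <- as.integer(task)
  if (length(task) != 1L || is.na(task) || task < 1L || task > 5L) {
    stop("task must be a single integer in 1..5")
  }
  switch(task,
    c("S", "ST", "LW", "ST"),
    c("ST", "LW", "SA", "LW", "ST"),
    c("ST", "LW", "SD", "LW", "ST"),
    c("ST", "LW", "RA", "LW", "ST"),
    c("ST", "LW", "RD", "LW", "ST")
  )
}
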