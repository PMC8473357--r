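#' Default locomotion transition-legality table
#'
#' The 7 x 7 logical matrix of allowed mode transitions, indexed
#' `[previous mode, current mode]`.  Sitting can only change to standing,
#' standing only to level walking (and back to sitting is forbidden),
#' level walking can change to any mode except sitting, and stair/ramp
#' modes can only return to level walking.  Self-transitions (holding a
#' mode) are always allowed.
#'
#' @return Logical 7 x 7 matrix with mode-code dimnames, class
#'   `"transition_rules"`.
#' @export
#' @examples
#' rules <- default_rules()
#' rules["S", "ST"]   # TRUE
#' rules["SA", "RA"]  # FALSE
default_rules <- function() {
  modes <- locomotion_modes()
  allowed <- matrix(FALSE, 7, 7, dimnames = list(previous = modes, current = modes))
  diag(allowed) <- TRUE
  allowed["S", "ST"] <- TRUE
  allowed["ST", "LW"] <- TRUE
  allowed["LW", c("ST", "SA", "SD", "RA", "RD")] <- TRUE
  allowed[c("SA", "SD", "RA", "RD"), "LW"] <- TRUE
  structure(allowed, class = c("transition_rules", "matrix", "array"))
}

validate_rules <- function(rules) {
  modes <- locomotion_modes()
  if (!is.matrix(rules) || !identical(dim(rules), c(7L, 7L))) {
    stop("rules must be a 7 x 7 matrix")
  }
  if (!is.logical(rules)) {
    storage.mode(rules) <- "logical"
  }
  if (is.null(dimnames(rules))) {
    dimnames(rules) <- list(previous = modes, current = modes)
  }
  if (!all(diag(rules))) stop("rule table must allow self-transitions")
  rules
}

#' Check that a scripted mode sequence is legal
#'
#' @param script character vector of mode codes.
#' @param rules transition rule table, default [default_rules()].
#' @return Invisibly `TRUE`; errors naming the first illegal pair.
#' @export
check_script_legal <- function(script, rules = default_rules()) {
  script <- as.character(as_mode(script))
  if (length(script) >= 2L) {
    for (i in seq_len(length(script) - 1L)) {
      if (!rules[script[i], script[i + 1L]]) {
        stop(sprintf("illegal mode transition in script: %s -> %s",
                     script[i], script[i + 1L]))
      }
    }
  }
  invisible(TRUE)
}

#' Read or write a transition rule table as JSON
#'
#' The JSON form is an object of mode-named rows, each a mode-named map of
#' 0/1 flags.
#'
#' @param rules rule table for writing.
#' @param path file path.
#' @return `read_rules()` returns a `transition_rules` matrix.
#' @export
write_rules <- function(rules, path) {
  rules <- validate_rules(rules)
  obj <- apply(rules, 1L, function(r) as.list(as.integer(r)), simplify = FALSE)
  obj <- lapply(obj, function(r) stats::setNames(r, colnames(rules)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  obj <- jsonlite::read_json(path)
  modes <- locomotion_modes()
  if (!setequal(names(obj), modes)) stop("rule JSON must have the 7 mode rows")
  allowed <- matrix(FALSE, 7, 7, dimnames = list(previous = modes, current = modes))
  for (p in modes) {
    row <- obj[[p]]
    if (!setequal(names(row), modes)) stop("rule JSON row ", p, " malformed")
    allowed[p, modes] <- as.logical(unlist(row[modes]))
  }
  validate_rules(structure(allowed, class = c("transition_rules", "matrix", "array")))
}
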