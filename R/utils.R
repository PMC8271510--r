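# internal helpers

#' Round half away from zero
#'
#' Penalty values are rounded to the nearest natural number with halves
#' rounded away from zero (so 7.5 -> 8), avoiding the banker's rounding of
#' base [round()].
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_qpass <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "qpass_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_qpass("%s must be finite numeric values", what,
               class = "qpass_input_error")
  }
  invisible(x)
}
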