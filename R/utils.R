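# Internal condition helpers: input errors (bad user input, exit code 2 at the
# CLI) are distinguished from internal errors so callers can map them.

inputError <- function(msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = NULL),
    class = c("ternimmune_input_error", "error", "condition")
  ))
}

#' Test whether a condition is a ternimmune input error
#'
#' Input errors signal malformed user input (bad files, unknown nodes,
#' undersized cohorts) as opposed to internal failures; the command-line
#' wrapper maps them to exit code 2.
#'
#' @param x a condition object.
#' @return `TRUE` if `x` was signalled by the package as an input error.
#' @export
isInputError <- function(x) inherits(x, "ternimmune_input_error")

# sign() that is guaranteed integer-valued on integer input
.sgn <- function(x) as.integer(sign(x))

.TERNARY <- c(-1L, 0L, 1L)

.checkTernary <- function(v, what = "value") {
  if (!all(v %in% .TERNARY)) {
    inputError("%s must be in {-1, 0, +1}; got %s", what,
               paste(unique(v[!v %in% .TERNARY]), collapse = ", "))
  }
  invisible(TRUE)
}
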