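#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for the printed percentages in the study report (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop with a classed condition so callers/tests can match on class
stop_cmc <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "cmcflow_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}
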