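#' Round half away from zero
#'
#' Decimal rounding where exact halves go away from zero (the convention used
#' for displayed percentages), unlike [round()] which rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(22.5, 0.125), c(0, 2))
#' round(2.5)        # banker's rounding: 2
#' round_half_up(2.5) # half away from zero: 3
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
#' @noRd
stop_config <- function(...) {
  stop(structure(
    class = c("omicsconcord_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @keywords internal
#' @noRd
stop_data <- function(...) {
  stop(structure(
    class = c("omicsconcord_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# scalar checks used by constructors
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
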