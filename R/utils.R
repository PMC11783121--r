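#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"); reported
#' percentages here follow the usual clinical convention of rounding .5 up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
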