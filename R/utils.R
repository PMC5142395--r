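#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Base [round()] rounds half to even; clinical tables conventionally round
#' half up, so 42.855 prints as 42.86.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Truncate to a number of decimal places
#'
#' Drops digits beyond `digits` without rounding (74.7899 -> 74.78).
#' Some published accuracy cells are truncated rather than rounded; this is
#' the compatibility mode used for them.
#'
#' @inheritParams round_half_up
#' @return truncated numeric vector.
#' @export
trunc_digits <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# format a percent/ratio cell: two decimals, blank for NA
fmt2 <- function(x, truncate = FALSE) {
  ifelse(is.na(x), "",
         formatC(if (truncate) trunc_digits(x, 2) else round_half_up(x, 2),
                 format = "f", digits = 2))
}
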