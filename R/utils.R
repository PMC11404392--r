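#' Round half away from zero
#'
#' Fixed-point rounding in which ties go away from zero (the convention used in
#' the reporting layer), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Reported proportion in percent
#'
#' Converts a numerator/denominator pair to a percentage rounded half-up, the
#' arithmetic used everywhere a scorecard or summary prints a proportion.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param digits Decimal digits to keep (default 1, as in report text).
#' @return Percentage as a bare number (e.g. `38.9`).
#' @examples
#' proportion(2034, 5231) # 38.9
#' @export
proportion <- function(numerator, denominator, digits = 1) {
  stopifnot(all(denominator > 0), all(numerator >= 0))
  round_half_up(100 * numerator / denominator, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fatal <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0
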