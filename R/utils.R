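# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (0.05 -> 0.1), the
#' convention used throughout the pool-composition tables. Base R's
#' `round()` rounds ties to even, which does not reproduce printed table
#' cells such as 21.9 x 13.5 = 295.7.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(0.05)   # 0.1
#' round_half_up(21.9 * 13.5)  # 295.7
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  # small epsilon absorbs binary representation error just below a tie
  sign(x) * floor(abs(x) * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

stop_ap <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_ap("%s is missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  }
  invisible(df)
}
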