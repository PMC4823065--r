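#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 0.05 -> 0.1), the
#' convention of the printed tables this package reproduces.  Base R's
#' `round()` rounds ties to even and cannot reproduce them.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(62.25, 1) # 62.3
#' round(62.25, 1)         # 62.2 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  # small guard against representation error, e.g. 1.15 stored as 1.14999...
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

check_count <- function(x, name, allow_zero = TRUE) {
  bad <- !is.finite(x) | x < 0 | x != floor(x) | (!allow_zero & x == 0)
  if (any(bad)) {
    abort(sprintf(
      "`%s` must contain non-negative integers (offending value: %s)",
      name, format(x[bad][1])
    ), class = "relapsekit_value_error")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name),
      class = "relapsekit_value_error")
  }
  invisible(x)
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}
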