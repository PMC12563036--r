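#' Round half away from zero
#'
#' Base R's `round()` rounds ties to even ("banker's rounding"), but regulatory
#' residue tables round ties upward: a measurement at 122.5% of its MRL is
#' reported as 123%. `round_half_up()` implements that convention. A tiny
#' relative epsilon absorbs binary representation error, so a ratio that is
#' exactly a tie in decimal (e.g. 0.735/0.6 * 100 = 122.5) rounds up even when
#' its double representation falls a few ulps short.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep (default 0).
#' @return `x` rounded half-up (half away from zero for negatives).
#' @examples
#' round_half_up(122.5)       # 123
#' round_half_up(7.4088, 2)   # 7.41
#' @export
round_half_up <- function(x, digits = 0) {
  z <- x * 10^digits
  eps <- abs(z) * 1e-9 + 1e-12
  sign(z) * floor(abs(z) + 0.5 + eps) / 10^digits
}

# Internal: abort with a consistent class so callers can test on it.
pr_abort <- function(msg, class = "primorisk_error") {
  rlang::abort(msg, class = class)
}

# Internal: check a scalar is a positive finite number.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    pr_abort(sprintf("`%s` must be a single positive number, got %s",
                     name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}
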