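# Internal helpers: typed error conditions, display rounding, input checks.

ssl_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ssl_error"), call = call))
}

check_count <- function(x, name, max = Inf) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > max) ||
      any(x != trunc(x))) {
    ssl_abort(
      sprintf("`%s` must be integer-valued in [0, %s]", name, format(max)),
      "ssl_invalid_input"
    )
  }
  invisible(x)
}

#' Round for display, half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero, the
#' convention used for all reported SSL values (so 0.505 displays as 0.51,
#' unlike [round()]'s banker's rounding). Statistics always run on unrounded
#' values; this is applied at reporting time only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_display(0.505)      # 0.51
#' round_display(0.7497)     # 0.75
#' @export
round_display <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Collapse a character vector of flags to a single comma-separated string.
join_flags <- function(flags) {
  if (length(flags) == 0) "" else paste(flags, collapse = ",")
}
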