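# internal helpers shared across modules

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all displayed counts and
#' per-patient figures. Base \code{round()} rounds half to even, which does
#' not match the headcount convention used throughout the result tables
#' (e.g. 31.69 -> 32, 22.41 -> 22, 0.5 -> 1).
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop with the caller's frame so error messages name the user-facing call
fail <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# named-list field check: complain about unknown keys (fail-fast on typos)
unknown_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) == 0L) character(0)
  else sprintf("%s: unknown field '%s'", where, extra)
}
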