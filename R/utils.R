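#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; clinical report tables use
#' conventional half-up rounding (2.5 -> 3).  A small epsilon guards against
#' binary representation error in values such as 0.105.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Clamp values into a closed interval
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Format a count with its percentage, table-style
#'
#' Renders "839 (11.4%)" cells: the count, then the proportion as a
#' half-up-rounded percentage to one decimal place.
#'
#' @param count event count (may be a non-integer simulated expectation).
#' @param denom denominator.
#' @param count_digits decimals used for the count (0 for observed counts).
#' @return character vector.
#' @export
#' @examples
#' format_count_pct(776, 7332)   # "776 (10.6%)"
format_count_pct <- function(count, denom, count_digits = 0) {
  pct <- round_half_up(100 * count / denom, 1)
  sprintf("%s (%s%%)",
          formatC(round_half_up(count, count_digits),
                  format = "f", digits = count_digits),
          formatC(pct, format = "f", digits = 1))
}

# Deterministic 31-bit hash of an id string, used to derive per-participant
# RNG substreams that do not depend on cohort row order.
.hash_id <- function(id) {
  vapply(as.character(id), function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a child seed below 2^31 from a master seed and stream labels.
.child_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (x in list(...)) {
    xs <- if (is.character(x)) .hash_id(x) else as.numeric(x)
    h <- (h * 48271 + xs + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
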