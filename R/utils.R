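## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables use conventional
#' half-away-from-zero rounding (159.65 -> 159.6 stays, 120.85 -> 120.9).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## All randomness flows through an explicit integer seed; global RNG state is
## saved and restored around every stochastic operation.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  withr::with_seed(as.integer(seed), code)
}

## Derive a stream-specific child seed from a master seed, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483647L
}

## sample() from a vector that may have length 1 without integer expansion
resample <- function(x, size = 1) x[sample.int(length(x), size)]

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
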