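# Shared numeric helpers.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; monetary amounts and exported person
#' counts in this package use the conventional half-up rule instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimal places.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(1116.655, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Truncate toward zero at `digits` decimal places (cost rounding option).
trunc_digits <- function(x, digits = 0) {
  scale <- 10^digits
  trunc(x * scale) / scale
}

# Integer-ish check tolerant of doubles read from CSV.
is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# Derive a 31-bit sub-seed from a root seed and a counter so that
# per-iteration streams are independent of evaluation order.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %%
               2147483629 + 1)
}
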