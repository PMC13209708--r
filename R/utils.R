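#' Round half away from zero at a given number of decimals
#'
#' Printed potency tables use conventional half-up rounding, not the banker's
#' rounding of base `round()`.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic sub-seed derivation; keeps results in 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + k * 40503) %% 2147483647)
}
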