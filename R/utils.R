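#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published survey tables almost
#' always round half up. All percentages printed by this package use this
#' rule so that, e.g., 156/508 renders as 30.7.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5)      # 1
#' round_half_up(30.65, 1) # 30.7
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage of num/den, half-up to one decimal (NA when den == 0).
pct1 <- function(num, den) {
  den <- ifelse(den > 0, den, NA_real_)
  round_half_up(100 * num / den, 1)
}

# Derive an independent 31-bit substream seed from a top-level seed.
# Multipliers kept small so seed * 131071 stays well inside 2^53.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 131071 + k * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must be a probability in [0, 1]."))
  }
  invisible(x)
}
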