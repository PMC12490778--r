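#' Format a p value the way SCED reports print it
#'
#' Two decimals without a leading zero; values at or above 0.995 are
#' rendered as a bound (`">=.99"`) because a discrete randomization
#' distribution cannot distinguish them from 1.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.05, 0.45, 0.999))
format_p <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(
    p >= 0.995,
    ">=.99",
    sub("^0", "", formatC(round(p, 2), format = "f", digits = 2))
  )
  out[is.na(p)] <- NA_character_
  out
}

# Run `code` under a temporary RNG seed when `seed` is given, leaving the
# global RNG state untouched; without a seed the current stream is used.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Deterministic child seeds (31-bit) for per-participant streams.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_config <- function(msg) abort(msg, class = "scedrand_config_error")
stop_validation <- function(msg) abort(msg, class = "scedrand_validation_error")
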