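#' @importFrom rlang abort warn .data
#' @importFrom stats median sd var quantile rnorm runif rbinom rlnorm plogis
#'   qlogis complete.cases
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Deterministic fan-out of a master seed into per-stage / per-unit seeds.
# Keeps every derived seed a valid 32-bit R integer.
split_seed <- function(seed, n, salt = 0L) {
  stopifnot(length(seed) == 1, is.finite(seed))
  base <- (as.numeric(seed) * 48271 + as.numeric(salt) * 1000003) %% 2147483563
  as.integer((base + 999983 * seq_len(n)) %% 2147483563) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_in_range <- function(x, lo, hi, what) {
  if (any(!is.finite(x) | x < lo | x > hi)) {
    abort(sprintf("`%s` must lie in [%s, %s]", what, lo, hi))
  }
  invisible(x)
}

# Sample standard deviation that returns NA (not an error) below n = 2.
sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) NA_real_ else stats::sd(x)
}
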