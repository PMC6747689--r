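#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (0.70665 ->
#' 0.7067 at 4 digits), the convention used when reporting accuracy tables.
#' Base [round()] rounds half to even and would disagree on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 4) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a base seed plus any number of string/integer tags
#' to an integer in `[0, 2^31 - 2]`. Every source of randomness in the
#' package (fold assignment, per-member model fits, the synthetic generator)
#' draws its seed through this function, so a single pipeline seed controls
#' the whole analysis. The hash is a plain polynomial rolling hash over the
#' tag string modulo the Mersenne prime 2^31 - 1; it is stable across
#' platforms and R versions.
#'
#' @param seed integer base seed.
#' @param ... further tags (coerced to character) identifying the consumer,
#'   e.g. `derive_seed(1, "grid", "KRFP", "RF", 3)`.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
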