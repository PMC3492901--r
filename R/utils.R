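#' Harmonic and squared-harmonic numbers
#'
#' `a1_n(n)` returns \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}, `a2_n(n)` returns
#' \eqn{a_2 = \sum_{i=1}^{n-1} 1/i^2}. These scale the Watterson estimator
#' and the variance terms of the neutrality statistics.
#'
#' @param n haploid sample size (integer >= 2)
#' @return numeric scalar
#' @keywords internal
a1_n <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

#' @rdname a1_n
#' @keywords internal
a2_n <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1)^2)
}

#' Half-up percentage rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up to `decimals`
#' places, the convention used in the summary tables (R's own `round()`
#' rounds half-even).
#'
#' @param numerator,denominator counts; `denominator > 0` required for a
#'   defined result
#' @param decimals integer number of decimal places
#' @return numeric percentage, or `NA_real_` when `denominator` is zero or
#'   not finite
#' @examples
#' percent(4362, 23299, 2)  # 18.72
#' percent(83, 146, 0)      # 57
#' @export
percent <- function(numerator, denominator, decimals = 2) {
  if (!is.finite(denominator) || denominator == 0) return(NA_real_)
  x <- 100 * numerator / denominator
  scale <- 10^decimals
  floor(x * scale + 0.5) / scale
}

#' Derive a reproducible integer sub-seed from a master seed and a key
#'
#' Every stochastic step of a run draws its seed deterministically from the
#' run's master seed and a string key (usually a gene id plus a step name),
#' so any single gene can be replayed in isolation. Plain 32-bit multiply-
#' and-add string hash; the result is kept in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed
#' @param key character scalar
#' @return integer seed
#' @export
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (cc in utf8ToInt(as.character(key))) {
    h <- (h * 31 + cc) %% 2147483647
  }
  # similar keys give nearly consecutive hashes, and nearly consecutive
  # seeds start Mersenne-Twister in correlated states; three Lehmer steps
  # scatter them across the full range
  for (i in 1:3) h <- (h * 48271) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
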