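#' Nonparametric signal-detection indices and working-memory capacity
#'
#' `a_prime()` is the nonparametric sensitivity index: 0.5 at chance
#' (H = F, including both rates 0 or 1), 1 at perfect discrimination.
#' For H >= F,
#' \deqn{A' = 0.5 + \frac{(H - F)(1 + H - F)}{4 H (1 - F)}}
#' and for H < F the mirrored form
#' \deqn{A' = 0.5 - \frac{(F - H)(1 + F - H)}{4 F (1 - H)}.}
#'
#' `b_double_prime()` is the nonparametric response-bias index in
#' \[-1, 1\] (positive = conservative, negative = liberal, 0 = neutral):
#' for H >= F,
#' \deqn{B'' = \frac{H(1-H) - F(1-F)}{H(1-H) + F(1-F)}}
#' and for H < F the numerator is mirrored to `F(1-F) - H(1-H)`. The
#' index is undefined (`NA`) when the denominator vanishes, i.e. when both
#' rates are exactly 0 or 1. No loglinear or 1/(2N) correction is applied
#' to extreme rates; undefined cells are reported as missing.
#'
#' `wm_capacity()` is the composite working-memory score
#' `2 * (H - F)`, ranging -2..2. It is linear in the rates, so a group
#' mean capacity equals twice the difference of the group mean rates (an
#' identity that does not hold for the nonlinear A' and B'').
#'
#' @param h,f Hit and false-alarm rates in \[0, 1\]; vectorized.
#' @return Numeric vector of the same length.
#' @examples
#' a_prime(0.9, 0.1)          # 0.9444
#' b_double_prime(0.8, 0.1)   # 0.28
#' wm_capacity(0.887, 0.110)  # 1.554
#' @export
a_prime <- function(h, f) {
  check_rates(h, f)
  hi <- pmax(h, f)
  lo <- pmin(h, f)
  num <- (hi - lo) * (1 + hi - lo)
  den <- 4 * hi * (1 - lo)
  core <- ifelse(hi == lo, 0, num / den) # hi == lo covers the 0/0 limits
  0.5 + sign(h - f) * core
}

#' @rdname a_prime
#' @export
b_double_prime <- function(h, f) {
  check_rates(h, f)
  vh <- h * (1 - h)
  vf <- f * (1 - f)
  den <- vh + vf
  num <- ifelse(h >= f, vh - vf, vf - vh)
  ifelse(den == 0, NA_real_, num / den)
}

#' @rdname a_prime
#' @export
wm_capacity <- function(h, f) {
  check_rates(h, f)
  2 * (h - f)
}

check_rates <- function(h, f) {
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(h) || !ok(f)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  invisible(NULL)
}
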