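#' Fixed-point coefficient as a multiplier-shift pair
#'
#' On the target hardware every multiplication by a real coefficient is
#' realised as an integer multiply followed by an arithmetic right shift:
#' `x * b` becomes `floor((x * m) / 2^k)` with `b ~ m / 2^k`. An `fx_coeff`
#' bundles the real-valued target, the integer multiplier `m` and the shift
#' amount `k`.
#'
#' @param m non-negative integer multiplier.
#' @param k shift amount in bits (0--16).
#' @param target real value the pair approximates (defaults to `m / 2^k`).
#' @return An object of class `fx_coeff` with fields `target`, `m`, `k` and
#'   the exact dyadic `value` `m / 2^k`.
#' @seealso [quantize_coeff()] to derive the pair from a real target.
#' @export
fx_coeff <- function(m, k, target = m / 2^k) {
  m <- as.numeric(m)
  k <- as.integer(k)
  stopifnot(length(m) == 1L, length(k) == 1L, is.finite(m), m >= 0,
            m == floor(m), k >= 0L, k <= 16L)
  structure(list(target = as.numeric(target), m = m, k = k, value = m / 2^k),
            class = "fx_coeff")
}

#' @export
print.fx_coeff <- function(x, ...) {
  cat(sprintf("<fx_coeff> %g ~ %d/2^%d = %.10g\n", x$target, as.integer(x$m),
              x$k, x$value))
  invisible(x)
}

#' Quantize a real coefficient to the closest dyadic fraction
#'
#' Searches all multiplier-shift pairs `(m, k)` with `k <= k_max` and returns
#' the pair minimising `|target - m / 2^k|`; ties are broken toward the
#' smaller shift. With the default `k_max = 8` every coefficient printed in
#' the feature parameter tables is reproduced exactly at 4-decimal precision
#' (e.g. 0.9961 -> 255/256, 0.9688 -> 31/32, 0.0078 -> 1/128).
#'
#' @param target real coefficient in `[0, 64]`.
#' @param k_max largest admissible shift (1--16; `k = 0` is always searched so
#'   integer gains quantize exactly).
#' @return An [fx_coeff()].
#' @export
quantize_coeff <- function(target, k_max = 8L) {
  stopifnot(is.numeric(target), length(target) == 1L, is.finite(target))
  if (target < 0) stop("fixed-point coefficient targets must be non-negative")
  if (target > 64) stop("coefficient target outside the supported [0, 64] range")
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 1L, k_max <= 16L)
  best <- NULL
  for (k in 0:k_max) {
    m <- round(target * 2^k)
    err <- abs(target - m / 2^k)
    if (is.null(best) || err < best$err) best <- list(m = m, k = k, err = err)
  }
  fx_coeff(best$m, best$k, target)
}

as_fx_coeff <- function(x, k_max = 8L) {
  if (inherits(x, "fx_coeff")) return(x)
  quantize_coeff(x, k_max)
}

#' Scale a fixed-point value by a coefficient
#'
#' Computes `floor((v * m) / 2^k)` with the intermediate product evaluated at
#' double width, i.e. a hardware multiply followed by an arithmetic right
#' shift (flooring toward `-Inf` for negative values). Raises an error if `v`
#' leaves the signed 32-bit range or the intermediate product the 64-bit
#' range.
#'
#' @param v integer value(s), within the signed 32-bit range.
#' @param coeff an [fx_coeff()] or a real number (quantized on the fly).
#' @return Scaled integer value(s), as numeric.
#' @export
fx_scale <- function(v, coeff) {
  coeff <- as_fx_coeff(coeff)
  .fx_scale_cpp(as.numeric(v), coeff$m, coeff$k)
}

#' Saturate a value between bounds
#'
#' `min(max(v, lb), ub)`; the clamp used on feature accumulators to prevent
#' drift and to speed up class transitions. Idempotent.
#'
#' @param v numeric value(s).
#' @param lb,ub lower/upper bound, `lb <= ub`.
#' @export
fx_saturate <- function(v, lb, ub) {
  stopifnot(lb <= ub)
  pmin(pmax(v, lb), ub)
}

#' Dyadic EMA coefficient for a target time constant
#'
#' For the smoothing recursion `y_i = (y_{i-1} + f_i) * b`, the effective
#' time constant is `T = b / ((1 - b) * fs)`. This helper returns the dyadic
#' coefficient `m / 2^k`, `k <= k_max`, whose time constant is closest to
#' `tau_s`.
#'
#' @param tau_s target time constant in seconds.
#' @param fs sampling rate in Hz.
#' @param k_max largest admissible shift.
#' @return An [fx_coeff()] (its `target` field is set to the exact dyadic
#'   value actually used).
#' @export
ema_coeff_for_tau <- function(tau_s, fs, k_max = 8L) {
  stopifnot(tau_s > 0, fs > 0)
  best <- NULL
  for (k in 1:k_max) {
    for (m in 1:(2^k - 1)) {
      b <- m / 2^k
      err <- abs(b / ((1 - b) * fs) - tau_s)
      if (is.null(best) || err < best$err) best <- list(m = m, k = k, err = err)
    }
  }
  fx_coeff(best$m, best$k)
}
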