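#' Fresh recursion state for a feature variant
#'
#' The accumulator starts at the variant's lower bound, the smoothed signal,
#' sign bit, slope counters and delay buffers at zero, so start-up is benign
#' and absorbed by the transition tolerance of the evaluation.
#'
#' @param params a parameter list from [feature_params()] (or a variant name).
#' @return A state list (`feat`, `smo`, `s`, `w`, `p`, `aux`, `buf`, `pos`).
#' @export
new_feature_state <- function(params) {
  if (is.character(params)) params <- feature_params(params)
  list(feat = params$lb, smo = 0, s = 0L, w = 0, p = 0, aux = 0,
       buf = numeric(max(1L, params$delay)), pos = 0L)
}

#' Run one streaming feature over a sample block
#'
#' Updates the feature state machine once per input sample and returns the
#' (smoothed, saturated) feature value after each update. Because the state
#' is returned and can be passed back in, running the input in chunks of any
#' size is bit-identical to a single batch call.
#'
#' @param x input samples at 2 kHz (the comb/lowpass/highpass-filtered EMG,
#'   integer ADC counts; rounded when `arithmetic = "fixed"`).
#' @param params variant name or parameter list from [feature_params()].
#' @param state recursion state from a previous call, or `NULL` to start
#'   fresh.
#' @param arithmetic `"fixed"` runs the integer multiplier/shift path used on
#'   the embedded target; `"float"` runs the reference path with real-valued
#'   coefficients (both truncate after each scale operation, as the original
#'   design flow did, so the two paths differ only by coefficient
#'   quantization).
#' @return A list with `values` (numeric, one per input sample) and `state`.
#' @export
run_feature <- function(x, params, state = NULL,
                        arithmetic = c("fixed", "float")) {
  arithmetic <- match.arg(arithmetic)
  if (is.character(params)) params <- feature_params(params)
  if (is.null(state)) state <- new_feature_state(params)
  x <- as.numeric(x)
  if (arithmetic == "fixed") x <- round(x)
  res <- .feature_run_cpp(x, params, state, arithmetic == "fixed")
  list(values = res$values, state = res$state)
}

#' Run a bank of feature variants over the same input
#'
#' Drives every configured variant once per sample with the same input stream
#' and returns the feature matrix in canonical column order.
#'
#' @inheritParams run_feature
#' @param features character vector of variant names (default: all 26).
#' @param state named list of per-variant states from a previous call.
#' @return A list with `values` (matrix, one column per variant, columns in
#'   the order of `features`) and `state` (named list of per-variant states).
#' @export
feature_bank <- function(x, features = feature_names(), state = NULL,
                         arithmetic = c("fixed", "float")) {
  arithmetic <- match.arg(arithmetic)
  stopifnot(all(features %in% feature_names()))
  out <- matrix(0, nrow = length(x), ncol = length(features),
                dimnames = list(NULL, features))
  new_state <- vector("list", length(features))
  names(new_state) <- features
  for (f in features) {
    r <- run_feature(x, f, state = state[[f]], arithmetic = arithmetic)
    out[, f] <- r$values
    new_state[[f]] <- r$state
  }
  list(values = out, state = new_state)
}
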