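#' Integer sample stream with its sampling rate
#'
#' Lightweight container for the EMG carrier at the rates used in the
#' processing chain: 10 kHz raw, 2 kHz after decimation, 250/40 Hz after
#' feature downsampling.
#'
#' @param samples numeric vector of finite samples (ADC-scale counts).
#' @param fs sampling rate in Hz; one of 10000, 2000, 250, 40.
#' @export
signal_stream <- function(samples, fs) {
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  fs <- as.numeric(fs)
  if (!fs %in% c(10000, 2000, 250, 40))
    stop("fs must be one of 10000, 2000, 250, 40 Hz")
  structure(list(samples = as.numeric(samples), fs = fs),
            class = "signal_stream")
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("<signal_stream> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

.stream_samples <- function(x) if (inherits(x, "signal_stream")) x$samples else as.numeric(x)

# keep class/rate of output consistent with input
.restream <- function(template, samples, fs = NULL) {
  if (inherits(template, "signal_stream")) {
    signal_stream(samples, if (is.null(fs)) template$fs else fs)
  } else samples
}

#' Decimate by block averaging
#'
#' Each output sample is the floored mean of `factor` consecutive input
#' samples (10 kHz -> 2 kHz with the default factor); a trailing remainder
#' shorter than `factor` is dropped.
#'
#' @param x samples or [signal_stream()].
#' @param factor decimation factor.
#' @export
downsample_average <- function(x, factor = 5L) {
  v <- .stream_samples(x)
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  n <- (length(v) %/% factor) * factor
  out <- floor(colMeans(matrix(v[seq_len(n)], nrow = factor)))
  fs <- if (inherits(x, "signal_stream")) x$fs / factor else NULL
  if (inherits(x, "signal_stream")) signal_stream(out, fs) else out
}

#' Comb filter notching 50 Hz and its harmonics
#'
#' FIR difference `y_i = x_i - x_{i - fs/f0}` with zero-padded history, which
#' places zeros at DC, `f0`, `2 f0`, ... Exact in integer arithmetic.
#'
#' @param x samples or [signal_stream()].
#' @param fs sampling rate in Hz (taken from the stream if omitted).
#' @param f0 notch fundamental in Hz; `fs` must be divisible by `f0`.
#' @export
comb_filter <- function(x, fs = NULL, f0 = 50) {
  v <- .stream_samples(x)
  if (is.null(fs)) fs <- x$fs
  if (fs %% f0 != 0) stop("fs must be divisible by the comb fundamental f0")
  D <- fs / f0
  y <- v - c(numeric(D), v[seq_len(max(0, length(v) - D))])
  .restream(x, y)
}

.butter_filter <- function(v, order, fc, fs, type) {
  bt <- signal::butter(order, fc / (fs / 2), type = type)
  as.numeric(signal::filter(bt, v))
}

#' First-order recursive lowpass
#'
#' Bilinear (pre-warped) Butterworth design with its -3 dB point at `fc`;
#' 531 Hz is the cutoff of the acquisition chain.
#'
#' @inheritParams comb_filter
#' @param fc cutoff frequency in Hz.
#' @export
lowpass1 <- function(x, fs = NULL, fc = 531) {
  if (is.null(fs)) fs <- x$fs
  .restream(x, .butter_filter(.stream_samples(x), 1, fc, fs, "low"))
}

#' Second-order recursive highpass (feature path)
#'
#' Removes the sub-60 Hz band, where motion artifacts concentrate, before
#' feature calculation. Bilinear Butterworth design, zero DC gain.
#'
#' @inheritParams lowpass1
#' @export
highpass2 <- function(x, fs = NULL, fc = 60) {
  if (is.null(fs)) fs <- x$fs
  .restream(x, .butter_filter(.stream_samples(x), 2, fc, fs, "high"))
}

#' Simulated analog sensor front end
#'
#' Cascade of a first-order highpass (11 Hz) and a first-order lowpass
#' (1064 Hz), emulating the analog bandpass of the capacitive sensing chain.
#' Applied to synthetic raw signals only.
#'
#' @inheritParams comb_filter
#' @param fcl,fcu lower/upper cutoff in Hz.
#' @export
analog_frontend_sim <- function(x, fs = 10000, fcl = 11, fcu = 1064) {
  if (inherits(x, "signal_stream")) fs <- x$fs
  v <- .stream_samples(x)
  v <- .butter_filter(v, 1, fcl, fs, "high")
  v <- .butter_filter(v, 1, fcu, fs, "low")
  .restream(x, v)
}

#' Rectified, EMA-smoothed envelope
#'
#' `env_i = (env_{i-1} + |x_i|) * b` with the dyadic coefficient whose
#' effective time constant `b/((1-b) fs)` is closest to `tau_ms`. Note the
#' recursion has DC gain `b/(1-b)`, so the envelope sits on an amplified
#' scale relative to `|x|`.
#'
#' @inheritParams comb_filter
#' @param tau_ms smoothing time constant in milliseconds.
#' @param arithmetic `"fixed"` (integer multiplier/shift) or `"float"`
#'   (real coefficient, still truncating; see [run_feature()]).
#' @param coeff optionally an explicit [fx_coeff()] overriding `tau_ms`.
#' @export
rectify_smooth <- function(x, fs = 2000, tau_ms = 51,
                           arithmetic = c("fixed", "float"), coeff = NULL) {
  arithmetic <- match.arg(arithmetic)
  if (inherits(x, "signal_stream")) fs <- x$fs
  if (is.null(coeff)) coeff <- ema_coeff_for_tau(tau_ms / 1000, fs)
  v <- abs(.stream_samples(x))
  if (arithmetic == "fixed") v <- round(v)
  res <- .ema_run_cpp(v, coeff$m, coeff$k, coeff$target,
                      arithmetic == "fixed", 0, 0, 2^31 - 1)
  .restream(x, res$values)
}

#' Pure delay line
#'
#' Shifts the stream by `round(delay_ms * fs / 1000)` samples with a
#' zero-padded head; used to align the envelope with the (slower) decision.
#'
#' @inheritParams comb_filter
#' @param delay_ms delay in milliseconds.
#' @export
delay_line <- function(x, fs = NULL, delay_ms = 100) {
  v <- .stream_samples(x)
  if (is.null(fs)) fs <- x$fs
  D <- round(delay_ms * fs / 1000)
  y <- c(numeric(min(D, length(v))), v[seq_len(max(0, length(v) - D))])
  .restream(x, y)
}

#' Digital pre-processing of one raw 10 kHz segment
#'
#' Front-end simulation (synthetic data only), averaging decimation to 2 kHz,
#' 50 Hz comb, 531 Hz lowpass, and a single rounding to integer counts. The
#' result is the 2 kHz carrier consumed by the feature bank (after the 60 Hz
#' highpass) and by the envelope.
#'
#' @param x raw samples at 10 kHz (vector or [signal_stream()]).
#' @param frontend apply [analog_frontend_sim()] first (use `TRUE` for
#'   synthetic raw signals, `FALSE` for data recorded behind a real front
#'   end).
#' @return Integer-valued numeric vector at 2 kHz (or a [signal_stream()]).
#' @export
preprocess_segment <- function(x, frontend = TRUE) {
  v <- .stream_samples(x)
  if (frontend) v <- analog_frontend_sim(v, fs = 10000)
  v <- downsample_average(v, 5L)
  v <- comb_filter(v, fs = 2000, f0 = 50)
  v <- lowpass1(v, fs = 2000, fc = 531)
  v <- round(v)
  if (inherits(x, "signal_stream")) signal_stream(v, 2000) else v
}
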