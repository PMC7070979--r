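# Seeded generator of labelled contraction and artifact signals. The original
# single-subject recordings are not deposited, so this module emulates their
# statistical structure: band-limited (60-500 Hz) contraction EMG under
# trapezoidal activation envelopes at strong/weak/short intensities, and
# low-frequency, large-amplitude artifacts (sensor lift-off, mechanical
# shock, vibration) with a deliberate 10-30% broadband admixture so that
# artifacts also occupy the contraction band and cannot be removed by
# filtering alone.

#' Generator configuration
#'
#' Defaults follow the study conditions: 10 kHz raw rate, per-class time
#' budgets of 381 s (contractions) and 489 s (artifacts), and a contraction
#' band of 60--500 Hz. Amplitudes are calibrated so that a strong contraction
#' has an RMS of 300 ADC counts, which puts the fixed feature thresholds
#' (hysteresis 242, Willison threshold 44, ...) on a meaningful scale; the
#' additive noise floor is 5% of that RMS.
#'
#' @param fs_raw raw sampling rate in Hz.
#' @param budget_contraction_s,budget_artifact_s per-class time budgets in
#'   seconds.
#' @param strong_rms RMS of a strong contraction in ADC counts.
#' @param noise_rms RMS of the additive sensor noise floor.
#' @param band contraction EMG band in Hz.
#' @param contraction_mix,artifact_mix named time-share of the subtypes
#'   within each class budget.
#' @param seed master seed; together with the budgets it fully determines the
#'   corpus.
#' @return A list of class `emg_gen_config`.
#' @export
generator_config <- function(fs_raw = 10000,
                             budget_contraction_s = 381,
                             budget_artifact_s = 489,
                             strong_rms = 300,
                             noise_rms = 0.05 * strong_rms,
                             band = c(60, 500),
                             contraction_mix = c(strong = 0.4, weak = 0.3, short = 0.3),
                             artifact_mix = c(liftoff = 1, shock = 1, vibration = 1) / 3,
                             seed = 1L) {
  stopifnot(budget_contraction_s > 0, budget_artifact_s > 0,
            abs(sum(contraction_mix) - 1) < 1e-9,
            abs(sum(artifact_mix) - 1) < 1e-9)
  structure(list(fs_raw = fs_raw,
                 budget_contraction_s = budget_contraction_s,
                 budget_artifact_s = budget_artifact_s,
                 strong_rms = strong_rms, noise_rms = noise_rms, band = band,
                 contraction_mix = contraction_mix,
                 artifact_mix = artifact_mix, seed = as.integer(seed)),
            class = "emg_gen_config")
}

#' Specification of one generated segment
#'
#' @param cls `"contraction"` or `"artifact"`.
#' @param subtype `"strong"`, `"weak"`, `"short"` (contractions) or
#'   `"liftoff"`, `"shock"`, `"vibration"` (artifacts).
#' @param duration_s segment duration in seconds (> 0; short contractions are
#'   at most 0.4 s).
#' @param seed child seed the segment is generated from.
#' @export
segment_spec <- function(cls, subtype, duration_s, seed) {
  cls <- match.arg(cls, c("contraction", "artifact"))
  subtype <- match.arg(subtype, c("strong", "weak", "short",
                                  "liftoff", "shock", "vibration"))
  stopifnot(duration_s > 0)
  if (subtype == "short" && duration_s > 0.4)
    stop("short contractions are at most 0.4 s long")
  structure(list(cls = cls, subtype = subtype, duration_s = duration_s,
                 seed = as.integer(seed)), class = "segment_spec")
}

# band-limited zero-mean Gaussian noise, unit RMS. `tilt_fc` optionally adds
# a first-order spectral roll-off inside the band: surface EMG spectra are
# peaked near 60-150 Hz with a decaying tail, and the knee varies between
# contractions, so crossing-rate statistics are not a fixed function of
# amplitude.
.band_noise <- function(n, band, fs, tilt_fc = NULL) {
  v <- .butter_filter(rnorm(n + 2000), 4, band[2], fs, "low")
  v <- .butter_filter(v, 4, band[1], fs, "high")
  if (!is.null(tilt_fc)) v <- .butter_filter(v, 1, tilt_fc, fs, "low")
  v <- v[-seq_len(2000)]  # discard filter warm-up
  v / sd(v)
}

# slow multiplicative effort drift (~0.3 Hz, +/-`depth`): isometric holds are
# not perfectly stationary
.effort_drift <- function(n, fs, depth = 0.25) {
  d <- .butter_filter(rnorm(n + 4000), 2, 0.3, fs, "low")[-seq_len(4000)]
  1 + depth * pmin(pmax(d / sd(d), -2), 2) / 2
}

# trapezoidal activation envelope with given rise/fall times
.trapezoid <- function(n, fs, rise_s, fall_s) {
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  pmax(0, pmin(1, t / rise_s, (dur - t) / fall_s))
}

#' Generate one contraction segment
#'
#' Band-limited Gaussian EMG under a trapezoidal envelope (rise/fall 50--150
#' ms). Subtype amplitude scales: strong 1.0, weak 0.3; short contractions
#' (<= 0.4 s) additionally carry a low-frequency (2--10 Hz) bump at onset and
#' offset, about 30% of the envelope peak, emulating the slight motion
#' artifact superimposed by the muscle moving under the skin.
#'
#' @param spec a [segment_spec()] with `cls = "contraction"`.
#' @param config a [generator_config()].
#' @return Integer-valued numeric vector at `config$fs_raw` (noise floor
#'   included).
#' @export
gen_contraction <- function(spec, config = generator_config()) {
  stopifnot(spec$cls == "contraction")
  fs <- config$fs_raw
  n <- round(spec$duration_s * fs)
  with_seed(spec$seed, {
    scale <- switch(spec$subtype, strong = 1, short = 1, weak = 0.3)
    rms <- config$strong_rms * scale
    rise <- runif(1, 0.05, 0.15)
    fall <- runif(1, 0.05, 0.15)
    env <- .trapezoid(n, fs, rise, fall)
    tilt <- runif(1, 100, 350)  # per-contraction spectral knee
    x <- .band_noise(n, config$band, fs, tilt_fc = tilt) * rms * env *
      .effort_drift(n, fs)
    if (spec$subtype == "short") {
      # onset/offset motion bump: half-sine at 2-10 Hz, ~30% of envelope peak
      fb <- runif(1, 2, 10)
      bl <- min(round(fs / (2 * fb)), n %/% 2)
      bump <- sin(pi * seq_len(bl) / bl) * 0.3 * 3 * rms
      x[seq_len(bl)] <- x[seq_len(bl)] + bump
      x[n - bl + seq_len(bl)] <- x[n - bl + seq_len(bl)] - rev(bump)
    }
    round(x + rnorm(n, 0, config$noise_rms))
  })
}

#' Generate one artifact segment
#'
#' Artifact morphologies: `liftoff` is a smooth 0.5--5 Hz excursion at 3--10x
#' the strong-contraction RMS; `shock` an exponentially damped oscillation
#' burst; `vibration` a 5--30 Hz tone with decaying harmonics. Every artifact
#' is mixed with 10--30% broadband power inside the contraction band, since
#' real artifacts also reach into the EMG band.
#'
#' @param spec a [segment_spec()] with `cls = "artifact"`.
#' @inheritParams gen_contraction
#' @return Integer-valued numeric vector at `config$fs_raw`. The attribute
#'   `"decay_tau_s"` is set for shocks.
#' @export
gen_artifact <- function(spec, config = generator_config()) {
  stopifnot(spec$cls == "artifact")
  fs <- config$fs_raw
  n <- round(spec$duration_s * fs)
  rms0 <- config$strong_rms
  with_seed(spec$seed, {
    t <- (seq_len(n) - 1) / fs
    tau <- NULL
    x <- switch(spec$subtype,
      liftoff = {
        v <- .butter_filter(rnorm(n + 4000), 2, 5, fs, "low")
        v <- .butter_filter(v, 1, 0.5, fs, "high")[-seq_len(4000)]
        v / max(abs(v)) * runif(1, 3, 10) * rms0
      },
      shock = {
        tau <- runif(1, 0.05, 0.2)
        t0 <- runif(1, 0, 0.3) * spec$duration_s
        f <- runif(1, 10, 40)  # ring-down of the soft tissue/sensor assembly
        amp <- runif(1, 3, 10) * rms0
        ifelse(t >= t0, amp * exp(-(t - t0) / tau) * sin(2 * pi * f * (t - t0)), 0)
      },
      vibration = {
        f <- runif(1, 5, 30)
        amp <- runif(1, 1, 4) * rms0
        ph <- runif(3, 0, 2 * pi)
        amp * (sin(2 * pi * f * t + ph[1]) +
               0.5 * sin(2 * pi * 2 * f * t + ph[2]) +
               0.25 * sin(2 * pi * 3 * f * t + ph[3]))
      })
    # motion-correlated broadband admixture: friction/triboelectric hash in
    # the contraction band, modulated by the instantaneous artifact motion
    # and scaled per segment over a wide (log-uniform) range topping out near
    # the weak-contraction level. Artifacts therefore reach into the EMG band
    # -- so in-band filtering alone cannot remove them -- with an intensity
    # that varies within and between artifacts. (Scaling by the artifact's
    # full amplitude would put more EMG-band power into artifacts than into
    # the contractions themselves.)
    mot <- .butter_filter(abs(x), 1, 2, fs, "low")
    mot <- pmax(mot, 0) / max(abs(mot), 1e-9)
    amp <- config$strong_rms * 0.5 * 10^runif(1, log10(0.03), log10(0.5))
    bb <- .band_noise(n, config$band, fs, tilt_fc = runif(1, 100, 350)) *
      amp * mot
    out <- round(x + bb + rnorm(n, 0, config$noise_rms))
    if (!is.null(tau)) attr(out, "decay_tau_s") <- tau
    out
  })
}

# subtype-specific duration ranges in seconds
.segment_duration <- function(subtype) {
  switch(subtype,
         # sustained isometric holds, acquired as ~10 s takes
         strong = runif(1, 8, 12), weak = runif(1, 8, 12),
         short = runif(1, 0.15, 0.4),
         liftoff = runif(1, 1, 3), shock = runif(1, 0.5, 1.5),
         vibration = runif(1, 1, 3))
}

#' Generate a labelled corpus of raw segments
#'
#' Draws segments per subtype until each subtype's share of the per-class
#' budget is met (so strong/weak/short contractions and the artifact types
#' are represented in their configured time shares). All randomness flows
#' from the master seed through per-segment child seeds; the same
#' configuration always yields the identical corpus.
#'
#' @param config a [generator_config()].
#' @return A list of class `emg_corpus`: elements are lists with `samples`
#'   (raw 10 kHz integers) and `spec` (a [segment_spec()]).
#' @export
gen_corpus <- function(config = generator_config()) {
  segments <- list()
  with_seed(config$seed, {
    for (cls in c("contraction", "artifact")) {
      budget <- if (cls == "contraction") config$budget_contraction_s else config$budget_artifact_s
      mix <- if (cls == "contraction") config$contraction_mix else config$artifact_mix
      for (subtype in names(mix)) {
        need <- budget * mix[[subtype]]
        got <- 0
        while (got < need) {
          dur <- min(.segment_duration(subtype), max(need - got, 0.15))
          if (subtype == "short") dur <- min(dur, 0.4)
          child <- sample.int(.Machine$integer.max - 1L, 1L)
          spec <- segment_spec(cls, subtype, dur, child)
          samples <- if (cls == "contraction") gen_contraction(spec, config)
                     else gen_artifact(spec, config)
          segments[[length(segments) + 1L]] <- list(samples = samples, spec = spec)
          got <- got + dur
        }
      }
    }
  })
  structure(segments, class = "emg_corpus", config = config)
}

#' @export
print.emg_corpus <- function(x, ...) {
  cls <- vapply(x, function(s) s$spec$cls, character(1))
  dur <- vapply(x, function(s) s$spec$duration_s, numeric(1))
  cat(sprintf("<emg_corpus> %d segments: %.1f s contraction, %.1f s artifact\n",
              length(x), sum(dur[cls == "contraction"]),
              sum(dur[cls == "artifact"])))
  invisible(x)
}

#' Activation threshold for small-signal removal
#'
#' Windows whose rectified, smoothed envelope never exceeds this threshold
#' would not activate the prosthesis drive and are removed from the data set.
#' The default is three times the envelope level of the configured noise
#' floor (mean rectified noise times the DC gain of the envelope EMA).
#'
#' @inheritParams gen_corpus
#' @param fs rate of the envelope stream in Hz.
#' @param tau_ms envelope smoothing time constant in milliseconds.
#' @export
small_signal_threshold <- function(config = generator_config(), fs = 2000,
                                   tau_ms = 51) {
  b <- ema_coeff_for_tau(tau_ms / 1000, fs)$value
  gain <- b / (1 - b)
  3 * config$noise_rms * sqrt(2 / pi) * gain
}
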