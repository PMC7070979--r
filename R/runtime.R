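# Online decision post-processing: debounce against single wrong decisions,
# alignment of the (slow) decision with the delayed EMG envelope, and the
# gated output that actually drives the prosthesis.

#' Debounce a binary decision stream
#'
#' The output switches to a new class only after observing strictly more than
#' `n_slope` consecutive decisions of that class, i.e. at the
#' `(n_slope + 1)`-th; any interruption resets the run counter. The initial
#' output state is artifact (0), which is fail-safe: no activation at
#' start-up. The alternative reading "exactly `n_slope` equal decisions" is
#' available via `rule = "geq"`.
#'
#' @param decisions integer 0/1 stream.
#' @param n_slope required run length minus one (offline: 2 for nn / tree /
#'   logistic regression, 3 for the rnn; online at the full 2 kHz decision
#'   rate: 20, rnn unchanged at 3).
#' @param init initial output state.
#' @param rule `"greater"` (switch after more than `n_slope`) or `"geq"`.
#' @return Integer 0/1 stream of the same length.
#' @export
debounce <- function(decisions, n_slope, init = 0L, rule = c("greater", "geq")) {
  rule <- match.arg(rule)
  stopifnot(n_slope >= 1)
  .debounce_cpp(as.integer(decisions), as.integer(n_slope), as.integer(init),
                rule == "greater")
}

#' Gate the envelope with the debounced decision
#'
#' Decision 1 passes the delayed envelope through; decision 0 either turns
#' the drive off (`policy = "off"`) or holds the last contraction-phase
#' output value (`policy = "hold"`).
#'
#' @param decisions debounced 0/1 stream.
#' @param envelope delayed envelope stream (same length and rate).
#' @param policy `"off"` or `"hold"`.
#' @return Numeric output stream: 0 (or the held value) during artifacts, the
#'   envelope during contractions.
#' @export
gate_output <- function(decisions, envelope, policy = c("off", "hold")) {
  policy <- match.arg(policy)
  stopifnot(length(decisions) == length(envelope))
  if (policy == "off") return(ifelse(decisions == 1, envelope, 0))
  src <- cummax(ifelse(decisions == 1, seq_along(envelope), 0L))
  ifelse(src == 0, 0, envelope[pmax(src, 1L)])
}

#' Align a decision stream with the delayed envelope
#'
#' Delays the envelope by `delay_ms` so that it corresponds in time to the
#' decision (which lags by the feature smoothing and the debounce), and
#' up-samples the decision stream to the envelope rate by zero-order hold.
#'
#' @param decisions 0/1 stream at `dec_rate`.
#' @param dec_rate decision rate in Hz.
#' @param envelope envelope stream at `env_rate`.
#' @param env_rate envelope rate in Hz (integer multiple of `dec_rate`).
#' @param delay_ms additional envelope delay in ms.
#' @return List with equal-length `decisions` and `envelope` at `env_rate`.
#' @export
align_streams <- function(decisions, dec_rate, envelope, env_rate,
                          delay_ms = 100) {
  if (env_rate %% dec_rate != 0)
    stop("env_rate must be an integer multiple of dec_rate")
  rep_n <- env_rate / dec_rate
  d <- rep(decisions, each = rep_n)
  e <- delay_line(envelope, fs = env_rate, delay_ms = delay_ms)
  n <- min(length(d), length(e))
  list(decisions = d[seq_len(n)], envelope = e[seq_len(n)])
}

#' Full online decision trace for a processed signal
#'
#' Streams a 2 kHz carrier through the feature bank and a quantized model,
#' debounces the raw decisions, aligns the rectified envelope, and gates the
#' output: the complete online post-processing chain behind the
#' digital-to-analog output.
#'
#' @param model a (quantized) `emg_model`. The feed-forward families decide
#'   at every 2 kHz sample (hence the larger online `n_slope` of 20); the
#'   recurrent net keeps its training rate of 250 Hz and `n_slope = 3`.
#' @param x2k processed 2 kHz carrier (integer counts, e.g. from
#'   [preprocess_segment()]).
#' @param n_slope debounce length; defaults to 20 (3 for the rnn).
#' @param policy gating policy, see [gate_output()].
#' @param delay_ms envelope alignment delay.
#' @return A `data.frame` (per 2 kHz step): `raw` and `decision` (debounced)
#'   0/1 streams, the delayed `envelope`, and the gated `output`.
#' @export
decision_trace <- function(model, x2k, n_slope = NULL,
                           policy = c("off", "hold"), delay_ms = 100) {
  policy <- match.arg(policy)
  if (is.null(n_slope)) n_slope <- if (model$family == "rnn") 3L else 20L
  X <- compute_features(x2k, features = model$features)
  dec_rate <- if (model$family == "rnn") 250 else 2000
  if (dec_rate != 2000) X <- downsample_features(X, 2000, dec_rate)
  raw <- predict_model(model, X)$decision
  deb <- debounce(raw, n_slope)
  env <- rectify_smooth(x2k, fs = 2000)
  al <- align_streams(deb, dec_rate, env, 2000, delay_ms = delay_ms)
  raw2k <- rep(raw, each = 2000 / dec_rate)[seq_along(al$decisions)]
  data.frame(raw = raw2k, decision = al$decisions, envelope = al$envelope,
             output = gate_output(al$decisions, al$envelope, policy))
}
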