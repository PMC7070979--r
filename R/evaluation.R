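# Transition-tolerant scoring: samples within a fixed window after each
# ground-truth class transition are excluded from the error count, so that
# the unavoidable reaction lag of the smoothed features does not dominate the
# score; everything later than the tolerance counts, which favours fast
# models.

# logical mask of samples excluded after each target transition
transition_mask <- function(target, tol_steps) {
  excl <- rep(FALSE, length(target))
  if (tol_steps <= 0 || length(target) < 2) return(excl)
  for (t in which(diff(target) != 0) + 1L) {
    excl[t:min(length(target), t + tol_steps - 1L)] <- TRUE
  }
  excl
}

#' Transition-tolerant accuracy and confusion matrix
#'
#' Excludes the `round(tol_ms * rate / 1000)` samples after every transition
#' of the target, then tallies the remaining samples into a confusion matrix
#' with contraction (1) as the positive class.
#'
#' @param pred predicted 0/1 stream (time order).
#' @param target ground-truth 0/1 stream.
#' @param tol_ms tolerance in ms (100 during training/validation, 150 for
#'   test scoring).
#' @param rate stream rate in Hz.
#' @param subtype optional per-sample subtype labels for a per-subtype
#'   accuracy breakdown.
#' @return An `eval_report`: confusion counts `tp`, `fn`, `fp`, `tn`,
#'   `accuracy` (percent, two decimals, half-up), `n_counted`, `n_excluded`
#'   and the optional `by_subtype` table.
#' @export
tolerant_accuracy <- function(pred, target, tol_ms, rate, subtype = NULL) {
  stopifnot(length(pred) == length(target))
  tol_steps <- round(tol_ms * rate / 1000)
  excl <- transition_mask(target, tol_steps)
  keep <- !excl
  p <- pred[keep]
  y <- target[keep]
  rep_ <- list(tp = sum(p == 1 & y == 1), fn = sum(p == 0 & y == 1),
               fp = sum(p == 1 & y == 0), tn = sum(p == 0 & y == 0),
               n_counted = sum(keep), n_excluded = sum(excl),
               tol_ms = tol_ms, rate = rate)
  rep_$accuracy <- accuracy_from_confusion(rep_$tp, rep_$fn, rep_$fp, rep_$tn)
  if (!is.null(subtype)) {
    st <- subtype[keep]
    rep_$by_subtype <- vapply(split(seq_along(st), st), function(i)
      round_half_up(100 * mean(p[i] == y[i]), 2), numeric(1))
  }
  structure(rep_, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%% (tol %g ms @ %g Hz)\n",
              x$accuracy, x$tol_ms, x$rate))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("actual contraction", "actual artifact"),
                              c("pred contraction", "pred artifact")))
  print(m)
  cat(sprintf("counted %d samples, excluded %d around transitions\n",
              x$n_counted, x$n_excluded))
  if (!is.null(x$by_subtype)) {
    cat("per-subtype accuracy (%):\n")
    print(x$by_subtype)
  }
  invisible(x)
}

#' Accuracy from confusion-matrix counts
#'
#' `100 (TP + TN) / (TP + FN + FP + TN)`, rounded half-up to two decimals
#' (contraction is the positive class).
#'
#' @param tp,fn,fp,tn confusion counts.
#' @return Accuracy in percent.
#' @export
accuracy_from_confusion <- function(tp, fn, fp, tn) {
  round_half_up(100 * (tp + tn) / (tp + fn + fp + tn), 2)
}

#' Effective time constant of the feature EMA
#'
#' For the recursion `feat_i = (feat_{i-1} + f_i) b` the impulse response
#' decays by `b` per sample, giving the effective time constant
#' `T = b / ((1 - b) fs)`. With the exact dyadic coefficients this evaluates
#' to 63.5 ms for `b = 254/256` and 127.5 ms for `b = 255/256` at 2 kHz.
#'
#' @param b EMA coefficient: an [fx_coeff()] (its exact dyadic value is
#'   used) or a plain number in `[0, 1)`.
#' @param fs sampling rate in Hz.
#' @return Time constant in milliseconds.
#' @export
ema_time_constant <- function(b, fs = 2000) {
  bv <- if (inherits(b, "fx_coeff")) b$value else as.numeric(b)
  stopifnot(bv >= 0, bv < 1)
  1000 * bv / ((1 - bv) * fs)
}

#' Accuracy sweep over the model grid
#'
#' Trains and evaluates every family / feature-count (/ hidden-width) cell on
#' the same corpus splits and returns the accuracy grid (rows: NN and RNN at
#' 3/6/9 hidden units, decision tree, logistic regression; columns: feature
#' counts). All cells are scored as quantized, debounced decisions at the
#' 150 ms test tolerance.
#'
#' @param ds40 `emg_dataset` at 40 Hz (logreg / tree / nn).
#' @param ds250 `emg_dataset` at 250 Hz with varied windows (rnn).
#' @param n_features feature-count grid.
#' @param hidden_units hidden widths for the network rows.
#' @param families which families to include.
#' @param max_epochs named epoch caps (`nn`, `rnn`), reduce for quick sweeps.
#' @param seed network initialization seed.
#' @return A data frame: one row per model, one column per feature count.
#' @export
sweep_models <- function(ds40, ds250 = NULL,
                         n_features = c(3, 6, 9, 12),
                         hidden_units = c(3, 6, 9),
                         families = c("nn", "rnn", "tree", "logreg"),
                         max_epochs = c(nn = 1000, rnn = 100), seed = 1L) {
  rows <- list()
  add_row <- function(label, family, ds, hidden = NULL, epochs = NULL) {
    acc <- vapply(n_features, function(nf) {
      fit <- cv_train(ds, family, n_features = nf,
                      hidden_units = hidden %||% c(3L, 6L, 9L),
                      max_epochs = epochs, seed = seed)
      evaluate_on_test(quantize_model(fit$model), ds)$accuracy
    }, numeric(1))
    rows[[label]] <<- acc
  }
  if ("nn" %in% families) {
    for (h in hidden_units)
      add_row(sprintf("NN (%d HU)", h), "nn", ds40, hidden = h,
              epochs = max_epochs[["nn"]])
  }
  if ("rnn" %in% families && !is.null(ds250)) {
    for (h in hidden_units)
      add_row(sprintf("RNN (%d HU)", h), "rnn", ds250, hidden = h,
              epochs = max_epochs[["rnn"]])
  }
  if ("tree" %in% families) add_row("Decision Tree", "tree", ds40)
  if ("logreg" %in% families) add_row("Log. Regression", "logreg", ds40)
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- as.character(n_features)
  out
}
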