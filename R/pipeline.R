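# Dataset assembly: alternating labelled windows, small-signal removal,
# feature matrices, correlation pruning, min-max normalization, feature-rate
# decimation and contiguous stratified splits.

# Proportional interleave (largest-remainder): a label sequence in which every
# prefix holds each group close to its overall share. Used to alternate the
# two classes and to cycle subtypes within a class, so that any contiguous
# block of windows is representative.
.interleave <- function(counts) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  labels <- names(counts)
  used <- stats::setNames(numeric(length(counts)), labels)
  out <- character(total)
  for (i in seq_len(total)) {
    deficit <- counts / total * i - used
    deficit[used >= counts] <- -Inf
    j <- which.max(deficit)
    out[i] <- labels[j]
    used[j] <- used[j] + 1
  }
  out
}

#' Pre-process every raw segment of a corpus to 2 kHz
#'
#' @param corpus an `emg_corpus` from [gen_corpus()] (or any list of
#'   `list(samples, spec)` elements with raw 10 kHz samples).
#' @return The same structure with `samples` replaced by the 2 kHz
#'   integer-valued output of [preprocess_segment()].
#' @export
preprocess_corpus <- function(corpus) {
  out <- lapply(corpus, function(s) {
    list(samples = preprocess_segment(s$samples), spec = s$spec)
  })
  attributes(out) <- attributes(corpus)
  out
}

#' Assemble alternating labelled windows
#'
#' Concatenates the pre-processed segments into per-subtype pools, cuts the
#' pools into windows (fixed 1 s, or uniformly 0.5--1.5 s when `vary` is set,
#' which prevents a recurrent model from learning the window period), and
#' interleaves them so that contraction and artifact windows alternate and
#' subtypes cycle proportionally. Trailing pool remainders shorter than a
#' window are dropped.
#'
#' @param segments output of [preprocess_corpus()].
#' @param window_s window duration in seconds when `vary = FALSE`.
#' @param vary draw each window's duration uniformly from 0.5--1.5 s.
#' @param seed seed for the duration draws (only used when `vary = TRUE`).
#' @param fs sampling rate of the segments in Hz.
#' @return A list of class `emg_windows`; each element has `samples`, `cls`
#'   (1 contraction / 0 artifact), `subtype` and `duration_s`.
#' @export
assemble_alternating <- function(segments, window_s = 1, vary = FALSE,
                                 seed = 1L, fs = 2000) {
  cls <- vapply(segments, function(s) s$spec$cls, character(1))
  subtype <- vapply(segments, function(s) s$spec$subtype, character(1))
  pool_of <- split(seq_along(segments), paste(cls, subtype, sep = "."))
  pools <- lapply(pool_of, function(idx)
    unlist(lapply(segments[idx], function(s) s$samples), use.names = FALSE))

  cut_pool <- function(v) {
    lens <- if (vary) {
      out <- numeric(0)
      left <- length(v)
      while (left >= 1.5 * fs) {
        d <- round(runif(1, 0.5, 1.5) * fs)
        out <- c(out, d)
        left <- left - d
      }
      if (left >= 0.5 * fs) out <- c(out, left)
      out
    } else {
      rep(window_s * fs, length(v) %/% (window_s * fs))
    }
    ends <- cumsum(lens)
    lapply(seq_along(lens), function(i)
      v[(ends[i] - lens[i] + 1):ends[i]])
  }

  windows_by_pool <- with_seed(seed, lapply(pools, cut_pool))
  counts <- lengths(windows_by_pool)

  # subtype order within each class, then class alternation
  next_i <- stats::setNames(rep(1L, length(counts)), names(counts))
  seq_for <- function(class_name) {
    cnt <- counts[grep(paste0("^", class_name, "\\."), names(counts))]
    .interleave(cnt)
  }
  class_counts <- c(
    contraction = sum(counts[grep("^contraction", names(counts))]),
    artifact = sum(counts[grep("^artifact", names(counts))]))
  class_seq <- .interleave(class_counts)
  sub_seq <- list(contraction = seq_for("contraction"),
                  artifact = seq_for("artifact"))
  sub_pos <- c(contraction = 0L, artifact = 0L)

  windows <- vector("list", length(class_seq))
  for (i in seq_along(class_seq)) {
    cl <- class_seq[i]
    sub_pos[cl] <- sub_pos[cl] + 1L
    pool <- sub_seq[[cl]][sub_pos[cl]]
    j <- next_i[pool]
    next_i[pool] <- j + 1L
    smp <- windows_by_pool[[pool]][[j]]
    windows[[i]] <- list(samples = smp,
                         cls = as.integer(cl == "contraction"),
                         subtype = sub("^[a-z]+\\.", "", pool),
                         duration_s = length(smp) / fs)
  }
  structure(windows, class = "emg_windows", fs = fs)
}

#' @export
print.emg_windows <- function(x, ...) {
  cls <- vapply(x, `[[`, integer(1), "cls")
  cat(sprintf("<emg_windows> %d windows (%d contraction / %d artifact), %.1f s total\n",
              length(x), sum(cls == 1), sum(cls == 0),
              sum(vapply(x, `[[`, numeric(1), "duration_s"))))
  invisible(x)
}

#' Remove windows with small signals
#'
#' Drops windows whose rectified, smoothed envelope never exceeds the
#' activation threshold: such windows would not drive the prosthesis and are
#' excluded from training and evaluation.
#'
#' @param windows an `emg_windows` list.
#' @param threshold activation threshold on the envelope scale; see
#'   [small_signal_threshold()].
#' @export
remove_small_signal <- function(windows, threshold) {
  fs <- attr(windows, "fs")
  keep <- vapply(windows, function(w)
    any(rectify_smooth(w$samples, fs = fs) > threshold), logical(1))
  structure(windows[keep], class = "emg_windows", fs = fs)
}

# concatenated sample timeline of a window sequence
.timeline <- function(windows) {
  lens <- vapply(windows, function(w) length(w$samples), integer(1))
  list(x = unlist(lapply(windows, `[[`, "samples"), use.names = FALSE),
       target = rep(vapply(windows, `[[`, integer(1), "cls"), lens),
       window = rep(seq_along(windows), lens))
}

#' Feature matrix over a window timeline
#'
#' Runs the feature bank continuously across window boundaries (feature
#' state is not reset at transitions, as in streaming operation). The
#' features consume the comb- and lowpass-filtered carrier directly: the
#' sub-60 Hz band is where motion artifacts live, and the bank's smoothed
#' references and hysteresis thresholds are designed to see and reject that
#' content. Set `highpass = TRUE` to interpose the 60 Hz second-order
#' highpass instead, which confines every feature to the EMG band.
#'
#' @param x 2 kHz integer samples (a concatenated window timeline).
#' @param features variant names; default all 26.
#' @param arithmetic see [run_feature()].
#' @param highpass apply [highpass2()] before the bank.
#' @return Numeric matrix, one column per feature at 2 kHz.
#' @export
compute_features <- function(x, features = feature_names(),
                             arithmetic = c("fixed", "float"),
                             highpass = FALSE) {
  if (highpass) x <- round(highpass2(x, fs = 2000))
  feature_bank(x, features = features, arithmetic = match.arg(arithmetic))$values
}

#' Decimate a feature stream
#'
#' Takes every `(from/to)`-th sample starting at the first one; the EMA
#' smoothing inside every feature has already band-limited the stream, so no
#' additional averaging is applied.
#'
#' @param x feature matrix (rows = samples) or vector.
#' @param from,to source and target rates in Hz; `from` must be divisible by
#'   `to`.
#' @export
downsample_features <- function(x, from = 2000, to = 40) {
  if (from %% to != 0) stop("`from` must be divisible by `to`")
  step <- from / to
  if (is.matrix(x)) {
    x[seq(1, nrow(x), by = step), , drop = FALSE]
  } else {
    x[seq(1, length(x), by = step)]
  }
}

#' Greedy correlation pruning of features
#'
#' Scans features in canonical order; a feature is dropped when its absolute
#' Pearson correlation with any earlier retained feature exceeds the
#' threshold (the earlier feature of the pair is kept). Constant columns are
#' dropped as well: their correlation is undefined and they cannot be
#' min-max normalized.
#'
#' @param X feature matrix (training partition).
#' @param threshold correlation magnitude above which the later feature of a
#'   pair is eliminated.
#' @return Integer vector of retained column indices (named).
#' @export
correlation_prune <- function(X, threshold = 0.9) {
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (sd(v) == 0) next
    if (length(keep)) {
      r <- abs(cor(X[, keep, drop = FALSE], v))
      if (any(r > threshold)) next
    }
    keep <- c(keep, j)
  }
  stats::setNames(keep, colnames(X)[keep])
}

#' Min-max normalization fitted on training data
#'
#' `feat' = (ymax - ymin) (feat - featmin) / (featmax - featmin) + ymin` with
#' `ymin = -1`, `ymax = +1`. Values outside the training range extrapolate
#' linearly (they are not clipped); in the quantized representation
#' (1024 = 1.0) extrapolated values saturate at the signed 16-bit range.
#'
#' @param X training feature matrix.
#' @return `minmax_fit()` returns a `minmax_spec` (per-feature `featmin`,
#'   `featmax`); `minmax_apply()` the normalized matrix, either real-valued
#'   in `[-1, 1]` or integer on the 1024 scale when `quantized = TRUE`.
#' @export
minmax_fit <- function(X) {
  featmin <- apply(X, 2, min)
  featmax <- apply(X, 2, max)
  if (any(featmax <= featmin))
    stop("constant feature column: featmax must exceed featmin ",
         "(prune constant features first)")
  structure(list(featmin = featmin, featmax = featmax, ymin = -1, ymax = 1),
            class = "minmax_spec")
}

#' @rdname minmax_fit
#' @param spec a `minmax_spec`.
#' @param quantized emit integers on the 1024 fixed-point scale.
#' @export
minmax_apply <- function(spec, X, quantized = FALSE) {
  vec <- !is.matrix(X)
  if (vec) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(spec$featmin)))
  Y <- sweep(X, 2, spec$featmin)
  Y <- sweep(Y, 2, spec$featmax - spec$featmin, "/") *
    (spec$ymax - spec$ymin) + spec$ymin
  if (quantized) Y <- pmin(pmax(round(Y * 1024), -32767), 32767)
  if (vec) Y[1, ] else Y
}

#' Contiguous stratified train/validation/test split
#'
#' Windows are partitioned at window granularity: within every
#' class-by-subtype group (taken in timeline order) the group is rotated by a
#' seeded offset and divided into contiguous runs of 70% / 15% / 15%, so each
#' partition is a union of contiguous time sequences, no partition boundary
#' splits a window, and every subtype is represented in each partition
#' according to its share of the corpus.
#'
#' @param windows an `emg_windows` list.
#' @param fractions named fractions for `train`, `val`, `test` (sum to 1).
#' @param seed seed for the rotation offsets.
#' @return List with integer window indices `train`, `val`, `test`.
#' @export
stratified_contiguous_split <- function(windows,
                                        fractions = c(train = 0.7, val = 0.15, test = 0.15),
                                        seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  cls <- vapply(windows, `[[`, integer(1), "cls")
  subtype <- vapply(windows, `[[`, character(1), "subtype")
  groups <- split(seq_along(windows), paste(cls, subtype))
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (idx in groups) {
      m <- length(idx)
      n_val <- round(fractions[["val"]] * m)
      n_test <- round(fractions[["test"]] * m)
      n_train <- m - n_val - n_test
      off <- sample.int(m, 1) - 1L
      rot <- idx[((seq_len(m) - 1 + off) %% m) + 1]
      out$train <- c(out$train, rot[seq_len(n_train)])
      out$val <- c(out$val, rot[n_train + seq_len(n_val)])
      out$test <- c(out$test, rot[n_train + n_val + seq_len(n_test)])
    }
  })
  lapply(out, sort)
}

#' Contiguous stratified cross-validation folds
#'
#' Assigns the pooled train+validation windows to `k` folds; within every
#' class-by-subtype group the windows are cut into `k` contiguous chunks.
#'
#' @param windows an `emg_windows` list.
#' @param pool integer window indices to fold (typically train + val).
#' @param k number of folds.
#' @return Integer fold id (1..k) per element of `pool`.
#' @export
cv_folds <- function(windows, pool, k = 5L) {
  cls <- vapply(windows[pool], `[[`, integer(1), "cls")
  subtype <- vapply(windows[pool], `[[`, character(1), "subtype")
  fold <- integer(length(pool))
  for (idx in split(seq_along(pool), paste(cls, subtype))) {
    m <- length(idx)
    fold[idx] <- pmin(k, ceiling(seq_len(m) / m * k))
  }
  fold
}

#' Assemble a model-ready dataset from a corpus
#'
#' Runs the full chain: segment pre-processing, alternating window assembly,
#' small-signal removal, continuous feature calculation at 2 kHz, decimation
#' to the model rate, and the contiguous stratified split.
#'
#' @param corpus an `emg_corpus` from [gen_corpus()].
#' @param rate feature/decision rate in Hz: 40 (logistic regression, tree,
#'   feed-forward net) or 250 (recurrent net).
#' @param vary vary window durations (recommended for the recurrent net).
#' @param window_s fixed window duration in seconds when `vary = FALSE`.
#' @param split_seed,assemble_seed seeds of the split rotation and the window
#'   duration draws.
#' @param features variant names to compute.
#' @param arithmetic see [run_feature()].
#' @return A list of class `emg_dataset`: feature matrix `X` at `rate`,
#'   targets `y`, per-sample `window` ids, the `windows` metadata, the
#'   `split` (window indices) and per-partition sample indices `samples`.
#' @export
make_dataset <- function(corpus, rate = 40, vary = FALSE, window_s = 1,
                         split_seed = 1L, assemble_seed = 1L,
                         features = feature_names(),
                         arithmetic = c("fixed", "float")) {
  config <- attr(corpus, "config")
  segs <- preprocess_corpus(corpus)
  win <- assemble_alternating(segs, window_s = window_s, vary = vary,
                              seed = assemble_seed)
  if (!is.null(config)) {
    win <- remove_small_signal(win, small_signal_threshold(config))
  }
  tl <- .timeline(win)
  F2k <- compute_features(tl$x, features = features,
                          arithmetic = match.arg(arithmetic))
  keep <- seq(1, nrow(F2k), by = 2000 / rate)
  X <- F2k[keep, , drop = FALSE]
  y <- tl$target[keep]
  window <- tl$window[keep]
  split <- stratified_contiguous_split(win, seed = split_seed)
  samples <- lapply(split, function(widx) which(window %in% widx))
  structure(list(X = X, y = y, window = window, windows = win,
                 split = split, samples = samples, rate = rate,
                 envelope = rectify_smooth(tl$x, fs = 2000),
                 config = config),
            class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("<emg_dataset> %d samples @ %g Hz, %d features, %d windows (train/val/test = %d/%d/%d)\n",
              nrow(x$X), x$rate, ncol(x$X), length(x$windows),
              length(x$split$train), length(x$split$val), length(x$split$test)))
  invisible(x)
}

# per-window sequences (for the recurrent net): list of lists with X, y
dataset_sequences <- function(ds, part) {
  widx <- ds$split[[part]]
  lapply(widx, function(w) {
    i <- which(ds$window == w)
    list(X = ds$X[i, , drop = FALSE], y = ds$y[i][1], idx = i)
  })
}
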