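# Cross-validated model selection over the hyper-parameter grids, and
# end-to-end test evaluation of a fitted (quantized) model with debounce and
# the transition-tolerant score.

#' Cross-validated training of one classifier family
#'
#' Prunes correlated features on the training partition, selects
#' `n_features` of the survivors, and trains the requested family with a
#' 5-fold cross-validation over its hyper-parameter grid (ridge penalty for
#' the logistic regression, split cap for the tree, hidden width for the
#' networks). Folds are contiguous window groups stratified by subtype;
#' per-fold scoring uses debounced decisions and the 100 ms transition
#' tolerance.
#'
#' Feature selection follows the family: the lasso path for the logistic
#' regression, and sequential backward elimination otherwise -- scored by
#' fold-CV tree accuracy for the tree, and by a fast linear proxy trainer
#' for the networks (backward elimination with the full network trainer in
#' the loop is supported through [sbs_select()] but is orders of magnitude
#' slower). The winning configuration is refit on the training partition;
#' the networks use the validation partition for early stopping and keep the
#' best of `restarts` random initializations by validation loss.
#'
#' @param ds an `emg_dataset` from [make_dataset()] (rate 40 for logreg /
#'   tree / nn, 250 for rnn).
#' @param family one of `"logreg"`, `"tree"`, `"nn"`, `"rnn"`.
#' @param n_features number of features to select (3, 6, 9 or 12 in the
#'   reference grid).
#' @param hidden_units hidden width grid for the networks (3, 6, 9).
#' @param max_splits_grid split-cap grid for the tree.
#' @param features explicit feature subset, bypassing selection.
#' @param tol_ms transition tolerance for fold scoring, in ms.
#' @param n_slope debounce length during fold scoring (2, or 3 for the rnn).
#' @param max_epochs optional epoch-cap override for the networks.
#' @param restarts random initializations for the final network fit.
#' @param seed seed for network initialization.
#' @param k number of folds.
#' @return List with the fitted `model` (an `emg_model`), the selected
#'   `features`, and a `cv` data frame (one row per grid value with its mean
#'   fold accuracy).
#' @export
cv_train <- function(ds, family = c("logreg", "tree", "nn", "rnn"),
                     n_features = 9L, hidden_units = c(3L, 6L, 9L),
                     max_splits_grid = c(1L, 2L, 3L, 4L, 8L, 16L),
                     features = NULL, tol_ms = 100, n_slope = NULL,
                     max_epochs = NULL, restarts = 3L, seed = 1L, k = 5L) {
  family <- match.arg(family)
  if (is.null(n_slope)) n_slope <- if (family == "rnn") 3L else 2L
  if (is.null(max_epochs)) max_epochs <- if (family == "rnn") 100L else 1000L
  rate <- ds$rate

  tr <- ds$samples$train
  retained <- names(correlation_prune(ds$X[tr, , drop = FALSE]))

  # fold membership at the sample level (train+val window pool)
  pool_w <- sort(c(ds$split$train, ds$split$val))
  fold_w <- cv_folds(ds$windows, pool_w, k = k)
  pool_s <- which(ds$window %in% pool_w)
  fold_s <- fold_w[match(ds$window[pool_s], pool_w)]
  yp <- ds$y[pool_s]
  wp <- ds$window[pool_s]

  score <- function(pred, truth) {
    tolerant_accuracy(debounce(pred, n_slope), truth, tol_ms, rate)$accuracy
  }

  # mean fold-CV accuracy of a tree on a feature subset
  tree_cv <- function(feats, max_splits) {
    mean(vapply(seq_len(k), function(f) {
      inb <- fold_s != f
      fit <- train_tree(ds$X[pool_s[inb], feats, drop = FALSE], yp[inb],
                        max_splits = max_splits)
      m <- build_model("tree", feats, fit, NULL, rate)
      score(predict_model(m, ds$X[pool_s[!inb], , drop = FALSE])$decision,
            yp[!inb])
    }, numeric(1)))
  }

  if (is.null(features)) {
    features <- if (family == "logreg") {
      nrm0 <- minmax_fit(ds$X[tr, retained, drop = FALSE])
      lasso_select(minmax_apply(nrm0, ds$X[tr, retained, drop = FALSE]),
                   ds$y[tr], n_keep = n_features)
    } else if (family == "tree") {
      sel <- retained
      while (length(sel) > n_features) {
        sc <- vapply(sel, function(f)
          tree_cv(setdiff(sel, f), max(max_splits_grid)), numeric(1))
        sel <- setdiff(sel, sel[which.max(sc)])
      }
      sel
    } else {
      nrm0 <- minmax_fit(ds$X[tr, retained, drop = FALSE])
      # single-penalty ridge fit as the fast linear proxy inside the
      # elimination loop
      sbs_select(minmax_apply(nrm0, ds$X[tr, retained, drop = FALSE]),
                 ds$y[tr], trainer = function(Xt, yt) {
                   fit <- suppressWarnings(
                     glmnet::glmnet(Xt, yt, family = "binomial", alpha = 0,
                                    lambda = 0.01))
                   w <- as.numeric(fit$beta)
                   b <- as.numeric(fit$a0)
                   function(Z) as.integer(drop(Z %*% w) + b > 0)
                 }, n_keep = n_features)
    }
  }
  stopifnot(all(features %in% colnames(ds$X)))
  norm_sel <- minmax_fit(ds$X[tr, features, drop = FALSE])

  net_fold <- function(hyper, f) {
    inb <- fold_s != f
    Xr <- ds$X[pool_s, features, drop = FALSE]
    nrm <- minmax_fit(Xr[inb, , drop = FALSE])
    if (family == "nn") {
      fit <- train_nn(minmax_apply(nrm, Xr[inb, , drop = FALSE]), yp[inb],
                      hidden_units = hyper,
                      Xval = minmax_apply(nrm, Xr[!inb, , drop = FALSE]),
                      yval = yp[!inb], max_epochs = max_epochs, seed = seed)
      m <- build_model("nn", features, fit, nrm, rate)
    } else {
      mk <- function(sel) lapply(unique(wp[sel]), function(wi) {
        i <- which(wp == wi)
        list(X = minmax_apply(nrm, Xr[i, , drop = FALSE]), y = yp[i][1])
      })
      fit <- train_rnn(mk(inb), mk(!inb), hidden_units = hyper,
                       max_epochs = max_epochs, seed = seed)
      m <- build_model("rnn", features, fit, nrm, rate)
    }
    score(predict_model(m, ds$X[pool_s[!inb], , drop = FALSE])$decision,
          yp[!inb])
  }

  if (family == "logreg") {
    Xn_all <- minmax_apply(norm_sel, ds$X[pool_s, features, drop = FALSE])
    fit <- train_logreg(Xn_all, yp, fold = fold_s, rate = rate,
                        tol_ms = tol_ms, n_slope = n_slope)
    model <- build_model("logreg", features, fit, norm_sel, rate)
    cv <- data.frame(hyper = "lambda", accuracy = NA_real_)
  } else {
    grid <- if (family == "tree") max_splits_grid else hidden_units
    cv <- data.frame(hyper = grid, accuracy = NA_real_)
    for (gi in seq_along(grid)) {
      cv$accuracy[gi] <- if (family == "tree") {
        tree_cv(features, grid[gi])
      } else {
        mean(vapply(seq_len(k), function(f) net_fold(grid[gi], f), numeric(1)))
      }
    }
    best <- grid[which.max(cv$accuracy)]
    model <- fit_final(ds, family, features, best, norm_sel, max_epochs,
                       seed, restarts)
  }
  list(model = model, cv = cv, features = features)
}

# refit the winning configuration on the training partition; networks use
# the validation partition for early stopping and keep the best of
# `restarts` initializations by validation loss
fit_final <- function(ds, family, features, hyper, norm, max_epochs, seed,
                      restarts = 3L) {
  tr <- ds$samples$train
  va <- ds$samples$val
  rate <- ds$rate
  Xtr_raw <- ds$X[tr, features, drop = FALSE]
  Xva_raw <- ds$X[va, features, drop = FALSE]
  pick_best <- function(fits) fits[[which.min(vapply(fits, `[[`, numeric(1), "val_loss"))]]
  switch(family,
    tree = {
      pool <- c(tr, va)  # the tree has no early stopping; use all non-test data
      fit <- train_tree(ds$X[pool, features, drop = FALSE], ds$y[pool],
                        max_splits = hyper)
      build_model("tree", features, fit, NULL, rate)
    },
    nn = {
      fits <- lapply(seq_len(restarts), function(r)
        train_nn(minmax_apply(norm, Xtr_raw), ds$y[tr], hidden_units = hyper,
                 Xval = minmax_apply(norm, Xva_raw), yval = ds$y[va],
                 max_epochs = max_epochs, seed = seed + r - 1L))
      build_model("nn", features, pick_best(fits), norm, rate)
    },
    rnn = {
      mk <- function(part) {
        lapply(dataset_sequences(ds, part), function(s)
          list(X = minmax_apply(norm, s$X[, features, drop = FALSE]), y = s$y))
      }
      str <- mk("train"); sva <- mk("val")
      fits <- lapply(seq_len(restarts), function(r)
        train_rnn(str, sva, hidden_units = hyper, max_epochs = max_epochs,
                  seed = seed + r - 1L))
      build_model("rnn", features, pick_best(fits), norm, rate)
    })
}

#' Evaluate a model on the test partition
#'
#' Runs the (typically quantized) model over the test samples in time order,
#' applies the decision debounce, and scores with the transition-tolerant
#' confusion matrix.
#'
#' @param model an `emg_model` (quantize with [quantize_model()] first for
#'   the embedded-equivalent figures).
#' @param ds the `emg_dataset` the model was trained on.
#' @param tol_ms transition tolerance in ms (150 for test scoring).
#' @param n_slope debounce length (defaults: 3 for the rnn, 2 otherwise).
#' @param part partition to score, default `"test"`.
#' @param by_subtype include a per-subtype accuracy breakdown.
#' @return An `eval_report` (see [tolerant_accuracy()]).
#' @export
evaluate_on_test <- function(model, ds, tol_ms = 150, n_slope = NULL,
                             part = "test", by_subtype = FALSE) {
  if (is.null(n_slope)) n_slope <- if (model$family == "rnn") 3L else 2L
  idx <- ds$samples[[part]]
  pred <- predict_model(model, ds$X[idx, , drop = FALSE])$decision
  dec <- debounce(pred, n_slope)
  st <- if (by_subtype) {
    vapply(ds$windows, `[[`, character(1), "subtype")[ds$window[idx]]
  } else NULL
  tolerant_accuracy(dec, ds$y[idx], tol_ms, ds$rate, subtype = st)
}
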