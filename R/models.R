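# Classifier families: L1-selected / ridge-trained logistic regression, a
# Gini CART with a max-splits cap, and the shallow satlins/purelin networks
# (feed-forward and delay-1 recurrent, in models-nn.R). All families share
# the emg_model container, the quantized 1024-scale forward pass, and the
# transition-tolerant cross-validated selection in cv_train().

.sigmoid <- function(z) 1 / (1 + exp(-z))

build_model <- function(family, features, params, normalization = NULL,
                        rate = 40) {
  structure(list(family = family, features = features, params = params,
                 normalization = normalization, rate = rate,
                 quantized = FALSE),
            class = "emg_model")
}

#' @export
print.emg_model <- function(x, ...) {
  cat(sprintf("<emg_model:%s%s> %d features (%s) @ %g Hz\n", x$family,
              if (isTRUE(x$quantized)) ", quantized" else "",
              length(x$features), paste(x$features, collapse = ", "), x$rate))
  invisible(x)
}

#' Lasso-path feature selection
#'
#' Fits an L1-penalized binomial model over a grid of `n_lambda` penalties
#' spanning the path from maximal sparsity to the densest coefficient vector,
#' and returns the non-zero support whose size is nearest to `n_keep`.
#'
#' @param X normalized feature matrix (training partition).
#' @param y binary targets (0 artifact / 1 contraction).
#' @param n_keep desired number of features.
#' @param n_lambda number of regularization penalties on the path.
#' @return Character vector of selected feature names.
#' @export
lasso_select <- function(X, y, n_keep, n_lambda = 30) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  n_keep <- min(n_keep, ncol(X))
  # deep path (small lambda.min.ratio) so the support can reach every size;
  # inputs are already min-max normalized, so no re-standardization
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = 1, nlambda = n_lambda,
                   lambda.min.ratio = 1e-4, standardize = FALSE,
                   maxit = 200000))
  supp_size <- colSums(as.matrix(fit$beta) != 0)
  pick <- which.min(abs(supp_size - n_keep))  # ties resolve to the sparser end
  support <- rownames(fit$beta)[as.matrix(fit$beta)[, pick] != 0]
  if (length(support) == 0) {
    first <- which(supp_size > 0)[1]
    support <- rownames(fit$beta)[as.matrix(fit$beta)[, first] != 0]
  }
  support
}

#' Sequential backward feature selection
#'
#' Starting from all columns, repeatedly removes the feature whose removal
#' maximizes held-out accuracy until `n_keep` remain.
#'
#' @inheritParams lasso_select
#' @param trainer function `(Xtr, ytr)` returning a prediction function
#'   `(Xnew) -> binary decisions`.
#' @param folds integer fold id per row (contiguous chunks by default).
#' @export
sbs_select <- function(X, y, trainer, n_keep, folds = NULL) {
  if (is.null(folds)) folds <- pmin(5L, ceiling(seq_len(nrow(X)) / nrow(X) * 5))
  score <- function(cols) {
    accs <- vapply(sort(unique(folds)), function(f) {
      fit <- trainer(X[folds != f, cols, drop = FALSE], y[folds != f])
      mean(fit(X[folds == f, cols, drop = FALSE]) == y[folds == f])
    }, numeric(1))
    mean(accs)
  }
  cols <- colnames(X)
  while (length(cols) > n_keep) {
    cand <- vapply(cols, function(cc) score(setdiff(cols, cc)), numeric(1))
    cols <- setdiff(cols, names(which.max(cand)))
  }
  cols
}

#' Ridge-penalized logistic regression
#'
#' L2-penalized logistic regression over a penalty path; when fold ids are
#' supplied the penalty is chosen by cross-validated transition-tolerant
#' accuracy, otherwise the least-penalized fit is used. The binary decision
#' is `sigmoid(w x + b) > 0.5`.
#'
#' @param X normalized feature matrix (rows in time order).
#' @param y binary targets.
#' @param fold optional integer fold id per row for penalty selection.
#' @param rate sample rate in Hz (for the tolerance mask).
#' @param tol_ms transition tolerance during selection.
#' @param n_slope debounce length applied before scoring folds.
#' @param n_lambda penalties on the path.
#' @return Parameter list with `weights`, `bias` and the chosen `lambda`.
#' @export
train_logreg <- function(X, y, fold = NULL, rate = 40, tol_ms = 100,
                         n_slope = 2L, n_lambda = 30) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  path <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         nlambda = n_lambda, lambda.min.ratio = 1e-6)
  lambdas <- path$lambda
  if (!is.null(fold)) {
    acc <- matrix(NA_real_, length(unique(fold)), length(lambdas))
    for (f in sort(unique(fold))) {
      fit <- glmnet::glmnet(X[fold != f, , drop = FALSE], y[fold != f],
                            family = "binomial", alpha = 0, lambda = lambdas)
      pr <- predict(fit, X[fold == f, , drop = FALSE], type = "response")
      for (j in seq_len(ncol(pr))) {
        dec <- debounce(as.integer(pr[, j] > 0.5), n_slope)
        acc[f, j] <- tolerant_accuracy(dec, y[fold == f], tol_ms, rate)$accuracy
      }
    }
    lam <- lambdas[which.max(colMeans(acc, na.rm = TRUE))]
  } else {
    lam <- min(lambdas)
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lam)
  list(weights = stats::setNames(as.numeric(fit$beta), rownames(fit$beta)),
       bias = as.numeric(fit$a0), lambda = lam)
}

# ---- decision tree (Gini CART via rpart, capped number of splits) ----------

.tree_nodes <- function(fit) {
  fr <- fit$frame
  ids <- as.integer(row.names(fr))
  leaf <- fr$var == "<leaf>"
  ylev <- attr(fit, "ylevels")
  nodes <- data.frame(id = ids,
                      feature = ifelse(leaf, NA_character_, as.character(fr$var)),
                      thresh = NA_real_, ncat = NA_real_,
                      class = as.integer(ylev[fr$yval]),
                      stringsAsFactors = FALSE)
  if (any(!leaf)) {
    counts <- ifelse(leaf, 0L, 1L + fr$ncompete + fr$nsurrogate)
    first <- cumsum(counts) - counts + 1L
    nodes$thresh[!leaf] <- fit$splits[first[!leaf], "index"]
    nodes$ncat[!leaf] <- fit$splits[first[!leaf], "ncat"]
  }
  nodes$qthresh <- ceiling(nodes$thresh)  # exact on integer features
  nodes
}

.tree_predict <- function(nodes, X, quantized = FALSE) {
  cur <- rep(1L, nrow(X))
  repeat {
    rows <- match(cur, nodes$id)
    open <- which(!is.na(nodes$feature[rows]))
    if (!length(open)) break
    r <- rows[open]
    xv <- X[cbind(open, match(nodes$feature[r], colnames(X)))]
    th <- if (quantized) nodes$qthresh[r] else nodes$thresh[r]
    goleft <- ifelse(nodes$ncat[r] < 0, xv < th, xv >= th)
    cur[open] <- nodes$id[r] * 2L + ifelse(goleft, 0L, 1L)
  }
  nodes$class[match(cur, nodes$id)]
}

#' Binary Gini decision tree with a split cap
#'
#' Greedy CART on the Gini diversity index (via `rpart`), pruned back to at
#' most `max_splits` internal nodes; the cap controls overfitting. The tree
#' operates on raw (un-normalized) feature values.
#'
#' @param X raw feature matrix.
#' @param y binary targets.
#' @param max_splits maximum number of internal nodes.
#' @param minsplit smallest node size rpart may split.
#' @return Parameter list with the node table (`nodes`) and `n_splits`.
#' @export
train_tree <- function(X, y, max_splits = 4L, minsplit = 20L) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  df <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0,
                        minsplit = minsplit,
                        maxdepth = min(max_splits, 30L)))
  cpt <- fit$cptable
  ok <- cpt[cpt[, "nsplit"] <= max_splits, , drop = FALSE]
  fit <- rpart::prune(fit, cp = ok[which.max(ok[, "nsplit"]), "CP"])
  nodes <- .tree_nodes(fit)
  list(nodes = nodes, n_splits = sum(!is.na(nodes$feature)))
}

# ---- shared prediction / quantization --------------------------------------

.q1024 <- function(x) round(x * 1024)

#' Quantize a trained model to the 1024 fixed-point scale
#'
#' All real parameters are multiplied by 1024 (= 1.0) and rounded to
#' integers; the quantized forward pass then runs in integer arithmetic with
#' the satlins clamp at +/-1024 and the decision threshold at 512. Tree
#' thresholds are instead quantized to integers on the raw feature scale,
#' which is exact for integer-valued features.
#'
#' @param model an `emg_model`.
#' @return The model with integer parameters attached and the quantized
#'   forward pass enabled (class `emg_model_q`).
#' @export
quantize_model <- function(model) {
  stopifnot(inherits(model, "emg_model"))
  pr <- model$params
  q <- if (model$family == "tree") {
    list(nodes = pr$nodes)  # qthresh column already present
  } else {
    lapply(pr[intersect(names(pr), c("weights", "bias", "W1", "b1", "W2", "b2", "Wr"))],
           .q1024)
  }
  model$q <- q
  model$quantized <- TRUE
  class(model) <- c("emg_model_q", "emg_model")
  model
}

# integer multiply-accumulate with the 1024 rescale (floor division, as the
# hardware's arithmetic shift would)
.qmac <- function(A, W) (A %*% W) %/% 1024

#' Model predictions on raw features
#'
#' Applies the model's stored normalization (not for trees), then the
#' family's forward pass -- in floating point, or in integer arithmetic when
#' the model has been [quantize_model()]-ed. For the recurrent net the rows
#' of `X` are treated as consecutive time steps.
#'
#' @param model an `emg_model`.
#' @param X raw feature matrix with named columns (superset of
#'   `model$features` allowed), rows in time order.
#' @param h0 initial hidden state (recurrent net), default zeros.
#' @return List with `decision` (integer 0/1 per row), `score` (the raw
#'   output, on the 1024 scale when quantized) and, for the recurrent net,
#'   the final hidden state `h`.
#' @export
predict_model <- function(model, X, h0 = NULL) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  Xs <- X[, model$features, drop = FALSE]
  quantized <- isTRUE(model$quantized)
  if (!is.null(model$normalization)) {
    Xs <- minmax_apply(model$normalization, Xs, quantized = quantized)
    if (!is.matrix(Xs)) Xs <- matrix(Xs, nrow = 1)
  } else if (quantized && model$family != "tree") {
    # un-normalized real-valued inputs enter the integer forward pass on the
    # 1024 scale (trees compare raw integer features directly)
    Xs <- pmin(pmax(round(Xs * 1024), -32767), 32767)
  }
  pr <- if (quantized) model$q else model$params
  switch(model$family,
    logreg = {
      s <- if (quantized) {
        drop(.qmac(Xs, matrix(pr$weights, ncol = 1))) + pr$bias
      } else {
        drop(Xs %*% pr$weights) + pr$bias
      }
      list(score = s, decision = as.integer(s > 0))
    },
    tree = {
      cls <- .tree_predict(pr$nodes, Xs, quantized = quantized)
      list(score = cls, decision = cls)
    },
    nn = {
      if (quantized) {
        Z <- sweep(.qmac(Xs, pr$W1), 2, pr$b1, "+")
        H1 <- fx_saturate(Z, -1024, 1024)
        s <- drop(.qmac(H1, pr$W2)) + pr$b2
        list(score = s, decision = as.integer(s > 512))
      } else {
        Z <- sweep(Xs %*% pr$W1, 2, pr$b1, "+")
        H1 <- satlins(Z)
        s <- drop(H1 %*% pr$W2) + pr$b2
        list(score = s, decision = as.integer(s > 0.5))
      }
    },
    rnn = {
      h <- if (is.null(h0)) numeric(nrow(pr$W2)) else h0
      n <- nrow(Xs)
      s <- numeric(n)
      if (quantized) {
        for (i in seq_len(n)) {
          z <- drop(.qmac(Xs[i, , drop = FALSE], pr$W1)) +
               drop(.qmac(matrix(h, nrow = 1), pr$Wr)) + pr$b1
          h <- fx_saturate(z, -1024, 1024)
          s[i] <- sum(h * pr$W2) %/% 1024 + pr$b2
        }
        list(score = s, decision = as.integer(s > 512), h = h)
      } else {
        for (i in seq_len(n)) {
          h <- satlins(drop(Xs[i, ] %*% pr$W1) + drop(h %*% pr$Wr) + pr$b1)
          s[i] <- sum(h * pr$W2) + pr$b2
        }
        list(score = s, decision = as.integer(s > 0.5), h = h)
      }
    },
    stop("unknown model family"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
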