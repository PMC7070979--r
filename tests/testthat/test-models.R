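# toy generators used across the model tests
toy_separable <- function(n = 400, seed = 13) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(f1 = runif(n) + 2 * y, f2 = rnorm(n))  # margin of 1 on f1
  list(X = X, y = y)
}

toy_xor <- function(n = 400, seed = 13) {
  set.seed(seed)
  a <- sample(0:1, n, TRUE)
  b <- sample(0:1, n, TRUE)
  X <- cbind(f1 = a * 2 - 1 + rnorm(n, sd = 0.25),
             f2 = b * 2 - 1 + rnorm(n, sd = 0.25))
  list(X = X, y = as.integer(xor(a, b)))
}

test_that("lasso selection keeps informative features across the path", {
  set.seed(5)
  n <- 2000
  inf <- rnorm(n)
  X <- cbind(inf = inf, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
             n4 = rnorm(n), n5 = rnorm(n))
  y <- as.integer(inf + rnorm(n, sd = 0.3) > 0)
  expect_identical(lasso_select(X, y, n_keep = 1), "inf")
  expect_length(lasso_select(X, y, n_keep = 6), 6)
  # a duplicated informative column enters the sparse support at most once
  X2 <- cbind(X[, "inf", drop = FALSE], dup = X[, "inf"], X[, -1])
  expect_lte(sum(lasso_select(X2, y, n_keep = 1) %in% c("inf", "dup")), 1)
  expect_error(lasso_select(X, rep(1, n), 2), "classes")
})

test_that("sequential backward selection removes the useless feature first", {
  set.seed(5)
  n <- 1200
  y <- rep(0:1, n / 2)
  X <- cbind(i1 = rnorm(n) + 2 * y, i2 = rnorm(n) - 1.5 * y,
             i3 = rnorm(n) + y, junk = rnorm(n))
  trainer <- function(Xt, yt) {
    fit <- train_logreg(Xt, yt)
    function(Z) as.integer(drop(Z %*% fit$weights) + fit$bias > 0)
  }
  expect_setequal(sbs_select(X, y, trainer, n_keep = 3), c("i1", "i2", "i3"))
  expect_identical(sbs_select(X, y, trainer, n_keep = 4), colnames(X))
})

test_that("ridge logistic regression separates separable data", {
  d <- toy_separable()
  fit <- train_logreg(d$X, d$y)
  m <- emgartifact:::build_model("logreg", colnames(d$X), fit, NULL, 40)
  expect_equal(mean(predict_model(m, d$X)$decision == d$y), 1)
  expect_error(train_logreg(d$X, rep(1, nrow(d$X))), "classes")
  # permuting the feature order permutes the weights with it
  fit2 <- train_logreg(d$X[, c("f2", "f1")], d$y)
  expect_equal(fit2$weights[c("f1", "f2")], fit$weights, tolerance = 1e-6)
})

test_that("the Gini tree respects its split cap and nails 1-D thresholds", {
  set.seed(2)
  x <- c(runif(60, 0, 4.9), runif(60, 5.1, 10))
  y <- as.integer(x > 5)
  fit <- train_tree(cbind(x = x), y, max_splits = 4, minsplit = 5)
  expect_equal(fit$n_splits, 1)
  th <- fit$nodes$thresh[!is.na(fit$nodes$feature)]
  expect_lt(abs(th - 5), 0.3)
  m <- emgartifact:::build_model("tree", "x", fit, NULL, 40)
  expect_equal(mean(predict_model(m, cbind(x = x))$decision == y), 1)
  # a noisy problem wants many splits; the cap must bind
  d <- toy_xor(800)
  fit2 <- train_tree(d$X, d$y, max_splits = 4)
  expect_lte(fit2$n_splits, 4)
})

test_that("satlins clamps and the network learns an XOR-style problem", {
  expect_equal(satlins(c(2, -3, 0.4)), c(1, -1, 0.4))
  expect_equal(dim(satlins(matrix(5, 2, 3))), c(2, 3))
  d <- toy_xor(600, seed = 1)
  v <- toy_xor(200, seed = 2)
  fit <- train_nn(d$X, d$y, hidden_units = 3, Xval = v$X, yval = v$y,
                  seed = 42)
  m <- emgartifact:::build_model("nn", colnames(d$X), fit, NULL, 40)
  expect_gte(mean(predict_model(m, d$X)$decision == d$y), 0.95)
})

test_that("a zero-weight network outputs its output bias everywhere", {
  pr <- list(W1 = matrix(0, 2, 3), b1 = numeric(3),
             W2 = matrix(0, 3, 1), b2 = 0.7)
  m <- emgartifact:::build_model("nn", c("f1", "f2"), pr, NULL, 40)
  out <- predict_model(m, cbind(f1 = rnorm(10), f2 = rnorm(10)))
  expect_true(all(out$score == 0.7))
  expect_true(all(out$decision == 1))
})

test_that("an rnn with zero recurrence reproduces the nn bit-exactly when quantized", {
  set.seed(3)
  pr <- list(W1 = matrix(rnorm(2 * 4), 2, 4), b1 = rnorm(4),
             W2 = matrix(rnorm(4), 4, 1), b2 = rnorm(1))
  prr <- c(pr, list(Wr = matrix(0, 4, 4)))
  X <- cbind(f1 = rnorm(50), f2 = rnorm(50))
  mq <- quantize_model(emgartifact:::build_model("nn", colnames(X), pr, NULL, 40))
  rq <- quantize_model(emgartifact:::build_model("rnn", colnames(X), prr, NULL, 250))
  expect_identical(predict_model(rq, X)$score, predict_model(mq, X)$score)
  expect_identical(predict_model(rq, X)$decision, predict_model(mq, X)$decision)
  # the default initial hidden state is zero
  expect_identical(predict_model(rq, X[1, , drop = FALSE], h0 = numeric(4))$score,
                   predict_model(rq, X[1, , drop = FALSE])$score)
})

test_that("the trained rnn uses its recurrence to carry context", {
  # class = value of a slow square wave observable only through noise; the
  # recurrent path can integrate over time where the static net cannot
  set.seed(7)
  mk <- function(n_seq, seed) {
    set.seed(seed)
    lapply(seq_len(n_seq), function(i) {
      y <- i %% 2
      Tn <- 40
      list(X = cbind(f1 = rnorm(Tn, mean = 0.3 * (2 * y - 1), sd = 1)), y = y)
    })
  }
  fit <- train_rnn(mk(40, 1), mk(10, 2), hidden_units = 4, seed = 5)
  m <- emgartifact:::build_model("rnn", "f1", fit, NULL, 250)
  te <- mk(20, 3)
  acc <- mean(unlist(lapply(te, function(s) {
    tail(predict_model(m, s$X)$decision, 20) == s$y
  })))
  expect_gt(acc, 0.8)
})

test_that("quantization scales by 1024 and stays within 1/2048 of the originals", {
  d <- toy_separable()
  fit <- train_logreg(d$X, d$y)
  m <- emgartifact:::build_model("logreg", colnames(d$X), fit, NULL, 40)
  mq <- quantize_model(m)
  expect_equal(emgartifact:::.q1024(0.5), 512)
  expect_true(all(abs(fit$weights - mq$q$weights / 1024) <= 1 / 2048))
  # decision flips between float and quantized forward are rare
  flips <- mean(predict_model(m, d$X)$decision != predict_model(mq, d$X)$decision)
  expect_lte(flips, 0.01)
})

test_that("tree quantization is exact on integer features", {
  ds <- small_ds40()
  tr <- ds$samples$train
  fit <- train_tree(ds$X[tr, c("ZCR1", "MAV2")], ds$y[tr], max_splits = 4)
  m <- emgartifact:::build_model("tree", c("ZCR1", "MAV2"), fit, NULL, 40)
  idx <- ds$samples$test
  expect_identical(predict_model(quantize_model(m), ds$X[idx, ])$decision,
                   predict_model(m, ds$X[idx, ])$decision)
})

test_that("cv_train returns a capped tree with its cross-validation report", {
  ds <- small_ds40()
  fit <- cv_train(ds, "tree", n_features = 3, max_splits_grid = c(2L, 4L))
  expect_s3_class(fit$model, "emg_model")
  expect_length(fit$features, 3)
  expect_lte(fit$model$params$n_splits, 4)
  expect_equal(nrow(fit$cv), 2)
  expect_true(all(is.finite(fit$cv$accuracy)))
})
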