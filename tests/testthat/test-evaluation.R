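# per-sample oracle for the exclusion mask: a sample is excluded iff some
# target transition happened at most K-1 steps before it
mask_oracle <- function(target, K) {
  tp <- which(diff(target) != 0) + 1L
  vapply(seq_along(target), function(i)
    any(tp <= i & tp > i - K), logical(1))
}

test_that("tolerant accuracy excludes the post-transition span only", {
  expect_equal(tolerant_accuracy(rep(1, 20), rep(1, 20), 100, 40)$accuracy, 100)
  expect_equal(tolerant_accuracy(rep(0, 20), rep(1, 20), 100, 40)$accuracy, 0)
  # target switches at step 10; 100 ms at 40 Hz masks 4 steps, so a decision
  # delayed by 2 steps is still perfect
  target <- c(rep(0, 9), rep(1, 21))
  pred <- c(rep(0, 11), rep(1, 19))
  rep_ <- tolerant_accuracy(pred, target, 100, 40)
  expect_equal(rep_$accuracy, 100)
  expect_equal(rep_$n_excluded, 4)
})

test_that("the exclusion mask matches the per-sample oracle", {
  set.seed(12)
  for (i in 1:25) {
    y <- debounce(sample(0:1, 120, TRUE), 1)  # realistic run structure
    K <- sample(1:8, 1)
    expect_identical(emgartifact:::transition_mask(y, K), mask_oracle(y, K))
  }
})

test_that("the report is consistent with its own confusion matrix", {
  set.seed(13)
  y <- rep(rep(0:1, 10), each = 12)
  p <- as.integer(runif(length(y)) < 0.8) * y +
    as.integer(runif(length(y)) < 0.1) * (1 - y)
  r <- tolerant_accuracy(p, y, 150, 40)
  expect_equal(r$accuracy, accuracy_from_confusion(r$tp, r$fn, r$fp, r$tn))
  expect_equal(r$tp + r$fn + r$fp + r$tn, r$n_counted)
  expect_equal(r$n_counted + r$n_excluded, length(y))
})

test_that("confusion-matrix accuracy is reported half-up to two decimals", {
  expect_equal(accuracy_from_confusion(7665, 3, 12, 8328), 99.91)
  expect_equal(accuracy_from_confusion(2215, 65, 80, 2414), 96.96)
  expect_equal(accuracy_from_confusion(10, 0, 0, 10), 100)
})

test_that("the EMA time-constant convention reproduces the published lags", {
  expect_equal(ema_time_constant(quantize_coeff(0.9922), 2000), 63.5)
  expect_equal(ema_time_constant(quantize_coeff(0.9961), 2000), 127.5)
  expect_equal(ema_time_constant(0, 2000), 0)
})

test_that("the model sweep fills the published grid layout", {
  ds <- small_ds40()
  ds250 <- make_dataset(small_corpus(), rate = 250, vary = TRUE, split_seed = 2)
  grid <- sweep_models(ds, ds250, n_features = c(3, 6),
                       hidden_units = c(3, 9),
                       max_epochs = c(nn = 25, rnn = 12), seed = 1)
  expect_equal(rownames(grid),
               c("NN (3 HU)", "NN (9 HU)", "RNN (3 HU)", "RNN (9 HU)",
                 "Decision Tree", "Log. Regression"))
  expect_equal(colnames(grid), c("3", "6"))
  expect_true(all(grid >= 0 & grid <= 100))
})
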