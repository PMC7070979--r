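test_that("debounce switches only after more than n_slope equal decisions", {
  expect_equal(debounce(c(1, 1, 1), 2), c(0, 0, 1))
  expect_equal(debounce(rep(1, 10), 2), c(0, 0, rep(1, 8)))
  expect_equal(debounce(rep(c(1, 1, 0), 10), 2), rep(0, 30))
  expect_equal(debounce(rep(0, 5), 3), rep(0, 5))
  # the alternative "exactly n_slope" reading is one decision earlier
  expect_equal(debounce(c(1, 1, 1), 2, rule = "geq"), c(0, 1, 1))
  expect_error(debounce(c(0, 1), 0))
})

test_that("debounce equals the run-length oracle on random streams", {
  set.seed(10)
  for (i in 1:50) {
    d <- sample(0:1, 200, TRUE)
    n <- sample(1:4, 1)
    expect_identical(debounce(d, n), debounce_rle(d, n))
  }
})

test_that("a clean transition is delayed by exactly n_slope + 1 periods", {
  for (n in 1:4) {
    d <- c(rep(0, 10), rep(1, 20))
    out <- debounce(d, n)
    expect_equal(which(out == 1)[1], 10 + n + 1)
  }
})

test_that("gate_output passes, cuts or holds the envelope", {
  env <- c(5, 6, 7)
  expect_equal(gate_output(c(1, 1, 1), env, "off"), env)
  expect_equal(gate_output(c(0, 0, 0), env, "off"), c(0, 0, 0))
  expect_equal(gate_output(c(1, 1, 0), env, "hold"), c(5, 6, 6))
  expect_equal(gate_output(c(0, 1, 0), env, "hold"), c(0, 6, 6))
  # invariant: the output is 0 or the envelope value (off policy)
  set.seed(11)
  d <- sample(0:1, 100, TRUE)
  e <- abs(rnorm(100))
  g <- gate_output(d, e, "off")
  expect_true(all(g == 0 | g == e))
})

test_that("align_streams zero-order-holds decisions and delays the envelope", {
  al <- align_streams(c(0, 1), 40, seq_len(100), 2000, delay_ms = 0)
  expect_equal(al$decisions, rep(c(0, 1), each = 50))
  expect_equal(al$envelope, seq_len(100))
  al2 <- align_streams(rep(1, 4), 250, seq_len(32), 250, delay_ms = 100)
  expect_equal(round(100 * 250 / 1000), 25)
  expect_true(all(al2$envelope[1:4] == 0))
  expect_error(align_streams(1, 40, 1:10, 300), "multiple")
})

test_that("decision_trace produces a gated online output", {
  ds <- small_ds40()
  tr <- ds$samples$train
  fit <- train_tree(ds$X[tr, c("ZCR1", "MAV2")], ds$y[tr], max_splits = 4)
  m <- quantize_model(
    emgartifact:::build_model("tree", c("ZCR1", "MAV2"), fit, NULL, 40))
  x2k <- mixed_segment()[1:4000]
  trc <- decision_trace(m, x2k, policy = "off")
  expect_named(trc, c("raw", "decision", "envelope", "output"))
  expect_equal(nrow(trc), 4000)
  expect_true(all(trc$output == 0 | trc$output == trc$envelope))
  # hold policy keeps the last contraction-phase value during artifacts
  trh <- decision_trace(m, x2k, policy = "hold")
  expect_true(all(trh$output[trh$decision == 1] ==
                    trh$envelope[trh$decision == 1]))
})
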