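# The compiled streaming engine is checked against a pure-R reference
# implementation of the same recursions (helper-data.R) and against
# closed-form/simulation oracles for the individual state machines.

test_that("compiled engine matches the R reference bit-exactly on mixed input", {
  set.seed(8)
  x <- round(c(rnorm(1500, sd = 300),                      # contraction-like
               2000 * sin(2 * pi * 20 * seq_len(1500) / 2000),  # artifact-like
               numeric(500)))
  for (f in feature_names()) {
    expect_identical(run_feature(x, f)$values, ref_feature(x, f)$values,
                     info = f)
  }
})

test_that("EMA update truncates and saturates as published", {
  b <- fx_coeff(255, 8)
  expect_equal(fx_scale(0 + 100, b), 99)
  # un-truncated closed form f*b/(1-b); truncation costs at most 2^k counts
  v <- run_feature(rep(10, 20000), "MAV1")$values
  expect_lt(abs(tail(v, 1) - 10 * 255), 256)
})

test_that("zero-crossing rate counts hysteresis-guarded crossings", {
  expect_equal(run_feature(c(300, -300), "ZCR2")$values, c(99, 198))
  # sub-hysteresis input never adds events: monotone decay
  st <- run_feature(c(300, -300, 300), "ZCR2")
  v <- run_feature(rep(c(200, -200), 500), "ZCR2", state = st$state)$values
  expect_true(all(diff(v) <= 0))
  # sustained alternation clamps the saturated variant at its upper bound
  v <- run_feature(rep(c(300, -300), 2000), "ZCR2S")$values
  expect_equal(max(v), 1000)
  expect_equal(tail(v, 1), 1000)
})

test_that("mean-crossing rate detects crossings through the smoothed signal", {
  # zero input: no events; the saturated variant stays pinned at its floor
  expect_true(all(run_feature(numeric(500), "MCR1S")$values == 2000))
  # settled constant input stops producing events
  v <- run_feature(rep(3000, 4000), "MCR1")$values
  expect_true(all(diff(tail(v, 2000)) <= 0))
  # 100 Hz sinusoid well above hysteresis: two events per period
  x <- round(5000 * sin(2 * pi * 100 * seq_len(2000) / 2000))
  expect_equal(ref_feature(x, "MCR1")$events, 200)
})

test_that("slope-sign change follows the printed branch cascade", {
  # strictly monotone input: a single sign-establishment event at start-up
  # (the cascade flips s from its initial 0), then no events and pure decay
  mono <- ref_feature(seq(0, 30000, by = 10), "SSC3")
  expect_lte(mono$events, 1)
  expect_true(all(diff(tail(mono$values, 2500)) <= 0))
  expect_lt(tail(mono$values, 1), 1)
  tri <- rep(c(seq(100, 1000, by = 100), seq(900, 100, by = -100)), 50)
  expect_equal(ref_feature(tri, "SSC3")$events, 77)
  # a tight dmax suppresses counting after long monotone runs
  pd <- feature_params("SSC3")
  pd$dmax <- 3
  expect_equal(ref_feature(tri, pd)$events, 28)
  expect_identical(run_feature(tri, pd)$values, ref_feature(tri, pd)$values)
})

test_that("waveform length scales the first difference", {
  # constant input contributes nothing beyond the initial step off the
  # zero-filled delay register
  v <- run_feature(rep(777, 3000), "WFL1")$values
  expect_true(all(diff(v[-1]) <= 0))
  expect_equal(tail(v, 1), 0)
  v <- run_feature(c(0, 256), "WFL1")$values
  expect_equal(v[2], 1)    # floor(floor(256/128) * 255/256)
  x <- round(cumsum(rnorm(4000, sd = 200)))
  x <- pmax(pmin(x, 30000), -30000)
  expect_true(all(run_feature(x, "WFL1S")$values <= 1300))
})

test_that("MAV2 tracks changes of the inner MAV1 and settles to zero", {
  expect_true(all(run_feature(numeric(400), "MAV2")$values == 0))
  v <- run_feature(rep(1000, 8000), "MAV2")$values
  expect_equal(tail(v, 1), 0)  # steady input: |delta MAV1| -> 0
  s <- run_feature(c(numeric(100), rep(500, 1900)), "MAV2")$values
  expect_gt(max(s), tail(s, 1))  # rises at the step, then decays
})

test_that("Willison amplitude thresholds at 44 (WAM1) and updates by 10 (WAM2)", {
  expect_true(all(run_feature(rep(30, 500), "WAM1")$values == 0))
  v <- run_feature(rep(100, 6000), "WAM1")$values
  expect_lt(abs(tail(v, 1) - 100 * 254 / 2), 128)  # closed form 12700
  # a WAM2 event adds 10, not 100: first event value is floor(10 * b)
  p <- feature_params("WAM2")
  x <- c(numeric(10), rep(10000, 100))
  r <- ref_feature(x, p)
  expect_gt(r$events, 0)
  first <- which(r$values > 0)[1]
  expect_equal(r$values[first], 9)
})

test_that("variance squares the input and VARS clamps at 4000", {
  expect_true(all(run_feature(numeric(200), "VAR")$values == 0))
  expect_equal(run_feature(100, "VAR")$values, 9960)
  v <- run_feature(rep(100, 2000), "VARS")$values
  expect_equal(max(v), 4000)
})

test_that("streamed chunks reproduce the batch run bit-exactly", {
  x <- mixed_segment()[1:6000]
  for (f in c("ZCR2S", "MCR1", "SSC5S", "WFL2S", "MAV2S", "WAM2", "VARS")) {
    batch <- run_feature(x, f)$values
    st <- NULL
    got <- numeric(0)
    for (chunk in split(x, ceiling(seq_along(x) / 777))) {
      r <- run_feature(chunk, f, state = st)
      got <- c(got, r$values)
      st <- r$state
    }
    expect_identical(got, batch, info = f)
  }
})

test_that("the feature bank is ordered, restrictable and deterministic", {
  x <- numeric(100)
  bank <- feature_bank(x)
  expect_identical(colnames(bank$values), feature_names())
  lbs <- feature_table()$lb
  expect_equal(unname(bank$values[100, ]), lbs)  # zero input pins at the floor
  sub <- feature_bank(mixed_segment()[1:500], features = c("SSC3", "ZCR2", "VARS"))
  expect_equal(ncol(sub$values), 3)
  again <- feature_bank(mixed_segment()[1:500], features = c("SSC3", "ZCR2", "VARS"))
  expect_identical(sub$values, again$values)
})

test_that("with zero input every feature decays monotonically", {
  x <- mixed_segment()[1:2000]
  for (f in feature_names()) {
    st <- run_feature(x, f)$state
    # let the internal smoothed-signal state drain first: its decay can emit
    # a few residual crossing events right after the signal stops
    st <- run_feature(numeric(1500), f, state = st)$state
    v <- run_feature(numeric(1000), f, state = st)$values
    expect_true(all(diff(v) <= 0), info = f)
  }
})
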