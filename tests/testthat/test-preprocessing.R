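test_that("downsample_average takes floored block means and drops remainders", {
  expect_equal(downsample_average(rep(10, 5)), 10)
  expect_equal(downsample_average(c(0, 5, 10, 15, 20)), 10)
  expect_length(downsample_average(1:12, 5), 2)
  s <- downsample_average(signal_stream(rep(7, 50), 10000))
  expect_s3_class(s, "signal_stream")
  expect_equal(s$fs, 2000)
})

test_that("comb filter nulls DC, 50 Hz and its harmonics", {
  expect_true(all(comb_filter(rep(123, 200), fs = 2000)[-(1:40)] == 0))
  t <- seq_len(4000) / 2000
  y <- comb_filter(sin(2 * pi * 50 * t), fs = 2000)
  expect_lt(max(abs(tail(y, 2000))), 1e-9)
  imp <- comb_filter(c(1, numeric(100)), fs = 2000)
  expect_equal(imp[1], 1)
  expect_equal(imp[41], -1)
  expect_true(all(imp[-c(1, 41)] == 0))
  expect_error(comb_filter(1:10, fs = 2000, f0 = 60), "divisible")
})

steady_gain <- function(y, x) {
  n <- length(x)
  tail_i <- (n %/% 2):n
  (max(y[tail_i]) - min(y[tail_i])) / (max(x[tail_i]) - min(x[tail_i]))
}

test_that("lowpass1 has unity DC gain and its -3 dB point at fc", {
  y <- lowpass1(rep(100, 2000), fs = 2000)
  expect_equal(tail(y, 1), 100, tolerance = 1e-6)
  t <- seq_len(20000) / 2000
  x <- sin(2 * pi * 531 * t)
  expect_equal(steady_gain(lowpass1(x, fs = 2000), x), 1 / sqrt(2),
               tolerance = 0.02)
  expect_true(all(lowpass1(numeric(100), fs = 2000) == 0))
})

test_that("highpass2 removes DC and has its -3 dB point at fc", {
  y <- highpass2(rep(500, 4000), fs = 2000)
  expect_lt(abs(tail(y, 1)), 1e-6)
  t <- seq_len(40000) / 2000
  x <- sin(2 * pi * 60 * t)
  expect_equal(steady_gain(highpass2(x, fs = 2000), x), 1 / sqrt(2),
               tolerance = 0.02)
  set.seed(4)
  w <- rnorm(20000)
  expect_lt(var(highpass2(w, fs = 2000)), var(w))
})

test_that("the simulated analog front end passes the EMG band only", {
  expect_lt(abs(tail(analog_frontend_sim(rep(1000, 20000)), 1)), 1)
  t <- seq_len(50000) / 10000
  g100 <- steady_gain(analog_frontend_sim(sin(2 * pi * 100 * t)),
                      sin(2 * pi * 100 * t))
  # a tone just below the 5 kHz Nyquist edge (exactly 5 kHz samples to zero)
  g5k <- steady_gain(analog_frontend_sim(sin(2 * pi * 4900 * t)),
                     sin(2 * pi * 4900 * t))
  expect_gt(20 * log10(g100), -1)                  # within 1 dB in band
  expect_gt(20 * log10(g100) - 20 * log10(g5k), 12)  # >= 12 dB down near 5 kHz
})

test_that("rectify_smooth is a positive EMA with the configured lag", {
  expect_true(all(rectify_smooth(numeric(100)) == 0))
  env <- rectify_smooth(rep(100, 4000), fs = 2000)
  b <- ema_coeff_for_tau(0.051, 2000)
  # converges to the closed-form equilibrium, short of it by the truncation
  eq <- 100 * b$value / (1 - b$value)
  expect_lt(eq - tail(env, 1), 2^b$k)
  expect_gte(eq, tail(env, 1))
  step_env <- rectify_smooth(c(numeric(10), rep(50, 500)), fs = 2000)
  expect_true(all(diff(step_env) >= 0))
})

test_that("delay_line shifts by round(delay_ms * fs / 1000) with a zero head", {
  x <- rnorm(300)
  expect_identical(delay_line(x, fs = 2000, delay_ms = 0), x)
  y <- delay_line(x, fs = 2000, delay_ms = 100)
  expect_true(all(y[1:200] == 0))
  expect_identical(y[201:300], x[1:100])
  expect_equal(sum(delay_line(x, fs = 250, delay_ms = 100) == 0), 25)
})

test_that("preprocess_segment emits integer counts at 2 kHz", {
  x <- preprocess_segment(rnorm(10000, sd = 300))
  expect_length(x, 2000)
  expect_true(all(x == round(x)))
})
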