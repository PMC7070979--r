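test_that("generation is fully determined by the seed", {
  cfg <- generator_config(seed = 9)
  sp <- segment_spec("contraction", "strong", 2, 77)
  expect_identical(gen_contraction(sp, cfg), gen_contraction(sp, cfg))
  sa <- segment_spec("artifact", "shock", 1, 78)
  expect_identical(gen_artifact(sa, cfg), gen_artifact(sa, cfg))
  cfg2 <- generator_config(budget_contraction_s = 10, budget_artifact_s = 10,
                           seed = 4)
  c1 <- gen_corpus(cfg2)
  c2 <- gen_corpus(cfg2)
  expect_identical(lapply(c1, `[[`, "samples"), lapply(c2, `[[`, "samples"))
})

test_that("strong contractions live in the 60-500 Hz band", {
  cfg <- generator_config(seed = 9)
  x <- gen_contraction(segment_spec("contraction", "strong", 3, 5), cfg)
  pw <- Mod(stats::fft(x - mean(x)))^2
  fr <- (seq_along(pw) - 1) / length(pw) * cfg$fs_raw
  inband <- sum(pw[fr >= 60 & fr <= 500]) / sum(pw[fr >= 1 & fr <= 5000])
  expect_gt(inband, 0.8)
})

test_that("lift-off artifacts sit far below the contraction band", {
  cfg <- generator_config(seed = 9)
  centroid <- function(v) {
    p <- Mod(stats::fft(v - mean(v)))^2
    f <- (seq_along(p) - 1) / length(p) * cfg$fs_raw
    i <- f >= 0.5 & f <= 5000
    sum(p[i] * f[i]) / sum(p[i])
  }
  a <- gen_artifact(segment_spec("artifact", "liftoff", 3, 6), cfg)
  x <- gen_contraction(segment_spec("contraction", "strong", 3, 5), cfg)
  expect_lt(centroid(a), centroid(x))
})

test_that("shock bursts decay below 5% of peak within three time constants", {
  cfg <- generator_config(seed = 9)
  for (sd_ in c(21, 22, 23)) {
    a <- gen_artifact(segment_spec("artifact", "shock", 1.5, sd_), cfg)
    tau <- attr(a, "decay_tau_s")
    peak_i <- which.max(abs(a))
    late <- abs(a[seq_along(a) / cfg$fs_raw >
                    peak_i / cfg$fs_raw + 3 * tau])
    expect_lt(max(late), 0.05 * max(abs(a)) + 8 * cfg$noise_rms)
  }
})

test_that("short contractions are capped at 0.4 s", {
  expect_error(segment_spec("contraction", "short", 0.5, 1), "0.4")
  expect_s3_class(segment_spec("contraction", "short", 0.3, 1), "segment_spec")
})

test_that("the corpus fills both class budgets with all subtypes", {
  cfg <- generator_config(budget_contraction_s = 10, budget_artifact_s = 10,
                          seed = 4)
  corpus <- gen_corpus(cfg)
  cls <- vapply(corpus, function(s) s$spec$cls, character(1))
  dur <- vapply(corpus, function(s) s$spec$duration_s, numeric(1))
  expect_gte(sum(dur[cls == "contraction"]), 10)
  expect_gte(sum(dur[cls == "artifact"]), 10)
  expect_setequal(unique(vapply(corpus, function(s) s$spec$subtype, character(1))),
                  c("strong", "weak", "short", "liftoff", "shock", "vibration"))
  # samples are integer ADC counts at the raw rate
  expect_true(all(corpus[[1]]$samples == round(corpus[[1]]$samples)))
})

test_that("at least one feature separates the classes by > 3 pooled SD", {
  ds <- small_ds40()
  # steady-state protocol: skip the 250 ms settling span after transitions,
  # mirroring the transition tolerance of the evaluation
  keep <- !emgartifact:::transition_mask(ds$y, 10L)
  X <- ds$X[keep, ]
  y <- ds$y[keep]
  sep <- vapply(colnames(X), function(f) {
    a <- X[y == 1, f]
    b <- X[y == 0, f]
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (sp == 0) 0 else abs(mean(a) - mean(b)) / sp
  }, numeric(1))
  expect_gt(max(sep), 3)
})
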