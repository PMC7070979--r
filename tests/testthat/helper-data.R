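# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 40 s per class: enough windows for split/pipeline/model checks
small_config <- function() {
  generator_config(budget_contraction_s = 40, budget_artifact_s = 40, seed = 1)
}

small_corpus <- function() fixture("small_corpus", gen_corpus(small_config()))

small_ds40 <- function() {
  fixture("small_ds40",
          make_dataset(small_corpus(), rate = 40, split_seed = 2))
}

# a 10 s mixed (contraction + artifact) processed 2 kHz segment
mixed_segment <- function() {
  fixture("mixed_segment", {
    cfg <- generator_config(seed = 5)
    xc <- preprocess_segment(
      gen_contraction(segment_spec("contraction", "strong", 5, 11), cfg))
    xa <- preprocess_segment(
      gen_artifact(segment_spec("artifact", "vibration", 5, 12), cfg))
    c(xc, xa)
  })
}

# Pure-R reference implementation of the feature recursions (independent of
# the compiled engine); also counts emitted events.
ref_feature <- function(x, params) {
  p <- if (is.character(params)) feature_params(params) else params
  fxs <- function(v, m, k) floor(v * m / 2^k)
  feat <- p$lb; smo <- 0; s <- 0; w <- 0; pcnt <- 0; aux <- 0
  buf <- numeric(max(1, p$delay)); pos <- 1
  out <- numeric(length(x)); events <- 0L
  for (i in seq_along(x)) {
    xi <- x[i]; f <- 0
    if (p$family == "zcr") {
      if (xi > p$hyst && s == 0) { f <- p$update; s <- 1 }
      else if (xi < -p$hyst && s == 1) { f <- p$update; s <- 0 }
    } else if (p$family == "mcr") {
      smo <- fxs(smo + xi, p$c_m, p$c_k)
      v <- fxs(smo, p$e_m, p$e_k)
      xd <- fxs(if (p$delay > 0) buf[pos] else xi, p$d_m, p$d_k)
      if (xd > v + p$hyst && s == 0) { f <- p$update; s <- 1 }
      else if (xd < v - p$hyst && s == 1) { f <- p$update; s <- 0 }
      if (p$delay > 0) { buf[pos] <- xi; pos <- pos %% p$delay + 1 }
    } else if (p$family == "ssc") {
      u <- smo
      smo <- fxs(smo + xi, p$c_m, p$c_k)
      v <- smo
      if (v > u && s == 0 && w >= p$dmin && pcnt < p$dmax) { f <- p$update; s <- 1; w <- 0; pcnt <- 0 }
      else if (v > u && s == 0 && w >= p$dmin) { s <- 1; w <- 0; pcnt <- 0 }
      else if (v > u && s == 0) { w <- w + 1 }
      else if (v > u) { s <- 1; w <- 0; pcnt <- pcnt + 1 }
      else if (v < u && s == 1 && w >= p$dmin && pcnt < p$dmax) { f <- p$update; s <- 0; w <- 0; pcnt <- 0 }
      else if (v < u && s == 1 && w >= p$dmin) { s <- 0; w <- 0; pcnt <- 0 }
      else if (v < u && s == 1) { w <- w + 1 }
      else { s <- 0; w <- 0; pcnt <- pcnt + 1 }
    } else if (p$family == "wfl") {
      f <- fxs(abs(xi - buf[1]), p$d_m, p$d_k)
      buf[1] <- xi
    } else if (p$family == "mav1") {
      f <- abs(xi)
    } else if (p$family == "mav2") {
      aux <- min(max(fxs(aux + abs(xi), p$b_m, p$b_k), 0), p$ub1)
      past <- if (p$delay > 0) buf[pos] else aux
      f <- abs(aux - past)
      if (p$delay > 0) { buf[pos] <- aux; pos <- pos %% p$delay + 1 }
    } else if (p$family == "wam1") {
      if (abs(xi) > p$thresh) f <- p$update
    } else if (p$family == "wam2") {
      smo <- fxs(smo + xi, p$c_m, p$c_k)
      xd <- fxs(if (p$delay > 0) buf[pos] else xi, p$d_m, p$d_k)
      if (abs(xd - smo) > p$thresh) f <- p$update
      if (p$delay > 0) { buf[pos] <- xi; pos <- pos %% p$delay + 1 }
    } else if (p$family == "var") {
      f <- xi^2
    }
    if (f == p$update && p$update > 0) events <- events + 1L
    oc <- if (p$family == "mav2") c(p$c_m, p$c_k) else c(p$b_m, p$b_k)
    feat <- min(max(fxs(feat + f, oc[1], oc[2]), p$lb), p$ub)
    out[i] <- feat
  }
  list(values = out, events = events)
}
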