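# independent run-length oracle for the debounce: scan the runs of the
# decision stream; a run of a new class longer than n_slope switches the
# output at its (n_slope + 1)-th element
debounce_rle <- function(d, n_slope) {
  out <- integer(length(d))
  o <- 0L
  pos <- 0L
  r <- rle(as.integer(d))
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    L <- r$lengths[i]
    seg <- rep(o, L)
    if (v != o && L > n_slope) {
      seg[(n_slope + 1):L] <- v
      o <- v
    }
    out[pos + seq_len(L)] <- seg
    pos <- pos + L
  }
  out
}
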