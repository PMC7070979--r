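# Canonical parameter table of the 26 feature variants. One row per variant,
# in the fixed order used everywhere in the package (ZCR, MCR, SSC, WFL, MAV,
# WAM, VAR families). Values: EMA coefficient b; smoothing coefficient c;
# input gain/shrink d; smoothed-signal gain e; input delay in samples;
# hysteresis and Willison threshold in ADC counts; saturation bounds lb/ub;
# slope-run limits dmin/dmax; per-event feature update; internal MAV1 bound
# ub1 (MAV2 only). NA marks "not used by this family".
.U16 <- 2^16 - 1

.feature_rows <- list(
  #     name     family   b      c      d      e    delay hyst  lb    ub    dmin dmax  thresh update ub1
  list("ZCR1",  "zcr",  0.9961, NA,    NA,    NA,   0,    0,    0,    .U16, NA,  NA,   NA,   100, NA),
  list("ZCR2",  "zcr",  0.9961, NA,    NA,    NA,   0,    242,  0,    .U16, NA,  NA,   NA,   100, NA),
  list("ZCR2S", "zcr",  0.9961, NA,    NA,    NA,   0,    242,  0,    1000, NA,  NA,   NA,   100, NA),
  list("MCR1",  "mcr",  0.9961, 0.8750, 6,    1,    8,    1044, 0,    .U16, NA,  NA,   NA,   100, NA),
  list("MCR1S", "mcr",  0.9961, 0.8750, 6,    1,    8,    1044, 2000, 3600, NA,  NA,   NA,   100, NA),
  list("MCR2",  "mcr",  0.9922, 0.9688, 1,    0.0313, 8,  0,    0,    .U16, NA,  NA,   NA,   100, NA),
  list("SSC1",  "ssc",  0.9961, 0.9922, NA,   NA,   0,    NA,   0,    .U16, 0,   .U16, NA,   100, NA),
  list("SSC1S", "ssc",  0.9961, 0.9922, NA,   NA,   0,    NA,   2000, 5000, 0,   .U16, NA,   100, NA),
  list("SSC2",  "ssc",  0.9961, 0.5,    NA,   NA,   0,    NA,   0,    .U16, 0,   .U16, NA,   100, NA),
  list("SSC2S", "ssc",  0.9961, 0.5,    NA,   NA,   0,    NA,   0,    14000, 0,  .U16, NA,   100, NA),
  list("SSC3",  "ssc",  0.9961, 0.9961, NA,   NA,   0,    NA,   0,    .U16, 5,   .U16, NA,   100, NA),
  list("SSC3S", "ssc",  0.9961, 0.9961, NA,   NA,   0,    NA,   900,  2000, 5,   .U16, NA,   100, NA),
  list("SSC4",  "ssc",  0.9961, 0.9961, NA,   NA,   0,    NA,   0,    .U16, 0,   1,    NA,   100, NA),
  list("SSC5",  "ssc",  0.9961, 0.75,   NA,   NA,   0,    NA,   0,    .U16, 3,   200,  NA,   100, NA),
  list("SSC5S", "ssc",  0.9961, 0.75,   NA,   NA,   0,    NA,   1500, 3000, 3,   200,  NA,   100, NA),
  list("WFL1",  "wfl",  0.9961, NA,    0.0078, NA,  0,    NA,   0,    .U16, NA,  NA,   NA,   100, NA),
  list("WFL1S", "wfl",  0.9961, NA,    0.0078, NA,  0,    NA,   0,    1300, NA,  NA,   NA,   100, NA),
  list("WFL2S", "wfl",  0.9922, NA,    0.0156, NA,  0,    NA,   0,    1894, NA,  NA,   NA,   100, NA),
  list("MAV1",  "mav1", 0.9961, NA,    NA,    NA,   0,    NA,   0,    .U16, NA,  NA,   NA,   NA,  NA),
  list("MAV1S", "mav1", 0.9961, NA,    NA,    NA,   0,    NA,   0,    600,  NA,  NA,   NA,   NA,  NA),
  list("MAV2",  "mav2", 0.9375, 0.9961, NA,   NA,   8,    NA,   0,    .U16, NA,  NA,   NA,   NA,  .U16),
  list("MAV2S", "mav2", 0.9375, 0.9961, NA,   NA,   8,    NA,   0,    6000, NA,  NA,   NA,   NA,  4000),
  list("WAM1",  "wam1", 0.9922, NA,    NA,    NA,   0,    NA,   0,    .U16, NA,  NA,   44,   100, NA),
  list("WAM2",  "wam2", 0.9961, 0.9922, 16,   NA,   64,   NA,   0,    .U16, NA,  NA,   3636, 10,  NA),
  list("VAR",   "var",  0.9961, NA,    NA,    NA,   0,    NA,   0,    .U16, NA,  NA,   NA,   NA,  NA),
  list("VARS",  "var",  0.9961, NA,    NA,    NA,   0,    NA,   0,    4000, NA,  NA,   NA,   NA,  NA)
)

.feature_df <- local({
  cols <- c("name", "family", "b", "c", "d", "e", "delay", "hyst", "lb", "ub",
            "dmin", "dmax", "thresh", "update", "ub1")
  df <- as.data.frame(do.call(rbind, lapply(.feature_rows, function(r) {
    names(r) <- cols
    r
  })), stringsAsFactors = FALSE)
  for (col in cols) df[[col]] <- unlist(df[[col]])
  df
})

#' Canonical feature variant names
#'
#' The 26 streaming time-domain feature variants in their canonical, stable
#' order (ZCR, MCR, SSC, WFL, MAV, WAM, VAR families).
#' @return Character vector of length 26.
#' @export
feature_names <- function() .feature_df$name

#' Feature parameter table
#'
#' @param quantized if `TRUE`, the coefficient columns are replaced by their
#'   dyadic fixed-point values (`m / 2^k`).
#' @return A data frame with one row per variant: EMA coefficient `b`,
#'   smoothing coefficient `c`, input gain `d`, smoothed-signal gain `e`,
#'   `delay` (samples), `hyst` and `thresh` (ADC counts), saturation bounds
#'   `lb`/`ub`, slope-run limits `dmin`/`dmax`, per-event `update`, and the
#'   internal bound `ub1` of the MAV2 recursion.
#' @export
feature_table <- function(quantized = FALSE) {
  df <- .feature_df
  if (quantized) {
    for (col in c("b", "c", "d", "e")) {
      df[[col]] <- vapply(df[[col]], function(v) {
        if (is.na(v)) NA_real_ else quantize_coeff(v)$value
      }, numeric(1))
    }
  }
  df
}

# flat parameter list consumed by the C++ engine; absent coefficients become
# identity-safe zeros, absent bounds their neutral values. The EMA
# coefficients b and c are designed in floating point and quantized for the
# hardware, so the reference path keeps their real-valued targets; the input
# scales d and e are defined as shift operations, so both paths use the
# exact dyadic value (the printed decimals are 4-digit displays of 1/128,
# 1/64, 1/32).
.coef_fields <- function(target, shift_defined = FALSE) {
  if (is.na(target)) {
    list(m = 0, k = 0L, t = 0)
  } else {
    q <- quantize_coeff(target)
    list(m = q$m, k = q$k, t = if (shift_defined) q$value else q$target)
  }
}

#' Full parameter set of one feature variant
#'
#' @param name one of [feature_names()].
#' @return A list with the variant's name, family and all engine parameters,
#'   including the quantized multiplier/shift pairs for `b`, `c`, `d`, `e`.
#' @export
feature_params <- function(name) {
  i <- match(name, .feature_df$name)
  if (is.na(i)) stop("unknown feature variant '", name, "'")
  r <- .feature_df[i, ]
  bq <- .coef_fields(r$b); cq <- .coef_fields(r$c)
  dq <- .coef_fields(r$d, shift_defined = TRUE)
  eq <- .coef_fields(r$e, shift_defined = TRUE)
  list(
    name = r$name, family = r$family,
    b_m = bq$m, b_k = bq$k, b_t = bq$t,
    c_m = cq$m, c_k = cq$k, c_t = cq$t,
    d_m = dq$m, d_k = dq$k, d_t = dq$t,
    e_m = eq$m, e_k = eq$k, e_t = eq$t,
    delay = as.integer(r$delay),
    hyst = ifelse(is.na(r$hyst), 0, r$hyst),
    lb = r$lb, ub = r$ub,
    dmin = ifelse(is.na(r$dmin), 0, r$dmin),
    dmax = ifelse(is.na(r$dmax), .U16, r$dmax),
    thresh = ifelse(is.na(r$thresh), 0, r$thresh),
    update = ifelse(is.na(r$update), 100, r$update),
    ub1 = ifelse(is.na(r$ub1), .U16, r$ub1)
  )
}

#' Write / read the feature parameter registry as JSON
#'
#' The registry mirrors the parameter table field-for-field and additionally
#' carries every coefficient as a `{target, m, k}` triple; reading it back
#' reproduces the engine parameter lists bit-exactly.
#'
#' @param path file path of the JSON registry.
#' @return `write_feature_registry()` returns `path` invisibly;
#'   `read_feature_registry()` returns a named list of parameter lists, one
#'   per variant, as produced by [feature_params()].
#' @export
write_feature_registry <- function(path) {
  reg <- lapply(feature_names(), feature_params)
  names(reg) <- feature_names()
  jsonlite::write_json(reg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_registry
#' @export
read_feature_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_params.json", package = "emgartifact")
  }
  reg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(reg, function(p) {
    p$delay <- as.integer(p$delay)
    for (f in c("b_k", "c_k", "d_k", "e_k")) p[[f]] <- as.integer(p[[f]])
    for (f in setdiff(names(p), c("name", "family", "delay", "b_k", "c_k", "d_k", "e_k")))
      p[[f]] <- as.numeric(p[[f]])
    p
  })
}
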