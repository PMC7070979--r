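# File interfaces: two-column delimited signal text, 16-bit PCM mono WAV
# (hand-written RIFF, no audio package is required), JSON model files, and
# delimited decision traces / feature matrices.

#' Read / write a signal as two-column delimited text
#'
#' Columns are `time_s` and `value`; the sampling rate is recovered from the
#' time column on read.
#'
#' @param x a [signal_stream()] (or numeric vector plus `fs`).
#' @param path file path.
#' @param fs sampling rate in Hz when `x` is a plain vector.
#' @return `read_signal_txt()` returns a [signal_stream()].
#' @export
write_signal_txt <- function(x, path, fs = NULL) {
  v <- .stream_samples(x)
  if (inherits(x, "signal_stream")) fs <- x$fs
  stopifnot(!is.null(fs))
  utils::write.table(data.frame(time_s = (seq_along(v) - 1) / fs, value = v),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_txt
#' @export
read_signal_txt <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  fs <- round(1 / stats::median(diff(df$time_s)))
  signal_stream(df$value, fs)
}

#' Read / write 16-bit PCM mono WAV
#'
#' Minimal canonical RIFF/WAVE layout; samples are clamped to the signed
#' 16-bit range.
#'
#' @inheritParams write_signal_txt
#' @export
write_wav <- function(x, path, fs = NULL) {
  v <- .stream_samples(x)
  if (inherits(x, "signal_stream")) fs <- x$fs
  stopifnot(!is.null(fs))
  v <- as.integer(pmin(pmax(round(v), -32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(v) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")      # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")     # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(v, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono is supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit samples are supported")
      readBin(con, "raw", sz - 16L)
    } else if (id == "data") {
      v <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
                   endian = "little")
      return(signal_stream(v, fs))
    } else {
      readBin(con, "raw", sz)
    }
  }
}

#' Write / read a trained model as JSON
#'
#' Schema-versioned serialization of an `emg_model`, including feature names,
#' the min-max normalization, float parameters, and -- for quantized models --
#' the integer parameters on the 1024 scale. Round-trips bit-exactly.
#'
#' @param model an `emg_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  payload <- list(schema_version = 1L,
                  family = model$family, features = model$features,
                  rate = model$rate, quantized = isTRUE(model$quantized),
                  normalization = if (!is.null(model$normalization))
                    unclass(model$normalization),
                  params = model$params, q = model$q)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_mats <- function(pr) {
    if (is.null(pr)) return(NULL)
    if (!is.null(pr$W1)) pr$W1 <- as.matrix(pr$W1)
    if (!is.null(pr$Wr)) pr$Wr <- as.matrix(pr$Wr)
    if (!is.null(pr$W2)) pr$W2 <- matrix(unlist(pr$W2), ncol = 1)
    if (!is.null(pr$nodes)) pr$nodes <- as.data.frame(pr$nodes)
    pr
  }
  norm <- NULL
  if (length(p$normalization)) {
    norm <- structure(list(
      featmin = unlist(p$normalization$featmin),
      featmax = unlist(p$normalization$featmax),
      ymin = p$normalization$ymin, ymax = p$normalization$ymax),
      class = "minmax_spec")
  }
  m <- build_model(p$family, p$features, fix_mats(p$params),
                   normalization = norm, rate = p$rate)
  if (isTRUE(p$quantized)) {
    m$q <- fix_mats(p$q)
    m$quantized <- TRUE
    class(m) <- c("emg_model_q", "emg_model")
  }
  m
}

#' Write a feature matrix as delimited text
#'
#' Tab-separated with a header row of canonical feature names.
#'
#' @param X feature matrix with named columns.
#' @param path file path.
#' @export
write_feature_matrix <- function(X, path) {
  utils::write.table(X, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' Write / read a split manifest as JSON
#'
#' Records which window ids belong to the train, validation and test
#' partitions of a dataset split.
#'
#' @param split list of integer window-id vectors (`train`, `val`, `test`),
#'   as produced by [stratified_contiguous_split()].
#' @param path file path.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(split, path, digits = NA)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.integer)
}
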