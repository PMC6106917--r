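#' Read a RIFF/WAVE file
#'
#' Minimal WAV reader for the encodings that occur in clinical voice
#' recordings: integer PCM (8/16/24/32 bit), IEEE float (32/64 bit), and the
#' WAVE_FORMAT_EXTENSIBLE wrapper around either. Integer samples are scaled
#' by the type's full scale so the result is nominally in [-1, 1].
#'
#' @param path path to a .wav file.
#' @return A list with elements \code{samples} (numeric matrix, one column
#'   per channel), \code{rate} (sampling rate in Hz), \code{bits} and
#'   \code{format} (\code{"pcm"} or \code{"float"}).
#' @seealso [load_recording()] for the higher-level entry point that
#'   collapses channels and returns a [voice_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read WAV file (no such file): ", path, call. = FALSE)
  }
  size <- file.info(path)$size
  if (is.na(size) || size < 44) {
    stop("cannot read WAV file (truncated or empty): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(len) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", len)
      fmt <- parse_fmt_chunk(body, path)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", len)
    } else {
      invisible(readBin(con, "raw", len))
    }
    if (len %% 2 == 1) invisible(readBin(con, "raw", 1)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path, call. = FALSE)
  if (is.null(data_raw) || length(data_raw) == 0) {
    stop("WAV file has no audio data: ", path, call. = FALSE)
  }

  x <- decode_wav_data(data_raw, fmt, path)
  n <- length(x) %/% fmt$channels
  mat <- matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels, byrow = TRUE)
  list(samples = mat, rate = fmt$rate, bits = fmt$bits, format = fmt$format)
}

parse_fmt_chunk <- function(body, path) {
  u16 <- function(off) {
    sum(as.integer(body[off + 1:2]) * c(1, 256))
  }
  u32 <- function(off) {
    sum(as.numeric(body[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  tag <- u16(0)
  channels <- u16(2)
  rate <- u32(4)
  bits <- u16(14)
  if (tag == 65534L) { # WAVE_FORMAT_EXTENSIBLE: real tag leads the GUID
    if (length(body) < 26) {
      stop("malformed extensible fmt chunk: ", path, call. = FALSE)
    }
    tag <- u16(24)
  }
  format <- switch(as.character(tag),
    "1" = "pcm",
    "3" = "float",
    stop("unsupported WAV encoding (format tag ", tag, "): ", path,
         call. = FALSE)
  )
  if (format == "pcm" && !bits %in% c(8, 16, 24, 32)) {
    stop("unsupported PCM bit depth (", bits, "): ", path, call. = FALSE)
  }
  if (format == "float" && !bits %in% c(32, 64)) {
    stop("unsupported float bit depth (", bits, "): ", path, call. = FALSE)
  }
  list(tag = tag, channels = channels, rate = rate, bits = bits,
       format = format)
}

decode_wav_data <- function(raw, fmt, path) {
  if (fmt$format == "float") {
    return(readBin(raw, "double", n = length(raw) %/% (fmt$bits / 8),
                   size = fmt$bits / 8, endian = "little"))
  }
  bytes <- fmt$bits / 8
  n <- length(raw) %/% bytes
  if (fmt$bits == 8) {
    # 8-bit WAV is unsigned, midpoint 128
    (as.integer(raw[seq_len(n)]) - 128) / 128
  } else if (fmt$bits == 24) {
    idx <- seq_len(n)
    b0 <- as.numeric(raw[(idx - 1) * 3 + 1])
    b1 <- as.numeric(raw[(idx - 1) * 3 + 2])
    b2 <- as.numeric(raw[(idx - 1) * 3 + 3])
    v <- b0 + 256 * b1 + 65536 * b2
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    v <- readBin(raw, "integer", n = n, size = bytes, signed = TRUE,
                 endian = "little")
    v / (2^(fmt$bits - 1))
  }
}

#' Write a mono or multichannel WAV file
#'
#' @param samples numeric vector (mono) or matrix with one column per
#'   channel, nominally in [-1, 1].
#' @param rate sampling rate in Hz.
#' @param path output path.
#' @param bits bit depth; 16 writes integer PCM, 32 writes IEEE float.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16) {
  if (!bits %in% c(16, 32)) {
    stop("write_wav supports 16-bit PCM or 32-bit float output", call. = FALSE)
  }
  if (is.matrix(samples)) {
    channels <- ncol(samples)
    x <- as.numeric(t(samples))
  } else {
    channels <- 1L
    x <- as.numeric(samples)
  }
  bytes <- bits / 8
  data_len <- length(x) * bytes
  fmt_tag <- if (bits == 16) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * channels * bytes), con, size = 4,
           endian = "little")
  writeBin(as.integer(channels * bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
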