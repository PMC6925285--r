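#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed integer PCM (8/16/24/32-bit)
#' and IEEE float (32-bit). Stereo input is down-mixed to mono by channel
#' averaging, with a warning.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric vector scaled to `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(fmt_raw[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(fmt_raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(fmt_raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (!fmt$audio_format %in% c(1L, 3L)) {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format,
         "); only PCM and IEEE float are supported")
  }
  bytes_per <- fmt$bits / 8
  n_total <- length(data_raw) %/% bytes_per
  x <- if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", n_total, size = 4, endian = "little")
  } else if (fmt$bits == 8) {
    (as.numeric(readBin(data_raw, "integer", n_total, size = 1,
                        signed = FALSE)) - 128) / 128
  } else if (fmt$bits %in% c(16, 32)) {
    readBin(data_raw, "integer", n_total, size = bytes_per,
            signed = TRUE, endian = "little") / (2^(fmt$bits - 1))
  } else if (fmt$bits == 24) {
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }
  if (fmt$n_channels > 1) {
    warning("down-mixing ", fmt$n_channels, "-channel WAV to mono")
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  list(samples = as.numeric(x), sample_rate = fmt$sample_rate)
}

#' Write a mono PCM16 WAV file
#'
#' @param samples numeric vector in `[-1, 1]` (clipped if outside).
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  x <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
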