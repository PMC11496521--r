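#' Audio clips
#'
#' The unit of audio the encoder consumes: a mono waveform with samples in
#' \[-1, 1\] and a sample rate of at least 8 kHz. Stereo input is averaged to
#' mono on ingest; material sampled below 8 kHz is refused rather than
#' upsampled, because the encoder's default analysis band extends to several
#' kHz.
#'
#' @param samples Numeric vector of samples in \[-1, 1\] (values outside are
#'   clipped), or a 2-column matrix (stereo, averaged to mono).
#' @param sample_rate Sampling rate in Hz, >= 8000.
#'
#' @return An object of class `audio_clip`: list with `samples`,
#'   `sample_rate`, and `duration` in seconds.
#' @export
audio_clip <- function(samples, sample_rate) {
  if (is.matrix(samples)) samples <- rowMeans(samples)
  sample_rate <- as.numeric(sample_rate)
  if (sample_rate < 8000) abort_invalid("sample rate below 8 kHz is not supported")
  samples <- pmin(1, pmax(-1, as.numeric(samples)))
  structure(
    list(samples = samples, sample_rate = sample_rate,
         duration = length(samples) / sample_rate),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.3f s @ %g Hz (%d samples)\n",
              x$duration, x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Read and write WAV files
#'
#' A minimal RIFF/WAVE codec: reads PCM 16-bit, PCM 24-bit and IEEE float
#' 32-bit files (mono or stereo; stereo is averaged to mono), and writes
#' PCM 16-bit mono. This covers the formats the sound fixtures and the
#' encoder exchange.
#'
#' @param path Path to a `.wav` file.
#' @param clip An [audio_clip()] to write.
#'
#' @return `read_wav()` returns an [audio_clip()]; `write_wav()` returns
#'   `path` invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort_invalid(sprintf("'%s' is not a RIFF file", path))
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort_invalid(sprintf("'%s' is not a WAVE file", path))
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)  # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort_invalid(sprintf("'%s': missing fmt or data chunk", path))
  n_bytes <- fmt$bits %/% 8
  n_samp <- length(data_raw) %/% n_bytes
  x <- if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", n_samp, size = 2, endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    # assemble signed 24-bit little-endian by hand
    b <- matrix(as.integer(data_raw[seq_len(n_samp * 3)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data_raw, "double", n_samp, size = 4, endian = "little")
  } else {
    abort_invalid(sprintf("unsupported WAV format (format tag %d, %d bits)",
                          fmt$audio_format, fmt$bits))
  }
  if (fmt$n_channels > 1) x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  audio_clip(x, fmt$sample_rate)
}

#' @rdname read_wav
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  pcm <- as.integer(round(pmin(1, pmax(-1, clip$samples)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
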