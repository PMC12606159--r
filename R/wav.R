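#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the uncompressed integer PCM recordings
#' produced by autonomous recorders (16- or 24-bit, single channel).
#' Samples are returned rescaled to the \[-1, 1) range.
#'
#' @param path Path to a WAV file.
#' @param channel For stereo files, which channel to keep (1 or 2). A stereo
#'   file without an explicit `channel` is an error, so that channel choice
#'   is always deliberate.
#' @return A list with `samples` (numeric vector in \[-1, 1)) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt or data chunk: ", path)
  if (fmt$audio_format != 1L) stop("only integer PCM WAV is supported")
  if (!fmt$bits %in% c(16L, 24L)) stop("only 16- or 24-bit PCM is supported")

  bytes_per <- fmt$bits / 8L
  n_frames <- length(data_raw) %/% (bytes_per * fmt$n_channels)
  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_frames * fmt$n_channels,
                 size = 2, signed = TRUE, endian = "little")
    x <- x / 32768
  } else {
    ints <- as.integer(data_raw)
    idx <- seq_len(n_frames * fmt$n_channels)
    b1 <- ints[(idx - 1L) * 3L + 1L]
    b2 <- ints[(idx - 1L) * 3L + 2L]
    b3 <- ints[(idx - 1L) * 3L + 3L]
    v <- b1 + 256 * b2 + 65536 * b3
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  }
  if (fmt$n_channels > 1L) {
    if (is.null(channel)) {
      stop("stereo WAV: specify channel = 1 or 2 explicitly")
    }
    x <- x[seq(channel, length(x), by = fmt$n_channels)]
  }
  list(samples = x, sample_rate = fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector; values are clipped to \[-1, 1).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  x <- pmax(pmin(samples, 1 - 1 / 32768), -1)
  ints <- as.integer(round(x * 32768))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
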