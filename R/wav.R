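#' Write a mono waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer for single-channel recordings. Samples are
#' written either as 16-bit PCM (values clipped to \[-1, 1\] and scaled to
#' the integer range) or as IEEE float32.
#'
#' @param x numeric vector of samples in \[-1, 1\] (PCM) or arbitrary
#'   amplitude (float).
#' @param path output file path.
#' @param sample_rate_hz sampling rate in Hz.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate_hz, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(is.numeric(x), length(x) > 0, sample_rate_hz > 0)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per_sample <- bits %/% 8L
  audio_fmt <- if (format == "pcm16") 1L else 3L
  data_size <- length(x) * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * bytes_per_sample), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Reads single-channel PCM16 or float32 WAV files written by
#' [write_wav()] or other standard tools.
#'
#' @param path file path.
#' @return list with `samples` (numeric, PCM scaled back to \[-1, 1\]) and
#'   `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file")
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_fmt = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little")
      )
      readBin(con, raw(), n = size - 8)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("only mono WAV files are supported")
      if (fmt$audio_fmt == 1L) {
        n <- size %/% 2L
        x <- readBin(con, integer(), n = n, size = 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt$audio_fmt == 3L) {
        n <- size %/% 4L
        x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else stop("unsupported WAV encoding: ", fmt$audio_fmt)
      return(list(samples = x, sample_rate_hz = fmt$rate))
    } else {
      readBin(con, raw(), n = size)
    }
  }
}
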