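# Minimal mono WAV I/O (16-bit PCM and 32-bit IEEE float), enough to exchange
# verbal-response clips with standard audio tools.

#' Write a mono WAV file
#'
#' @param samples numeric vector in `[-1, 1]` (clipped if outside).
#' @param fs_hz sampling rate.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs_hz, path, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  samples <- pmin(1, pmax(-1, as.numeric(samples)))
  n <- length(samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt <- if (bits == 16) 1L else 3L   # PCM / IEEE float
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(samples * 32767)), con, size = 2,
             endian = "little")
  } else {
    writeBin(samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, single channel.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric, 16-bit data scaled to `[-1, 1]`) and
#'   `fs_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      if (channels != 1) stop("only mono WAV supported", call. = FALSE)
      fmt <- list(format = audio_format, fs = fs, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", size / 2, size = 2, signed = TRUE,
                           endian = "little") / 32767
      } else if (fmt$format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", size / 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)",
             call. = FALSE)
      }
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  list(samples = samples, fs_hz = fmt$fs)
}
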