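#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 8-, 16- and 32-bit integer PCM and 32-bit
#' IEEE float, mono or stereo. Samples are returned as doubles scaled to
#' [-1, 1]; stereo files yield a two-column matrix.
#'
#' @param path path to a WAV file
#' @return list with `samples` (numeric vector or matrix) and `rate` (Hz)
#' @export
read_wav <- function(path) {
  if (!file.exists(path) || file.size(path) < 44)
    stop("not a readable WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV file: ", path)
  if (!fmt$format %in% c(1L, 3L))
    stop("unsupported WAV encoding (", fmt$format, "): ", path)
  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(dat, "integer", length(dat), 1,
                               signed = FALSE)) - 128) / 128,
    "16" = readBin(dat, "integer", length(dat) %/% 2, 2, signed = TRUE,
                   endian = "little") / 32768,
    "32" = if (fmt$format == 3L)
             readBin(dat, "double", length(dat) %/% 4, 4, endian = "little")
           else
             readBin(dat, "integer", length(dat) %/% 4, 4,
                     endian = "little") / 2147483648,
    stop("unsupported WAV bit depth (", fmt$bits, "): ", path))
  if (length(x) == 0) stop("empty WAV file: ", path)
  if (fmt$channels > 1) {
    n <- (length(x) %/% fmt$channels) * fmt$channels
    x <- matrix(x[seq_len(n)], ncol = fmt$channels, byrow = TRUE)
  }
  list(samples = x, rate = fmt$rate)
}

#' Write a 16-bit PCM WAV file
#'
#' @param samples numeric vector (mono) or matrix (one column per channel)
#'   of amplitudes in [-1, 1]
#' @param rate sampling rate in Hz
#' @param path output path
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, rate, path) {
  if (inherits(samples, "waveform")) { rate <- samples$rate; samples <- samples$samples }
  ch <- if (is.matrix(samples)) ncol(samples) else 1L
  x <- if (is.matrix(samples)) as.numeric(t(samples)) else as.numeric(samples)
  pcm <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # PCM
  writeBin(as.integer(ch), con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * ch * 2), con, 4, endian = "little")
  writeBin(as.integer(ch * 2), con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
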