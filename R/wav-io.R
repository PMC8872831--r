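# Minimal RIFF/WAVE PCM 16-bit I/O.
#
# Written in-package: reads and writes the exact subset of the format the
# measurement chain uses (PCM, 16-bit, mono or stereo), validating the RIFF
# structure and naming the offending path on any format error. Dithering is
# deliberately not applied on export (determinism over audio fidelity).

read_le_int <- function(con, size, signed = TRUE, n = 1L) {
  readBin(con, "integer", n = n, size = size, signed = signed,
          endian = "little")
}

#' Read a PCM WAV file
#'
#' Reads a 16-bit PCM mono or stereo WAV file. Samples are normalized to
#' \[-1, 1\] (division by 32768). A mono file yields an [audio_signal()]; a
#' stereo file yields a [nasality_recording()] with the left channel mapped
#' to nasal and the right to oral, the channel convention of
#' nasality-microphone captures.
#'
#' @param path Path to the WAV file.
#' @return An [audio_signal()] or [nasality_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  fail <- function(why) stop(sprintf("not a readable PCM WAV file (%s): %s",
                                     why, path))
  if (!identical(rawToChar(readBin(con, "raw", 4L)), "RIFF")) fail("no RIFF header")
  invisible(read_le_int(con, 4L))  # chunk size
  if (!identical(rawToChar(readBin(con, "raw", 4L)), "WAVE")) fail("no WAVE tag")

  fmt <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) fail("truncated before data chunk")
    chunk_id <- rawToChar(id_raw)
    chunk_len <- read_le_int(con, 4L)
    if (length(chunk_len) < 1L || chunk_len < 0) fail("truncated chunk header")
    if (chunk_id == "fmt ") {
      body <- readBin(con, "raw", chunk_len)
      if (length(body) < 16L) fail("short fmt chunk")
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(body[15:16]) * c(1, 256)))
    } else if (chunk_id == "data") {
      if (is.null(fmt)) fail("data chunk before fmt chunk")
      if (fmt$audio_format != 1L) fail(sprintf("non-PCM format tag %d", fmt$audio_format))
      if (fmt$bits != 16L) fail(sprintf("unsupported bit depth %d", fmt$bits))
      n_samp <- chunk_len %/% 2L
      raw_samples <- read_le_int(con, 2L, n = n_samp)
      if (length(raw_samples) < n_samp) fail("truncated data chunk")
      x <- raw_samples / 32768
      if (fmt$n_channels == 1L)
        return(audio_signal(x, fmt$sample_rate))
      if (fmt$n_channels == 2L) {
        left <- x[seq(1L, length(x), by = 2L)]
        right <- x[seq(2L, length(x), by = 2L)]
        return(nasality_recording(left, right, fmt$sample_rate))
      }
      fail(sprintf("unsupported channel count %d", fmt$n_channels))
    } else {
      skipped <- readBin(con, "raw", chunk_len + chunk_len %% 2L)
      if (length(skipped) < chunk_len) fail("truncated chunk")
    }
  }
}

#' Write a PCM WAV file
#'
#' Writes an [audio_signal()] (mono) or [nasality_recording()] (stereo,
#' nasal = left, oral = right) as 16-bit PCM. Values are clipped to
#' \[-1, 1 - 2^-15\] and quantized without dithering.
#'
#' @param x An [audio_signal()] or [nasality_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  if (inherits(x, "audio_signal")) {
    channels <- list(x$samples)
    fs <- x$sample_rate
  } else if (inherits(x, "nasality_recording")) {
    channels <- list(x$nasal$samples, x$oral$samples)
    fs <- x$sample_rate
  } else stop("'x' must be an audio_signal or nasality_recording")
  n_ch <- length(channels)
  quant <- lapply(channels, function(s)
    as.integer(round(pmin(pmax(s, -1), 1 - 2^-15) * 32768)))
  interleaved <- as.integer(do.call(rbind, quant))
  data_len <- length(interleaved) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  w_int <- function(v, size) writeBin(as.integer(v), con, size = size,
                                      endian = "little")
  writeChar("RIFF", con, eos = NULL); w_int(36L + data_len, 4L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_int(16L, 4L)
  w_int(1L, 2L); w_int(n_ch, 2L)                 # PCM, channels
  w_int(round(fs), 4L); w_int(round(fs) * n_ch * 2L, 4L)  # rates
  w_int(n_ch * 2L, 2L); w_int(16L, 2L)           # block align, bits
  writeChar("data", con, eos = NULL); w_int(data_len, 4L)
  w_int(interleaved, 2L)
  invisible(path)
}
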