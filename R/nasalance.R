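# Nasalance: 100 * nasal energy / (nasal + oral energy), framewise, from a
# two-channel nasality-microphone recording (nasal = left, oral = right).

#' Two-channel nasality recording
#'
#' Pairs the nasal and oral microphone channels of a nasality-microphone
#' capture. Both channels must share length and sample rate (8 kHz is the
#' conventional device rate).
#'
#' @param nasal,oral [audio_signal()] objects of equal length and rate, or
#'   plain numeric vectors (interpreted at `sample_rate`).
#' @param sample_rate Sample rate in Hz used when plain vectors are given.
#' @return An object of class `nasality_recording`.
#' @export
nasality_recording <- function(nasal, oral, sample_rate = 8000) {
  if (!inherits(nasal, "audio_signal")) nasal <- audio_signal(nasal, sample_rate)
  if (!inherits(oral, "audio_signal")) oral <- audio_signal(oral, sample_rate)
  if (length(nasal$samples) != length(oral$samples))
    stop("nasal and oral channels must have equal length")
  if (nasal$sample_rate != oral$sample_rate)
    stop("nasal and oral channels must share a sample rate")
  structure(list(nasal = nasal, oral = oral,
                 sample_rate = nasal$sample_rate),
            class = "nasality_recording")
}

#' @export
print.nasality_recording <- function(x, ...) {
  cat(sprintf("<nasality_recording: %d samples @ %g Hz (%.3f s)>\n",
              length(x$nasal$samples), x$sample_rate,
              length(x$nasal$samples) / x$sample_rate))
  invisible(x)
}

#' Band-pass filter a nasality recording
#'
#' Applies an identical zero-phase band-pass to both channels: a 2nd-order
#' Butterworth band-pass (a 4th-order transfer function) run forward and
#' backward with [signal::filtfilt()], so the channels stay time-aligned. The
#' default 350-650 Hz band (centre 500 Hz) is the conventional nasalance
#' analysis band.
#'
#' @param rec A [nasality_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < sample_rate / 2`.
#' @return The filtered [nasality_recording()].
#' @export
bandpass_filter <- function(rec, low = 350, high = 650) {
  stopifnot(inherits(rec, "nasality_recording"))
  fs <- rec$sample_rate
  if (!(0 < low && low < high && high < fs / 2))
    stop("invalid band: need 0 < low < high < sample_rate/2")
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  filt <- function(ch)
    audio_signal(signal::filtfilt(bf, ch$samples), fs)
  nasality_recording(filt(rec$nasal), filt(rec$oral))
}

#' Framewise nasalance trace
#'
#' Per frame, nasalance = 100 * E_nasal / (E_nasal + E_oral), where E is the
#' sum of squared samples in the frame. Frames whose combined energy falls
#' below `silence_floor` times the energy of a full-scale frame are marked
#' undefined (`NA`) and excluded from summaries.
#'
#' @param rec A [nasality_recording()].
#' @param frame_len Frame length in seconds, default 0.025.
#' @param hop Hop between frame starts in seconds, default 0.010.
#' @param silence_floor Relative combined-energy floor, default 1e-8.
#' @return An object of class `nasalance_trace`: list with `frame_times`
#'   (frame centres in s), `values` (percent, `NA` where undefined),
#'   `frame_len` and `hop` (samples), and `bandpass_applied = FALSE` (set by
#'   the caller when filtering was applied upstream).
#' @export
nasalance_trace <- function(rec, frame_len = 0.025, hop = 0.010,
                            silence_floor = 1e-8) {
  stopifnot(inherits(rec, "nasality_recording"))
  fs <- rec$sample_rate
  flen <- max(1L, round(frame_len * fs))
  fhop <- max(1L, round(hop * fs))
  n <- length(rec$nasal$samples)
  if (flen > n) stop("frame length exceeds recording length")
  starts <- seq.int(1L, n - flen + 1L, by = fhop)
  floor_abs <- silence_floor * flen  # full-scale frame energy = flen * 1^2
  vals <- vapply(starts, function(s) {
    idx <- s:(s + flen - 1L)
    en <- sum(rec$nasal$samples[idx]^2)
    eo <- sum(rec$oral$samples[idx]^2)
    if (en + eo < floor_abs) NA_real_ else 100 * en / (en + eo)
  }, numeric(1))
  if (all(is.na(vals)))
    warning("recording is silent everywhere; trace has no defined frames")
  structure(list(frame_times = (starts - 1L + flen / 2) / fs,
                 values = vals,
                 frame_len = flen, hop = fhop,
                 bandpass_applied = FALSE),
            class = "nasalance_trace")
}

#' Mean nasalance over a marked region
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator; 0 for a
#' single frame) of the defined frame values whose centres fall inside the
#' region.
#'
#' @param trace A [nasalance_trace()].
#' @param region Numeric `c(start, end)` in seconds; default spans the whole
#'   trace.
#' @return An object of class `nasalance_summary`: list with `mean`, `sd`
#'   (percent), `region` and `n_frames`.
#' @export
mean_nasalance <- function(trace, region = NULL) {
  stopifnot(inherits(trace, "nasalance_trace"))
  if (is.null(region)) region <- range(trace$frame_times)
  sel <- trace$frame_times >= region[1L] & trace$frame_times <= region[2L] &
    !is.na(trace$values)
  if (!any(sel))
    stop("region contains no defined nasalance frames")
  v <- trace$values[sel]
  structure(list(mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 region = as.numeric(region),
                 n_frames = length(v)),
            class = "nasalance_summary")
}

#' @export
print.nasalance_summary <- function(x, ...) {
  cat(sprintf("<nasalance: mean %.1f%%, sd %.1f%%, %d frames in [%.2f, %.2f] s>\n",
              x$mean, x$sd, x$n_frames, x$region[1L], x$region[2L]))
  invisible(x)
}
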