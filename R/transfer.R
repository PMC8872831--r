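# Transfer-function ratio estimation.
#
# The measured capture is split into non-overlapping rectangular windows of
# fft_len samples, the magnitude FFT of each window is averaged across
# windows, and the unit-less ratio is taken against the equally averaged
# excitation spectrum, evaluated at the harmonic grid bins only (off-grid
# bins carry no excitation energy and the ratio is undefined there).

#' Transfer-function container
#'
#' Holds the unit-less magnitude ratio on the harmonic-bin frequency axis,
#' together with the number of analysis windows averaged, an optional speech
#' condition label, and a flag recording whether voice-source harmonics have
#' been removed.
#'
#' @param frequencies Numeric vector of bin frequencies in Hz.
#' @param values Numeric vector of non-negative ratio values, same length.
#' @param n_windows Number of analysis windows averaged (>= 1).
#' @param condition Optional condition tag, `"normal"` or `"hypernasal"`.
#' @param harmonics_removed Logical flag, default `FALSE`.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(frequencies, values, n_windows,
                              condition = NULL, harmonics_removed = FALSE) {
  if (length(frequencies) != length(values))
    stop("'frequencies' and 'values' must have equal length")
  if (!all(is.finite(values)) || any(values < 0))
    stop("'values' must be finite and non-negative")
  if (n_windows < 1) stop("'n_windows' must be >= 1")
  if (!is.null(condition))
    condition <- match.arg(condition, c("normal", "hypernasal"))
  structure(list(frequencies = as.numeric(frequencies),
                 values = as.numeric(values),
                 n_windows = as.integer(n_windows),
                 condition = condition,
                 harmonics_removed = isTRUE(harmonics_removed)),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf(
    "<transfer_function: %d bins, %.1f-%.1f Hz, %d windows%s%s>\n",
    length(x$values), min(x$frequencies), max(x$frequencies), x$n_windows,
    if (is.null(x$condition)) "" else paste0(", ", x$condition),
    if (x$harmonics_removed) ", harmonics removed" else ""))
  invisible(x)
}

#' Split a signal into rectangular analysis windows
#'
#' Non-overlapping rectangular frames of `fft_len` samples. A final partial
#' frame is zero-padded to full length and counted, so the number of frames is
#' `ceiling(length / fft_len)`: a one-second capture at 44.1 kHz with a
#' 4096-point FFT yields 11 windows.
#'
#' @param signal An [audio_signal()].
#' @param fft_len Frame length in samples.
#' @return A numeric matrix with `fft_len` rows, one column per frame.
#' @export
segment_windows <- function(signal, fft_len) {
  stopifnot(inherits(signal, "audio_signal"))
  n <- length(signal$samples)
  if (n < fft_len)
    stop(sprintf("signal of %d samples is shorter than one %d-sample frame",
                 n, fft_len))
  n_frames <- ceiling(n / fft_len)
  padded <- c(signal$samples, numeric(n_frames * fft_len - n))
  matrix(padded, nrow = fft_len, ncol = n_frames)
}

#' Average magnitude spectrum across frames
#'
#' Takes the FFT of each rectangular frame and averages the magnitude (not
#' power) spectra bin-wise across frames.
#'
#' @param frames Matrix from [segment_windows()] (frames in columns).
#' @return Numeric vector of length `nrow(frames) / 2 + 1`: the averaged
#'   one-sided magnitude spectrum (bins 0 .. Nyquist).
#' @export
average_spectrum <- function(frames) {
  frames <- as.matrix(frames)
  if (ncol(frames) < 1L) stop("need at least one frame")
  nfft <- nrow(frames)
  mags <- abs(stats::mvfft(frames))[seq_len(nfft %/% 2 + 1L), , drop = FALSE]
  rowMeans(mags)
}

#' Compute the transfer-function ratio
#'
#' Estimates the unit-less ratio between the averaged magnitude spectrum of a
#' measured capture and that of the excitation reference, evaluated at the
#' harmonic grid bins. An excerpt of the measured capture can be selected with
#' `start` / `excerpt_len` (in seconds); excerpt selection is deliberately
#' manual, mirroring how steady portions of a sustained vowel are chosen.
#'
#' @param measured Measured capture, an [audio_signal()].
#' @param excitation_ref Excitation reference signal, an [audio_signal()] at
#'   the same sample rate.
#' @param grid The [build_harmonic_grid()] the excitation was built from.
#' @param start Excerpt start time in seconds (default 0 = beginning).
#' @param excerpt_len Excerpt length in seconds (default `NULL` = to the end).
#' @param condition Optional condition label attached to the result.
#' @return A [transfer_function()] on the grid frequency axis, with
#'   `n_windows` set to the number of windows averaged for the measured
#'   excerpt.
#' @export
compute_ratio <- function(measured, excitation_ref, grid,
                          start = 0, excerpt_len = NULL, condition = NULL) {
  stopifnot(inherits(measured, "audio_signal"),
            inherits(excitation_ref, "audio_signal"),
            inherits(grid, "harmonic_grid"))
  if (measured$sample_rate != excitation_ref$sample_rate)
    stop("measured and excitation signals must share a sample rate")
  fs <- measured$sample_rate
  nfft <- round(fs / grid$delta_f)

  i0 <- round(start * fs) + 1L
  i1 <- if (is.null(excerpt_len)) length(measured$samples) else
    min(length(measured$samples), i0 + round(excerpt_len * fs) - 1L)
  if (i0 < 1L || i0 >= i1) stop("excerpt is empty or outside the capture")
  excerpt <- audio_signal(measured$samples[i0:i1], fs)

  # both signals follow the same ceiling segmentation; note that a final
  # zero-padded partial window biases the averaged spectrum slightly, so
  # excerpts (and the reference) are best taken in whole analysis windows
  meas_frames <- segment_windows(excerpt, nfft)
  meas_avg <- average_spectrum(meas_frames)
  exc_avg <- average_spectrum(segment_windows(excitation_ref, nfft))

  idx <- grid$bin_indices + 1L
  eps <- .Machine$double.eps * nfft * max(exc_avg)
  dead <- which(exc_avg[idx] <= eps)
  if (length(dead) > 0L)
    stop(sprintf("excitation reference has no energy at grid bin %d (%.1f Hz)",
                 grid$bin_indices[dead[1L]], grid$frequencies[dead[1L]]))

  transfer_function(frequencies = grid$frequencies,
                    values = meas_avg[idx] / exc_avg[idx],
                    n_windows = ncol(meas_frames),
                    condition = condition)
}
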