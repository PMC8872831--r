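# Pseudorandom multi-harmonic excitation synthesis.
#
# The excitation is a sum of equal-amplitude cosines on the FFT bin grid
# between f_min and f_max with randomised phases, so that a rectangular
# analysis window of fft_len samples sees every component exactly on a bin.

#' Excitation design specification
#'
#' Bundles the parameters that determine the harmonic grid of the broadband
#' excitation: sampling rate, FFT length (which sets the frequency resolution
#' `sample_rate / fft_len` and the analysis-window duration), the excited
#' frequency range, and the seed for phase randomisation.
#'
#' The defaults (44.1 kHz, 2^12-point FFT, 200 Hz to 4 kHz) give 355 harmonics
#' spaced 10.77 Hz apart and a 93 ms analysis window.
#'
#' @param sample_rate Sampling frequency in Hz.
#' @param fft_len FFT length in samples; must be a power of two.
#' @param f_min,f_max Excited frequency range in Hz; `0 < f_min < f_max <
#'   sample_rate / 2`.
#' @param seed Integer seed for the phase generator.
#' @return An object of class `excitation_spec`.
#' @seealso [build_harmonic_grid()], [synthesize_excitation()]
#' @export
excitation_spec <- function(sample_rate = 44100, fft_len = 4096,
                            f_min = 200, f_max = 4000, seed = 1L) {
  if (sample_rate <= 0) stop("'sample_rate' must be positive")
  if (!is_power_of_two(fft_len)) stop("'fft_len' must be a power of two")
  if (!(0 < f_min && f_min <= f_max && f_max < sample_rate / 2))
    stop("need 0 < f_min <= f_max < sample_rate/2")
  structure(list(sample_rate = as.numeric(sample_rate),
                 fft_len = as.integer(fft_len),
                 f_min = as.numeric(f_min),
                 f_max = as.numeric(f_max),
                 seed = as.integer(seed)),
            class = "excitation_spec")
}

#' @export
print.excitation_spec <- function(x, ...) {
  df <- x$sample_rate / x$fft_len
  cat(sprintf(
    "<excitation_spec: fs %g Hz, %d-point FFT (delta_f %.2f Hz, window %.0f ms), %g-%g Hz, seed %d>\n",
    x$sample_rate, x$fft_len, df, 1000 * x$fft_len / x$sample_rate,
    x$f_min, x$f_max, x$seed))
  invisible(x)
}

#' Build the harmonic grid for an excitation specification
#'
#' Selects the FFT bins that carry excitation energy and draws a random phase
#' for each. The bin range brackets the requested band: it runs from the
#' largest bin whose frequency does not exceed `f_min` through the smallest
#' bin whose frequency is not below `f_max`, inclusive. Under the default
#' specification this yields 355 harmonics (bins 18 through 372).
#'
#' Phases are drawn uniformly on \[0, 2*pi) from a generator seeded with
#' `spec$seed`, so the same specification always produces the same grid.
#'
#' @param spec An [excitation_spec()].
#' @return An object of class `harmonic_grid`: a list with `bin_indices`,
#'   `frequencies` (Hz), `phases` (radians) and `delta_f` (Hz).
#' @export
build_harmonic_grid <- function(spec) {
  stopifnot(inherits(spec, "excitation_spec"))
  delta_f <- spec$sample_rate / spec$fft_len
  k_lo <- floor(spec$f_min / delta_f)
  k_hi <- ceiling(spec$f_max / delta_f)
  if (k_hi < k_lo || k_hi < 1L)
    stop("invalid excitation spec: no FFT bin brackets the requested range")
  k_lo <- max(k_lo, 1L)  # never excite DC
  bins <- seq.int(k_lo, k_hi)
  phases <- with_seed(spec$seed, stats::runif(length(bins), 0, 2 * pi))
  structure(list(bin_indices = as.integer(bins),
                 frequencies = bins * delta_f,
                 phases = phases,
                 delta_f = delta_f),
            class = "harmonic_grid")
}

#' @export
print.harmonic_grid <- function(x, ...) {
  cat(sprintf("<harmonic_grid: %d harmonics, %.2f-%.2f Hz, delta_f %.2f Hz>\n",
              length(x$bin_indices), min(x$frequencies), max(x$frequencies),
              x$delta_f))
  invisible(x)
}

#' Synthesize the pseudorandom broadband excitation signal
#'
#' Sums equal-amplitude cosines at the grid frequencies with the grid phases
#' and peak-normalizes the result to 0.9 full scale (headroom for 16-bit
#' export without clipping). Because every component lies exactly on an FFT
#' bin, the signal is periodic with period `fft_len` samples; it is built as
#' one inverse-FFT period and tiled, which is exact for bin-aligned
#' components.
#'
#' @param grid A [build_harmonic_grid()] result.
#' @param duration Signal duration in seconds; must cover at least one
#'   analysis window (`fft_len / sample_rate`). Default 5 s.
#' @param spec The [excitation_spec()] the grid was built from.
#' @return An [audio_signal()].
#' @export
synthesize_excitation <- function(grid, duration = 5, spec) {
  stopifnot(inherits(grid, "harmonic_grid"), inherits(spec, "excitation_spec"))
  n <- round(duration * spec$sample_rate)
  if (n < spec$fft_len)
    stop(sprintf("duration %.4g s is shorter than one analysis window (%.4g s)",
                 duration, spec$fft_len / spec$sample_rate))
  nfft <- spec$fft_len
  if (length(grid$bin_indices) == 0L)
    return(audio_signal(numeric(n), spec$sample_rate))
  # one period via inverse FFT: unit-amplitude cosine at bin k needs
  # X[k] = (N/2) e^{i phi}, X[N-k] = conj(X[k])
  spec_vec <- complex(nfft)
  spec_vec[grid$bin_indices + 1L] <- (nfft / 2) * exp(1i * grid$phases)
  spec_vec[nfft - grid$bin_indices + 1L] <- Conj(spec_vec[grid$bin_indices + 1L])
  period <- Re(stats::fft(spec_vec, inverse = TRUE)) / nfft
  samples <- rep_len(period, n)
  peak <- max(abs(samples))
  if (peak > 0) samples <- samples * (0.9 / peak)
  audio_signal(samples, spec$sample_rate)
}
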