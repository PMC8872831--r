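# Resonator-bank tract simulator: ground truth for the measurement chain.
#
# A simulated capture is the excitation filtered by a linear-phase FIR
# realizing a designed resonator-bank magnitude response (frequency-sampling
# design on the FFT grid, so the ratio at grid bins matches the designed
# response exactly once the filter transient has passed), plus optional voice
# harmonics at multiples of f0 and seeded white noise.

# --- preset constants ---------------------------------------------------
# The two condition presets encode the qualitative normal-vs-hypernasal
# phenomenology: nostril-measured responses show resonances near 2.3 kHz and
# 3 kHz in the normal condition; increased oral-nasal coupling moves the
# 2-2.5 kHz peak down in frequency and gain and adds low-frequency energy
# near 250 Hz. Parameter values are this package's own choices (the
# phenomenology constrains direction, not magnitude).
.preset_constants <- list(
  normal = list(
    resonators = list(c(center = 2300, bandwidth = 200, gain = 1.0),
                      c(center = 3000, bandwidth = 250, gain = 0.8)),
    low_freq_boost = NULL,
    baseline_gain = 0.2,
    nasalance_split = 0.33
  ),
  hypernasal = list(
    resonators = list(c(center = 2050, bandwidth = 250, gain = 0.6),
                      c(center = 3000, bandwidth = 250, gain = 0.8)),
    low_freq_boost = c(center = 250, gain = 0.5, sigma = 120),
    baseline_gain = 0.2,
    nasalance_split = 0.67
  )
)

# Rating-calibration constants for the simulated validation study: logit of
# P(rated hypernasal) = b0 + b1 * nasalance, with between-token spread of the
# nasal energy split around the condition means.
.rating_constants <- list(b0 = -4.2588, b1 = 0.0863, split_sd = 0.08)

#' Single resonator specification
#'
#' @param center Centre frequency in Hz (below Nyquist at use time).
#' @param bandwidth -3 dB bandwidth in Hz, > 0.
#' @param gain Peak magnitude gain, > 0.
#' @return An object of class `resonator_spec`.
#' @export
resonator_spec <- function(center, bandwidth, gain) {
  if (bandwidth <= 0 || gain <= 0 || center <= 0)
    stop("center, bandwidth and gain must be strictly positive")
  structure(list(center = center, bandwidth = bandwidth, gain = gain),
            class = "resonator_spec")
}

#' Simulated tract configuration
#'
#' A resonator bank plus an optional Gaussian low-frequency boost and a flat
#' baseline gain, tagged with the speech condition it represents.
#'
#' @param resonators List of [resonator_spec()]s (may be empty).
#' @param low_freq_boost Optional `c(center, gain, sigma)` Gaussian bump.
#' @param baseline_gain Flat baseline magnitude, > 0.
#' @param condition Condition label, `"normal"` or `"hypernasal"`.
#' @return An object of class `tract_config`.
#' @export
tract_config <- function(resonators = list(), low_freq_boost = NULL,
                         baseline_gain = 0.2,
                         condition = c("normal", "hypernasal")) {
  condition <- match.arg(condition)
  if (baseline_gain <= 0) stop("'baseline_gain' must be strictly positive")
  stopifnot(all(vapply(resonators, inherits, logical(1), "resonator_spec")))
  structure(list(resonators = resonators, low_freq_boost = low_freq_boost,
                 baseline_gain = baseline_gain, condition = condition),
            class = "tract_config")
}

#' Designed tract magnitude response
#'
#' Baseline gain plus the sum of second-order resonator magnitude responses
#' `gain * f*bw / sqrt((fc^2 - f^2)^2 + (f*bw)^2)` (each peaking at `gain` at
#' its centre), plus the optional Gaussian low-frequency boost. Strictly
#' positive everywhere.
#'
#' @param config A [tract_config()].
#' @param frequencies Frequencies in Hz at which to evaluate.
#' @return Numeric magnitude values, same length as `frequencies`.
#' @export
tract_response <- function(config, frequencies) {
  stopifnot(inherits(config, "tract_config"))
  v <- rep(config$baseline_gain, length(frequencies))
  for (r in config$resonators) {
    num <- frequencies * r$bandwidth
    v <- v + r$gain * num / sqrt((r$center^2 - frequencies^2)^2 + num^2)
  }
  if (!is.null(config$low_freq_boost)) {
    b <- config$low_freq_boost
    v <- v + b[["gain"]] * exp(-0.5 * ((frequencies - b[["center"]]) / b[["sigma"]])^2)
  }
  v
}

#' Condition preset
#'
#' The documented normal / hypernasal tract configurations: the normal preset
#' has resonators near 2.3 kHz and 3 kHz; the hypernasal preset moves the
#' first resonator to about 2.05 kHz with reduced gain and adds a
#' low-frequency boost near 250 Hz. `jitter_seed` applies small
#' take-to-take multiplicative jitter (+/-2 % gain, +/-10 Hz centre, both
#' 1 SD) to emulate within-condition variability across repeats.
#'
#' @param name `"normal"` or `"hypernasal"`.
#' @param jitter_seed Optional integer seed; `NULL` returns the exact preset.
#' @return A [tract_config()].
#' @export
tract_preset <- function(name, jitter_seed = NULL) {
  if (!name %in% names(.preset_constants))
    stop(sprintf("unknown preset '%s' (use 'normal' or 'hypernasal')", name))
  pc <- .preset_constants[[name]]
  res <- lapply(pc$resonators, function(r)
    resonator_spec(r[["center"]], r[["bandwidth"]], r[["gain"]]))
  cfg <- tract_config(res, pc$low_freq_boost, pc$baseline_gain, name)
  if (is.null(jitter_seed)) return(cfg)
  with_seed(jitter_seed, {
    cfg$resonators <- lapply(cfg$resonators, function(r)
      resonator_spec(r$center + stats::rnorm(1, 0, 10),
                     r$bandwidth,
                     r$gain * (1 + stats::rnorm(1, 0, 0.02))))
    cfg
  })
}

#' Voice source specification
#'
#' Harmonic voice source superimposed on a simulated capture: harmonics at
#' multiples of `f0` with a spectral tilt, scaled so the voice RMS is `level`
#' times the filtered-excitation RMS. `level = 0` disables the voice.
#'
#' @param f0 Fundamental frequency in Hz, default 250.
#' @param n_harmonics Number of harmonics, default 14.
#' @param tilt Spectral tilt in dB per octave, default -6.
#' @param level Voice RMS relative to the filtered excitation RMS, >= 0.
#' @return An object of class `voice_source`.
#' @export
voice_source <- function(f0 = 250, n_harmonics = 14, tilt = -6, level = 1) {
  if (f0 <= 0) stop("'f0' must be positive")
  if (level < 0) stop("'level' must be >= 0")
  structure(list(f0 = f0, n_harmonics = as.integer(n_harmonics),
                 tilt = tilt, level = level),
            class = "voice_source")
}

# Linear-phase FIR (length nfft, delay nfft/2) realizing the tract response
# by frequency sampling on the nfft-point grid. For an input periodic with
# period nfft the steady-state output is the exact circular convolution, so
# the measured window spectrum is mag[k] * X[k] exactly.
design_tract_fir <- function(config, nfft, sample_rate) {
  freqs <- (0:(nfft / 2)) * sample_rate / nfft
  mag <- tract_response(config, freqs)
  delay <- nfft / 2
  k <- 0:(nfft / 2)
  half <- mag * exp(-2i * pi * k * delay / nfft)
  full <- c(half, Conj(half[(nfft / 2):2]))
  Re(stats::fft(full, inverse = TRUE)) / nfft
}

# FFT-based full convolution, then truncated to the input length (the first
# ~nfft samples carry the filter transient).
fir_filter <- function(x, h) {
  n_out <- length(x) + length(h) - 1L
  nfft <- 2^ceiling(log2(n_out))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE) / nfft)[seq_along(x)]
}

#' Simulate an nRMD capture
#'
#' Filters the excitation with a linear-phase FIR realizing the configured
#' tract response (frequency-sampling design on the FFT grid), then adds
#' voice harmonics and white noise. With voice and noise disabled, the
#' measurement chain recovers the designed response exactly at grid bins once
#' the filter transient (one FFT length) is discarded.
#'
#' @param excitation The excitation [audio_signal()].
#' @param config A [tract_config()].
#' @param voice Optional [voice_source()]; `NULL` or `level = 0` disables it.
#' @param noise_level White-noise RMS relative to the filtered-excitation
#'   RMS, default 0.
#' @param seed Integer seed for voice phases and noise.
#' @param fft_len FFT grid length for the filter design, default 4096.
#' @return The simulated capture as an [audio_signal()].
#' @export
simulate_capture <- function(excitation, config, voice = NULL,
                             noise_level = 0, seed = NULL, fft_len = 4096) {
  stopifnot(inherits(excitation, "audio_signal"),
            inherits(config, "tract_config"))
  fs <- excitation$sample_rate
  h <- design_tract_fir(config, fft_len, fs)
  y <- fir_filter(excitation$samples, h)
  base_rms <- rms(y)
  with_seed(seed, {
    if (!is.null(voice) && voice$level > 0) {
      t <- (seq_along(y) - 1L) / fs
      v <- numeric(length(y))
      m_max <- min(voice$n_harmonics, floor((fs / 2 - 1) / voice$f0))
      amps <- 10^(voice$tilt * log2(seq_len(m_max)) / 20)
      phis <- stats::runif(m_max, 0, 2 * pi)
      for (m in seq_len(m_max))
        v <- v + amps[m] * cos(2 * pi * m * voice$f0 * t + phis[m])
      v <- v * (voice$level * base_rms / rms(v))
      y <- y + v
    }
    if (noise_level > 0)
      y <- y + stats::rnorm(length(y), 0, noise_level * base_rms)
  })
  audio_signal(y, fs)
}

#' Simulate a two-channel nasality recording
#'
#' Generates a voiced harmonic signal and splits its energy between the nasal
#' and oral channels: the nasal channel carries a fraction `split` of the
#' total energy (so the expected nasalance is `100 * split`), plus a small
#' amount of independent noise per channel. By default `split` follows the
#' configured condition (normal 0.33, hypernasal 0.67), the two-group
#' structure either side of about 50 % nasalance.
#'
#' @param config A [tract_config()] (only its condition label is used), or a
#'   condition string.
#' @param duration Duration in seconds.
#' @param seed Integer seed for phases and channel noise.
#' @param split Optional explicit nasal energy fraction in \[0, 1\],
#'   overriding the condition default.
#' @param sample_rate Sample rate in Hz, default 8000.
#' @param noise_level Per-channel noise RMS relative to the voiced-signal
#'   RMS, default 0.001.
#' @return A [nasality_recording()].
#' @export
simulate_nasality_channels <- function(config, duration, seed = NULL,
                                       split = NULL, sample_rate = 8000,
                                       noise_level = 0.001) {
  cond <- if (inherits(config, "tract_config")) config$condition
  else match.arg(config, c("normal", "hypernasal"))
  if (is.null(split)) split <- .preset_constants[[cond]]$nasalance_split
  if (split < 0 || split > 1) stop("'split' must lie in [0, 1]")
  n <- round(duration * sample_rate)
  if (n < 1L) stop("'duration' must be positive")
  t <- (0:(n - 1L)) / sample_rate
  with_seed(seed, {
    m_max <- floor((sample_rate / 2 - 1) / 250)
    amps <- 10^(-6 * log2(seq_len(m_max)) / 20)
    phis <- stats::runif(m_max, 0, 2 * pi)
    s <- numeric(n)
    for (m in seq_len(m_max))
      s <- s + amps[m] * cos(2 * pi * m * 250 * t + phis[m])
    s <- s / max(abs(s)) * 0.8
    sig_rms <- rms(s)
    nasal <- sqrt(split) * s + stats::rnorm(n, 0, noise_level * sig_rms)
    oral <- sqrt(1 - split) * s + stats::rnorm(n, 0, noise_level * sig_rms)
    nasality_recording(nasal, oral, sample_rate)
  })
}

#' Simulate a rated validation token
#'
#' Study-level generator tying the pieces together for one token: draws a
#' token-specific nasal energy split around the condition mean (between-token
#' SD 0.08, clipped to \[0.02, 0.98\]), simulates the two-channel recording,
#' computes its mean nasalance through the nasalance chain, and draws the
#' binary "rated hypernasal" verdict from the logistic rating model
#' `logit(p) = -4.2588 + 0.0863 * nasalance`.
#'
#' @param condition `"normal"` or `"hypernasal"`.
#' @param seed Integer seed for this token.
#' @param duration Recording duration in seconds, default 0.6.
#' @param bandpass Apply the 350-650 Hz nasalance band-pass, default `TRUE`.
#' @return List with `condition`, `split`, `nasalance` (percent) and
#'   `rated_hypernasal` (logical).
#' @export
simulate_rated_token <- function(condition, seed, duration = 0.6,
                                 bandpass = TRUE) {
  condition <- match.arg(condition, c("normal", "hypernasal"))
  base_split <- .preset_constants[[condition]]$nasalance_split
  with_seed(seed, {
    split <- min(0.98, max(0.02, stats::rnorm(1, base_split,
                                              .rating_constants$split_sd)))
    rec <- simulate_nasality_channels(condition, duration,
                                      seed = NULL, split = split)
    if (bandpass) rec <- bandpass_filter(rec)
    nas <- mean_nasalance(nasalance_trace(rec))$mean
    p <- stats::plogis(.rating_constants$b0 + .rating_constants$b1 * nas)
    list(condition = condition, split = split, nasalance = nas,
         rated_hypernasal = stats::runif(1) < p)
  })
}
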