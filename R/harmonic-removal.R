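# Voice-source harmonic removal.
#
# During phonation the voice harmonics ride on the measured ratio as sharp
# narrow peaks. The removal pipeline: smooth the spectrum, detect peaks whose
# topographic prominence exceeds a standard-deviation criterion while
# enforcing a minimum centre separation, replace peaks narrower than a width
# threshold with a straight line between their boundaries, and smooth again.
# Detection runs on log amplitude by default: voice harmonics are a
# multiplicative excess and the spectra are conventionally inspected on a
# logarithmic axis.

#' Removal parameters
#'
#' The constants of the harmonic-removal algorithm: peaks are detected with a
#' prominence of `prominence_sd_multiple` standard deviations of the working
#' spectrum and a minimum centre separation of `min_distance` Hz; detected
#' peaks narrower than `width_threshold` Hz (full width at half prominence)
#' are pruned. `smoothing_span` sets the moving-average width of the two
#' smoothing passes; the default 50 Hz stays below the 65 Hz separation
#' criterion so neighbouring voice harmonics remain individually detectable.
#'
#' @param prominence_sd_multiple Dimensionless prominence criterion, default 1.
#' @param min_distance Minimum peak separation in Hz, default 65.
#' @param width_threshold Pruning width threshold in Hz, default 100.
#' @param smoothing_span Moving-average span in Hz, default 50.
#' @return An object of class `removal_params`.
#' @export
removal_params <- function(prominence_sd_multiple = 1, min_distance = 65,
                           width_threshold = 100, smoothing_span = 50) {
  vals <- c(prominence_sd_multiple, min_distance, width_threshold, smoothing_span)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all removal parameters must be strictly positive")
  structure(list(prominence_sd_multiple = prominence_sd_multiple,
                 min_distance = min_distance,
                 width_threshold = width_threshold,
                 smoothing_span = smoothing_span),
            class = "removal_params")
}

#' Smooth a spectrum with a centred moving average
#'
#' Window width is `round(span / delta_f)` bins, forced odd; edges use a
#' shrinking window so the output length equals the input length. A one-bin
#' window is the identity.
#'
#' @param values Numeric spectrum values.
#' @param span Smoothing span in Hz.
#' @param delta_f Bin spacing in Hz.
#' @return Smoothed values, same length.
#' @export
smooth_spectrum <- function(values, span, delta_f) {
  if (span < delta_f) stop("'span' must be at least one bin (delta_f)")
  k <- round(span / delta_f)
  if (k %% 2 == 0) k <- k + 1L
  if (k <= 1L) return(values)
  h <- (k - 1L) %/% 2L
  n <- length(values)
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima with plateau handling: returns the (rounded) midpoint index of
# each flat-topped run strictly above both neighbours.
find_local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
        i <- j
      }
    }
    i <- i + 1L
  }
  peaks
}

# Topographic prominence of a peak at index p: extend left and right to the
# nearest strictly-higher sample (or the signal edge); the base is the higher
# of the two interval minima. Also returns the base interval bounds.
peak_prominence <- function(v, p) {
  n <- length(v)
  i <- p
  left_min <- v[p]; left_idx <- p
  while (i > 1L && v[i - 1L] <= v[p]) {
    i <- i - 1L
    if (v[i] < left_min) { left_min <- v[i]; left_idx <- i }
  }
  i <- p
  right_min <- v[p]; right_idx <- p
  while (i < n && v[i + 1L] <= v[p]) {
    i <- i + 1L
    if (v[i] < right_min) { right_min <- v[i]; right_idx <- i }
  }
  list(prominence = v[p] - max(left_min, right_min),
       left_base = left_idx, right_base = right_idx)
}

# Full width at half prominence with linear interpolation of the crossing
# points, bounded by the prominence bases. Returns fractional indices.
peak_width_half_prom <- function(v, p, prom, left_base, right_base) {
  h <- v[p] - prom / 2
  i <- p
  while (i > left_base && v[i - 1L] > h) i <- i - 1L
  left_ip <- if (i > left_base && v[i - 1L] <= h)
    (i - 1L) + (h - v[i - 1L]) / (v[i] - v[i - 1L]) else as.numeric(i)
  i <- p
  while (i < right_base && v[i + 1L] > h) i <- i + 1L
  right_ip <- if (i < right_base && v[i + 1L] <= h)
    i + (v[i] - h) / (v[i] - v[i + 1L]) else as.numeric(i)
  c(left_ip, right_ip)
}

#' Detect voice-source peaks
#'
#' Finds local maxima whose topographic prominence is at least
#' `prominence_sd_multiple` times the standard deviation of the supplied
#' (already smoothed) values, then enforces the minimum centre separation by
#' keeping the more prominent of any two peaks closer than `min_distance`.
#' Width is the full width at half prominence, interpolated between bins.
#'
#' @param values Smoothed spectrum values.
#' @param frequencies Frequency axis in Hz (uniformly spaced).
#' @param params A [removal_params()].
#' @return A `peak_set`: data frame with one row per surviving peak
#'   (`center_index`, `center_frequency`, `height`, `prominence`, `width_hz`,
#'   `left_idx`, `right_idx`). Zero rows when nothing qualifies.
#' @export
detect_voice_peaks <- function(values, frequencies, params = removal_params()) {
  stopifnot(length(values) == length(frequencies))
  empty <- data.frame(center_index = integer(0), center_frequency = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      width_hz = numeric(0), left_idx = integer(0),
                      right_idx = integer(0))
  class(empty) <- c("peak_set", "data.frame")
  cand <- find_local_maxima(values)
  if (length(cand) == 0L) return(empty)
  delta_f <- if (length(frequencies) > 1L)
    (frequencies[length(frequencies)] - frequencies[1L]) / (length(frequencies) - 1L)
  else 1

  threshold <- params$prominence_sd_multiple * stats::sd(values)
  rows <- lapply(cand, function(p) {
    pr <- peak_prominence(values, p)
    if (pr$prominence < threshold || pr$prominence <= 0) return(NULL)
    w <- peak_width_half_prom(values, p, pr$prominence,
                              pr$left_base, pr$right_base)
    data.frame(center_index = p,
               center_frequency = frequencies[p],
               height = values[p],
               prominence = pr$prominence,
               width_hz = (w[2L] - w[1L]) * delta_f,
               left_idx = max(1L, as.integer(floor(w[1L]))),
               right_idx = min(length(values), as.integer(ceiling(w[2L]))))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  peaks <- do.call(rbind, rows)

  # enforce min_distance: greedily keep by descending prominence
  ord <- order(-peaks$prominence, peaks$center_frequency)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(peaks$center_frequency[i] -
                peaks$center_frequency[kept]) >= params$min_distance))
      kept <- c(kept, i)
  }
  peaks <- peaks[sort(kept), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}

#' Prune narrow peaks from a spectrum
#'
#' For every detected peak narrower than `width_threshold`, the values between
#' its left and right half-prominence boundaries are replaced by the straight
#' line joining the boundary values. Wider peaks are left untouched.
#'
#' @param values Spectrum values the peaks were detected on.
#' @param frequencies Frequency axis in Hz.
#' @param peaks A `peak_set` from [detect_voice_peaks()].
#' @param params A [removal_params()].
#' @return Values with narrow-peak regions replaced, same length.
#' @export
prune_narrow_peaks <- function(values, frequencies, peaks,
                               params = removal_params()) {
  out <- values
  if (nrow(peaks) == 0L) return(out)
  narrow <- peaks[peaks$width_hz < params$width_threshold, , drop = FALSE]
  for (i in seq_len(nrow(narrow))) {
    l <- narrow$left_idx[i]
    r <- narrow$right_idx[i]
    if (r - l < 1L) next
    out[l:r] <- seq(out[l], out[r], length.out = r - l + 1L)
  }
  out
}

#' Remove voice-source harmonics from a transfer function
#'
#' Runs the full pipeline — smooth, detect, prune, smooth again — and returns
#' the transfer function flagged `harmonics_removed = TRUE`. By default the
#' pipeline operates on log10 amplitude (`log_scale = TRUE`); set
#' `log_scale = FALSE` to work on linear values.
#'
#' Re-running on an already-flagged transfer function issues a warning and
#' returns the input unchanged.
#'
#' @param tf A [transfer_function()].
#' @param params A [removal_params()].
#' @param log_scale Detect and prune on log10 amplitude (default `TRUE`).
#' @return The cleaned [transfer_function()], flagged `harmonics_removed`.
#' @export
remove_harmonics <- function(tf, params = removal_params(), log_scale = TRUE) {
  stopifnot(inherits(tf, "transfer_function"))
  if (tf$harmonics_removed) {
    warning("transfer function is already flagged harmonics_removed; returning unchanged")
    return(tf)
  }
  delta_f <- if (length(tf$frequencies) > 1L)
    (tf$frequencies[length(tf$frequencies)] - tf$frequencies[1L]) /
      (length(tf$frequencies) - 1L)
  else params$smoothing_span
  v <- if (log_scale) log10(pmax(tf$values, .Machine$double.xmin)) else tf$values

  v <- smooth_spectrum(v, params$smoothing_span, delta_f)
  peaks <- detect_voice_peaks(v, tf$frequencies, params)
  v <- prune_narrow_peaks(v, tf$frequencies, peaks, params)
  v <- smooth_spectrum(v, params$smoothing_span, delta_f)

  out_values <- if (log_scale) 10^v else pmax(v, 0)
  transfer_function(tf$frequencies, out_values, tf$n_windows,
                    condition = tf$condition, harmonics_removed = TRUE)
}
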