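# internal helpers shared across modules

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

is_power_of_two <- function(n) {
  n == round(n) && n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

rms <- function(x) sqrt(mean(x^2))

#' Construct an audio signal
#'
#' Lightweight container for a mono sampled signal: a numeric vector of
#' dimensionless amplitudes (nominally within \[-1, 1\] for playback) plus its
#' sample rate.
#'
#' @param samples Numeric vector of finite sample values.
#' @param sample_rate Sampling frequency in Hz.
#' @return An object of class `audio_signal` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    stop("'samples' must contain only finite values")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("'sample_rate' must be a single positive number")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

duration_s <- function(sig) length(sig$samples) / sig$sample_rate
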