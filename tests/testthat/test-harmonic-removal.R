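delta_10 <- 10  # convenient uniform axis for constructed fixtures

test_that("moving-average smoothing preserves constants and spreads impulses", {
  x <- rep(3.2, 50)
  expect_equal(smooth_spectrum(x, 50, delta_10), x)

  y <- stats::rnorm(50)
  expect_equal(smooth_spectrum(y, delta_10, delta_10), y)  # 1-bin kernel

  imp <- numeric(51); imp[26] <- 10
  sm <- smooth_spectrum(imp, 50, delta_10)  # 5-bin kernel
  expect_equal(sm[24:28], rep(2, 5))        # plateau of h/5
  expect_equal(sm[c(23, 29)], c(0, 0))
  expect_length(sm, 51)
})

test_that("peak detection needs local maxima with sufficient prominence", {
  freqs <- seq(0, 990, by = delta_10)
  params <- removal_params()

  ramp <- seq_along(freqs) * 0.1
  expect_equal(nrow(detect_voice_peaks(ramp, freqs, params)), 0)

  # flat baseline + one clear bump -> exactly one peak at the bump centre
  bump <- 0.05 * sin(seq_along(freqs)) + 3 * exp(-0.5 * ((freqs - 500) / 30)^2)
  pk <- detect_voice_peaks(bump, freqs, params)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$center_frequency, 500)
  expect_gt(pk$prominence, stats::sd(bump))

  # two bumps 40 Hz apart (< 65 Hz separation): the taller survives
  two <- 2 * exp(-0.5 * ((freqs - 480) / 12)^2) +
    3 * exp(-0.5 * ((freqs - 520) / 12)^2)
  pk2 <- detect_voice_peaks(two, freqs, params)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$center_frequency, 520)
})

test_that("pruning replaces narrow peaks with a chord and leaves wide peaks alone", {
  freqs <- seq(0, 1990, by = delta_10)
  params <- removal_params()
  base <- 1 + freqs / 4000

  narrow <- base + 5 * exp(-0.5 * ((freqs - 800) / 18)^2)  # ~42 Hz FWHM
  pk <- detect_voice_peaks(narrow, freqs, params)
  expect_equal(nrow(pk), 1)
  expect_lt(pk$width_hz, params$width_threshold)
  pruned <- prune_narrow_peaks(narrow, freqs, pk, params)
  l <- pk$left_idx; r <- pk$right_idx
  chord <- seq(narrow[l], narrow[r], length.out = r - l + 1)
  expect_equal(pruned[l:r], chord)
  expect_identical(pruned[-(l:r)], narrow[-(l:r)])

  wide <- base + 5 * exp(-0.5 * ((freqs - 800) / 130)^2)  # ~300 Hz FWHM
  pkw <- detect_voice_peaks(wide, freqs, params)
  expect_gt(pkw$width_hz[1], params$width_threshold)
  expect_identical(prune_narrow_peaks(wide, freqs, pkw, params), wide)

  empty <- detect_voice_peaks(seq_along(freqs) * 0.1, freqs, params)
  expect_identical(prune_narrow_peaks(narrow, freqs, empty, params), narrow)
})

test_that("removal pipeline preserves smooth spectra and flags its output", {
  tf <- clean_capture_tf()
  cleaned <- remove_harmonics(tf)
  expect_true(cleaned$harmonics_removed)
  expect_false(tf$harmonics_removed)
  rc <- rank_correlation(cleaned$values, tf$values)
  expect_gte(rc$rho, 0.99)

  flat <- transfer_function(default_grid()$frequencies, rep(2, 355), 5)
  expect_equal(remove_harmonics(flat)$values, rep(2, 355), tolerance = 1e-12)

  expect_warning(again <- remove_harmonics(cleaned), "already flagged")
  expect_identical(again$values, cleaned$values)
})

test_that("voice-harmonic excess is reduced by at least half at harmonic bins", {
  tf <- voiced_capture_tf()
  cleaned <- remove_harmonics(tf)
  truth <- tract_response(tract_preset("normal"), default_grid()$frequencies)
  hb <- voice_harmonic_bins()
  excess_in <- tf$values[hb] - truth[hb]
  excess_out <- cleaned$values[hb] - truth[hb]
  # the claim applies to harmonics that actually inject a clear peak; with
  # the -6 dB/octave source tilt the upper harmonics leave no excess at the
  # nearest bin (some even interfere destructively with the excitation)
  strong <- excess_in > 0.1
  expect_gte(sum(strong), 5)
  expect_true(all(excess_out[strong] <= 0.5 * excess_in[strong]))
  expect_lte(max(cleaned$values), max(tf$values))
})

test_that("re-detection on the cleaned spectrum finds no narrow prominent peaks", {
  cleaned <- remove_harmonics(voiced_capture_tf())
  params <- removal_params()
  pk <- detect_voice_peaks(log10(cleaned$values), cleaned$frequencies, params)
  if (nrow(pk) > 0)
    expect_true(all(pk$width_hz >= params$width_threshold))
})

test_that("removal is deterministic", {
  a <- remove_harmonics(voiced_capture_tf())
  b <- remove_harmonics(voiced_capture_tf())
  expect_identical(a$values, b$values)
})
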