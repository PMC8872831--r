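tone_recording <- function(f, fs = 8000, dur = 0.5) {
  t <- (0:(dur * fs - 1)) / fs
  s <- 0.5 * sin(2 * pi * f * t)
  nasality_recording(s, s, fs)
}

test_that("band-pass keeps the 500 Hz band and rejects 100 Hz", {
  in500 <- tone_recording(500)
  out500 <- bandpass_filter(in500)
  expect_gte(sqrt(mean(out500$nasal$samples^2)) /
               sqrt(mean(in500$nasal$samples^2)), 0.95)

  in100 <- tone_recording(100)
  out100 <- bandpass_filter(in100)
  expect_lte(sqrt(mean(out100$nasal$samples^2)) /
               sqrt(mean(in100$nasal$samples^2)), 0.10)

  zero <- nasality_recording(rep(0, 4000), rep(0, 4000))
  expect_true(all(abs(bandpass_filter(zero)$nasal$samples) < 1e-12))

  expect_error(bandpass_filter(in500, low = 650, high = 350), "invalid band")
})

test_that("framewise nasalance follows the energy ratio", {
  fs <- 8000
  t <- (0:(fs / 2 - 1)) / fs
  voiced <- 0.5 * sin(2 * pi * 250 * t)

  silent_nasal <- nasality_recording(rep(0, length(t)), voiced, fs)
  tr0 <- nasalance_trace(silent_nasal)
  expect_true(all(tr0$values == 0, na.rm = TRUE))

  equal <- nasality_recording(voiced, voiced, fs)
  expect_true(all(abs(nasalance_trace(equal)$values - 50) < 1e-9))

  double <- nasality_recording(2 * voiced, voiced, fs)  # energy 4:1
  expect_true(all(abs(nasalance_trace(double)$values - 80) < 1e-9))
})

test_that("nasalance is bounded, scale invariant and channel-swap antisymmetric", {
  for (seed in 1:4) {
    rec <- simulate_nasality_channels("hypernasal", 0.4, seed = seed,
                                      split = stats::runif(1))
    tr <- nasalance_trace(rec)
    vals <- tr$values[!is.na(tr$values)]
    expect_true(all(vals >= 0 & vals <= 100))

    scaled <- nasality_recording(
      audio_signal(3.7 * rec$nasal$samples, rec$sample_rate),
      audio_signal(3.7 * rec$oral$samples, rec$sample_rate))
    expect_equal(nasalance_trace(scaled)$values, tr$values, tolerance = 1e-9)

    swapped <- nasality_recording(rec$oral, rec$nasal)
    expect_equal(nasalance_trace(swapped)$values, 100 - tr$values,
                 tolerance = 1e-9)
  }
})

test_that("silent frames are undefined and an all-silent recording warns", {
  fs <- 8000
  n <- fs %/% 2
  half_silent <- nasality_recording(
    c(rep(0, n / 2), 0.5 * sin(2 * pi * 300 * (1:(n / 2)) / fs)),
    rep(0, n), fs)
  tr <- nasalance_trace(half_silent)
  expect_true(anyNA(tr$values))
  expect_true(any(!is.na(tr$values)))

  expect_warning(nasalance_trace(nasality_recording(rep(0, n), rep(0, n), fs)),
                 "silent")
})

test_that("region summaries use the sample standard deviation", {
  tr <- structure(list(frame_times = c(0.1, 0.2), values = c(20, 40),
                       frame_len = 200L, hop = 80L, bandpass_applied = FALSE),
                  class = "nasalance_trace")
  s <- mean_nasalance(tr)
  expect_equal(s$mean, 30)
  expect_equal(s$sd, stats::sd(c(20, 40)))  # n - 1 denominator, 14.142...
  expect_equal(round(s$sd, 2), 14.14)

  one <- mean_nasalance(tr, region = c(0.05, 0.15))
  expect_equal(one$mean, 20)
  expect_equal(one$sd, 0)
  expect_equal(one$n_frames, 1)

  const <- structure(list(frame_times = 1:5 / 10, values = rep(30, 5),
                          frame_len = 200L, hop = 80L,
                          bandpass_applied = FALSE),
                     class = "nasalance_trace")
  sc <- mean_nasalance(const)
  expect_equal(sc$mean, 30)
  expect_equal(sc$sd, 0)

  expect_error(mean_nasalance(tr, region = c(0.5, 0.6)), "no defined")
})
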