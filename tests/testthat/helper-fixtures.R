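# Shared fixtures, computed lazily and cached for the whole test run.
# Simulations use scaled-down study conditions: a 32-window (~3 s)
# excitation (a whole number of analysis windows, so the averaged reference
# spectrum is exact), 8-window excerpts starting after the one-window filter
# transient, voice level 0.5, noise level 0.01.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

default_spec <- function() fixture("spec", excitation_spec())
default_grid <- function() fixture("grid", build_harmonic_grid(default_spec()))
test_excitation <- function() fixture(
  "exc2",
  synthesize_excitation(default_grid(), 32 * 4096 / 44100, default_spec()))

# excerpt bounds skipping the filter transient, whole analysis windows
excerpt_start <- function() 4096 / 44100
excerpt_len <- function() 8 * 4096 / 44100

# clean capture: normal preset, no voice, no noise
clean_capture_tf <- function() fixture("tf_clean", {
  cfg <- tract_preset("normal")
  cap <- simulate_capture(test_excitation(), cfg, fft_len = 4096)
  compute_ratio(cap, test_excitation(), default_grid(),
                start = excerpt_start(), excerpt_len = excerpt_len())
})

# voiced, noisy capture of the normal preset (for harmonic-removal tests)
voiced_capture_tf <- function() fixture("tf_voiced", {
  cfg <- tract_preset("normal")
  cap <- simulate_capture(test_excitation(), cfg,
                          voice = voice_source(level = 0.5),
                          noise_level = 0.01, seed = 3, fft_len = 4096)
  compute_ratio(cap, test_excitation(), default_grid(),
                start = excerpt_start(), excerpt_len = excerpt_len())
})

# grid bins nearest to the voice harmonics inside the excitation band
voice_harmonic_bins <- function(f0 = 250) {
  g <- default_grid()
  f <- f0 * seq_len(15)
  f <- f[f >= min(g$frequencies) & f <= max(g$frequencies) - 100]
  vapply(f, function(fi) which.min(abs(g$frequencies - fi)), integer(1))
}

# six replicate transfer functions (3 takes x 2 conditions), voice and noise
# on, per-take preset jitter, harmonics removed
six_condition_tfs <- function() fixture("tfs6", {
  mk <- function(cond, k) {
    cfg <- tract_preset(cond, jitter_seed = 100 * k + (cond == "hypernasal"))
    cap <- simulate_capture(test_excitation(), cfg,
                            voice = voice_source(level = 0.5),
                            noise_level = 0.01,
                            seed = 10 * k + (cond == "hypernasal"),
                            fft_len = 4096)
    remove_harmonics(compute_ratio(cap, test_excitation(), default_grid(),
                                   start = excerpt_start(),
                                   excerpt_len = excerpt_len(),
                                   condition = cond))
  }
  c(lapply(1:3, mk, cond = "hypernasal"), lapply(1:3, mk, cond = "normal"))
})

# exact two-sided signed-rank p by enumerating every sign assignment
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}
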