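---
title: "Measuring nasal-tract transfer functions with broadband excitation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nasal-tract transfer functions with broadband excitation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrmd)
```

## The measurement model

The quantity this package estimates is a unit-less magnitude "ratio": the
averaged spectrum of a microphone capture taken at the nostrils while
broadband noise excites the nasal/vocal tract, divided by the averaged
spectrum of the excitation itself, evaluated on the excitation's harmonic
grid. Because the same excitation is used for every measurement of a
speaker, the ratio cancels the stimulus and retains the tract's filtering;
because no level calibration is applied, it is meaningful in *comparisons*
(normal vs hypernasal productions of the same speaker) rather than as an
absolute transfer function. The key assumptions are linearity and approximate
time-invariance of the tract over the analysed excerpt, which is why the
method suits sustained vowels and not connected speech: the 93 ms analysis
window is longer than the interval over which running speech is
quasi-stationary, and window averaging assumes a stable configuration.

### Excitation design

The excitation is a sum of equal-amplitude cosines with uniformly random
phases at every FFT bin between `f_min` and `f_max`. All parameters live in
`excitation_spec()`:

| parameter | default | role |
|---|---|---|
| `sample_rate` | 44100 Hz | sampling rate of the capture chain |
| `fft_len` | 4096 (2^12) | sets Δf = fs/N = 10.77 Hz and the 93 ms window |
| `f_min`, `f_max` | 200, 4000 Hz | excited band |
| `seed` | 1 | phase randomisation |

The harmonic grid *brackets* the band: bins run from
`floor(f_min/Δf)` to `ceil(f_max/Δf)` inclusive, giving 355 harmonics under
the defaults. The endpoint rule is a genuine design choice — strict
inclusion (bins strictly inside the band) would give 353 — and bracketing
was chosen because it is the only natural convention that reproduces the
355-harmonic design count. A consequence of the bracketing rule is that the
grid is never empty for any valid band, however narrow: the degenerate case
`f_min = f_max` on a bin frequency yields a single-harmonic grid.

Synthesis exploits the fact that every component is bin-aligned: one period
of length `fft_len` is built by inverse FFT and tiled, which makes the
signal exactly periodic. The peak is normalized to 0.9 full scale — a
digital headroom convention (the hardware chain sets playback level in
dB SPL, which has no digital counterpart) that guarantees clipping-free
16-bit export. Amplitudes are equal across harmonics: the earlier
closed-tract calibration stage that shaped per-harmonic amplitudes is
deliberately not implemented, since condition *differences* within a speaker
are unaffected by a fixed spectral envelope.

### Ratio estimation

`segment_windows()` cuts the capture into non-overlapping rectangular
windows of `fft_len` samples, zero-padding a final partial window (ceiling
convention — the only one consistent with 11 windows for a 1 s excerpt at
the default design). `average_spectrum()` averages *magnitude* FFTs, not
powers and not complex spectra; the upstream software's averaging domain is
unpublished, and magnitude averaging matches the displayed log-amplitude
ratios this pipeline feeds. The ratio is evaluated at grid bins only:
off-grid bins carry no excitation energy, so the ratio is undefined there
(requesting a bin where the reference has no energy raises an error naming
the bin).

Excerpt selection (`start`, `excerpt_len` of `compute_ratio()`) is manual by
design, mirroring how one-second stretches of consistent pitch and amplitude
are chosen from a sustained vowel. One numerical caveat is documented in the
code: a zero-padded partial window biases the averaged spectrum slightly
(the pad spreads energy off the harmonic bins), so accurate work should use
excerpts — and an excitation reference — spanning a whole number of
analysis windows. The package's own tests use a 32-window reference and
8-window excerpts taken after the one-window filter transient, under which
the simulator's designed responses are recovered to floating-point accuracy;
the 1 % tolerance asserted in the tests leaves room for less careful
excerpting.

## Voice-harmonic removal

Phonation superimposes narrow peaks on the ratio at multiples of f0
(≈250 Hz here). The removal pipeline is smooth → detect → prune → smooth,
with constants in `removal_params()`:

| parameter | default | meaning |
|---|---|---|
| `prominence_sd_multiple` | 1 | detection threshold, in SDs of the working spectrum |
| `min_distance` | 65 Hz | minimum peak-centre separation |
| `width_threshold` | 100 Hz | peaks narrower than this are pruned |
| `smoothing_span` | 50 Hz | moving-average span of both smoothing passes |

Several details are underdetermined by the constants alone, and the package
documents its choices:

* **Working scale.** Detection and pruning run on log10 amplitude by default
  (`log_scale = TRUE`): voice harmonics are multiplicative excess and the
  spectra are conventionally inspected on a log axis. The switch is exposed.
* **Prominence baseline.** "1 standard deviation" is computed over the whole
  working spectrum (all grid bins) — the simplest reading; a local SD is a
  possible alternative that would require a neighbourhood parameter the
  design does not supply.
* **Width.** Full width at half prominence, the standard topographic
  definition, with sub-bin interpolation of the crossing points.
* **Straight line.** The replacement line joins the values at the peak's
  half-prominence boundary bins — the minimal anchor choice.
* **Tie-break.** When two peaks fall within `min_distance`, the more
  prominent one is kept (deterministic greedy pass in descending
  prominence).
* **Smoothing span.** 50 Hz (≈5 bins, forced odd) stays below the 65 Hz
  separation criterion so adjacent voice harmonics remain individually
  detectable; edges use a shrinking window so length is preserved.

The pipeline never increases the spectrum's maximum (smoothing and chord
replacement are both max-non-increasing), is deterministic, and flags its
output; re-running on flagged input warns and returns the input unchanged.
One property the tests make precise: the ≥50 % reduction of voice-harmonic
excess applies to harmonics that actually inject a clear peak. With a
−6 dB/octave source tilt the uppermost harmonics leave little or no excess
at the nearest grid bin (magnitude averaging of a non-bin-aligned component
can even interfere destructively), so the assertion is made over harmonics
whose injected excess exceeds 0.1 ratio units.

## Nasalance

Nasalance is `100 * E_nasal / (E_nasal + E_oral)` per frame, energies being
sums of squared samples. Framing is 25 ms with a 10 ms hop — not prescribed
by the upstream device (whose internals are proprietary) but standard speech
practice; both are parameters. The 350–650 Hz analysis band is realized as
an order-2 Butterworth band-pass (a 4th-order transfer function) applied
forward-backward, i.e. zero-phase, keeping the two channels time-aligned;
the commercial device's filter realization is unpublished, so numerical
parity is claimed only with the defining energy-ratio formula, not with any
particular product. Frames whose combined energy falls below 1e-8 of a
full-scale frame are undefined (avoiding 0/0) and excluded from summaries;
summaries use the sample SD (n−1; a single frame reports SD 0). The trace
is bounded in [0, 100], invariant to common scaling of both channels, and
channel-swap antisymmetric (v → 100 − v) — all property-tested.

## Condition statistics

* **Rank correlation** — Spearman with average ranks and the t-approximation
  p-value (`stats::cor.test`, `exact = FALSE`); constant vectors are an
  error rather than NA.
* **Kolmogorov–Smirnov** — `stats::ks.test`, asymptotic p.
* **Wilcoxon signed-rank** — implemented in-package because the base
  function does not expose the Z statistic the workflow reports: zeros
  dropped, average ranks, tie-corrected normal approximation, no continuity
  correction. The normal approximation is used at every n (the workflow
  applies it bin-wise across hundreds of bins); an exhaustive sign-flip
  enumeration serves as the test oracle at n ≤ 12, where the two agree to
  within 0.06 in p.
* **Agreement** — a verdict matches when it agrees with the intended
  condition; "could not tell" never matches. In Cohen's kappa, by contrast,
  "could not tell" is a full third category: kappa measures rater
  self-consistency across repeats, not correctness.
* **Logistic calibration** — `stats::glm` (binomial IRLS, coefficient
  tolerance 1e-8); perfect separation and single-class inputs are explicit
  errors. The halfway point is −b0/b1 from the *unrounded* fit. (Evaluating
  −b0/b1 from externally rounded two/four-decimal coefficients can differ
  from a published halfway point in the second decimal; the package always
  reports its own fit.)
* **Difference spectrum** — per-bin mean(hypernasal) − mean(normal);
  negative values mean the normal condition is larger. No multiple-testing
  correction is applied anywhere, matching the unadjusted reporting
  convention of this workflow.
* Report rounding: two decimals for correlations, one for percentages.

## The simulator: what it emulates, and what it does not

`tract_preset()` encodes the condition contrast as a resonator bank:

* **normal** — resonators at 2300 Hz (bandwidth 200 Hz, gain 1.0) and
  3000 Hz (250 Hz, 0.8) over a 0.2 baseline;
* **hypernasal** — the first resonator moved to 2050 Hz with gain 0.6, the
  3000 Hz resonator shared, plus a Gaussian low-frequency boost at 250 Hz
  (gain 0.5, sigma 120 Hz).

The direction of these changes — the 2–2.5 kHz peak lower in frequency and
amplitude, more energy near 200–300 Hz — is the documented hypernasal
phenomenology; the magnitudes are this package's own constants, declared
once in `R/simulator.R`. Take-to-take variability is modelled as ±2 % gain
and ±10 Hz centre jitter (1 SD) per take. Captures are built by filtering
the excitation with a linear-phase FIR obtained by frequency sampling on
the FFT grid — chosen so that the steady-state ratio at grid bins equals
the designed response *exactly*, making the simulator a closed-form oracle
for the whole chain — plus seeded voice harmonics and white noise.

For nasalance, `simulate_nasality_channels()` splits a voiced harmonic
signal between channels by an energy fraction tied to condition (normal
0.33, hypernasal 0.67, between-token SD 0.08 in `simulate_rated_token()`),
chosen once to produce two groups either side of ~50 % nasalance with
slight overlap. Simulated verdicts follow a logistic rating model with
intercept −4.2588 and slope 0.0863 per percent nasalance — the published
calibration of expert ratings against nasalance, used here as the
generator's ground truth so that the fitting code can be exercised against
known coefficients.

What the simulator does **not** model: physiological acoustics (paranasal
sinuses, wall absorption, the missing ~700 Hz nasal resonance and its
coupling-dependent behaviour), vowel identity (one resonator bank stands in
for all vowels), source-tract interaction, or room acoustics. Passing tests
on simulated data therefore demonstrate that the *signal chain* is correct
and that the documented condition contrast is recoverable when present;
they do not validate the clinical sensitivity of the method on real
speakers, which requires real recordings.

A further stand-in: the per-token expert ratings behind the published
agreement summaries are not distributed, so `synthetic_ratings_table()`
reconstructs a session whose marginal counts match every reported figure
(208 presentations, 95.7 % agreement, the nine mismatch tokens by word,
96.9 % after excluding the three high-nasalance words, 94 % repeat
agreement, kappa 0.88). It is labelled synthetic throughout; conclusions
drawn from it are about the agreement arithmetic, not about the raters.

## Problem sizes and numerical conventions

The test suite and the acceptance script run simulations at deliberately
moderate sizes, stated here as the package's choices: a 32-window (~3 s)
excitation, 8-window excerpts starting after the one-window FIR transient,
three takes per condition, voice level 0.5, noise level 0.01; 400 simulated
rated tokens (0.6 s at 8 kHz) for the logistic calibration; 200 replicates
at n = 500 for the slope-recovery property. All randomness flows through
explicit seeds (`with_seed` scoping restores the caller's RNG state), so
every reported number is reproducible bit-for-bit.

Degenerate inputs are errors, not silent results: empty excerpts, signals
shorter than one window, constant vectors in correlation, all-zero paired
differences, single-class or separated logistic data, silent recordings
(warning + all-undefined trace), invalid bands and unknown presets.

## Known limitations

* Magnitude-only processing: no phase information is retained, so the
  pipeline cannot distinguish minimum-phase from mixed-phase tract changes.
* The ceiling-window convention biases ratios slightly when excerpts are
  not whole multiples of the window length (quantified above); this is
  inherent to the stated segmentation and documented rather than corrected.
* The prominence SD baseline is global; spectra with strongly varying local
  variance may need the exposed parameters retuned.
* Nasalance numerical parity with commercial devices is not claimed.
* Connected speech is out of scope: the long analysis window and the
  averaging stage presume a sustained articulatory configuration.
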