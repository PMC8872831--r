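# nrmd

Hypernasality — excess nasal resonance during speech, usually caused by
velopharyngeal insufficiency (incomplete closure of the soft palate against
the pharyngeal wall, most often after cleft palate) — is clinically assessed
by expert perceptual rating, supplemented by acoustic indices such as
nasalance. `nrmd` implements the signal chain of a non-invasive alternative:
measuring the transfer function of the nasal/vocal tract system by playing
pseudorandom broadband noise at the nostrils and recording the response with
a co-located microphone (a nostril resonance measurement device), then
comparing normal and hypernasal productions of the same vowels.

The package is aimed at speech-acoustics researchers who want to reproduce,
test or extend this measurement chain without the hardware: a built-in
resonator-bank tract simulator generates ground-truth captures for every
stage.

## The method

1. **Excitation.** The stimulus is a sum of equal-amplitude cosines with
   randomised phases on the FFT bin grid between *f*<sub>min</sub> and
   *f*<sub>max</sub>. With the defaults — *f*<sub>s</sub> = 44.1 kHz, a
   2¹²-point FFT, 200 Hz–4 kHz — the grid has 355 harmonics spaced
   Δf = *f*<sub>s</sub>/N = 10.77 Hz apart, and the analysis window is
   N/*f*<sub>s</sub> ≈ 93 ms.
2. **Ratio estimation.** The capture is split into non-overlapping
   rectangular windows of N samples (a 1 s excerpt gives 11 windows; a final
   partial window is zero-padded), the magnitude FFTs are averaged across
   windows, and the unit-less "ratio" is the averaged measured spectrum over
   the averaged excitation spectrum, evaluated at the harmonic bins.
3. **Voice-harmonic removal.** During phonation the voice source adds sharp
   narrow peaks at multiples of f₀ (≈250 Hz). The cleaning pipeline smooths
   the log spectrum, detects peaks with topographic prominence ≥ 1 SD and
   centre separation ≥ 65 Hz, replaces peaks narrower than 100 Hz (full
   width at half prominence) with a straight line, and smooths again.
4. **Nasalance.** From a two-channel nasality-microphone recording
   (nasal = left, oral = right, band-passed 350–650 Hz), nasalance is
   100·E<sub>nasal</sub>/(E<sub>nasal</sub>+E<sub>oral</sub>) per frame.
5. **Condition statistics.** Spearman rank correlations within and across
   speech conditions, two-sample Kolmogorov–Smirnov and paired Wilcoxon
   signed-rank tests, rater agreement and Cohen's kappa, a logistic
   calibration of perceptual ratings against nasalance, and the
   hypernasal-minus-normal difference spectrum.

## Worked example

```r
library(nrmd)

# design the excitation
spec <- excitation_spec()          # 44.1 kHz, 2^12-point FFT, 200 Hz - 4 kHz
grid <- build_harmonic_grid(spec)
print(grid)
#> <harmonic_grid: 355 harmonics, 193.80-4005.18 Hz, delta_f 10.77 Hz>

# synthesize and "measure" simulated vowels (3 takes per condition)
exc <- synthesize_excitation(grid, duration = 32 * 4096 / 44100, spec)
measure <- function(cond, k) {
  cfg <- tract_preset(cond, jitter_seed = 100 * k)
  cap <- simulate_capture(exc, cfg, voice = voice_source(level = 0.5),
                          noise_level = 0.01, seed = k, fft_len = 4096)
  tf <- compute_ratio(cap, exc, grid, start = 4096 / 44100,
                      excerpt_len = 8 * 4096 / 44100, condition = cond)
  remove_harmonics(tf)
}
tfs_hn <- lapply(1:3, measure, cond = "hypernasal")
tfs_nm <- lapply(4:6, measure, cond = "normal")
print(tfs_hn[[1]])
#> <transfer_function: 355 bins, 193.8-4005.2 Hz, 8 windows, hypernasal, harmonics removed>

# replicate consistency and the condition contrast
report <- correlation_report(c(tfs_hn, tfs_nm))
print(report)
#> <correlation_report: within HN 1.00, within N 1.00, across 0.81; within range 0.00>
ds <- difference_spectrum(tfs_hn, tfs_nm, scope = "pooled")
cat(sprintf("band mean 2-2.5 kHz: %+.3f   band mean 200-300 Hz: %+.3f\n",
            band_mean(ds, 2000, 2500), band_mean(ds, 200, 300)))
#> band mean 2-2.5 kHz: -0.278   band mean 200-300 Hz: +0.359

# nasalance of a simulated hypernasal token
rec <- bandpass_filter(simulate_nasality_channels("hypernasal", 0.6, seed = 42))
print(mean_nasalance(nasalance_trace(rec)))
#> <nasalance: mean 67.0%, sd 0.0%, 58 frames in [0.01, 0.58] s>
```

Reading the output: replicate takes of the same condition correlate more
strongly (1.00) than takes across conditions (0.81); the pooled difference
spectrum is negative over 2–2.5 kHz (the normal condition's peak there is
higher and at a higher frequency) and positive near 200–300 Hz (the
hypernasal condition carries more low-frequency energy); and the simulated
hypernasal token sits above 50 % nasalance, on the hypernasal side of the
two-group boundary.

## Command line

A thin wrapper over the same functions ships in `inst/cli/nrmd`:

```sh
Rscript inst/cli/nrmd synthesize --duration 5 --seed 1 -o excitation.wav
Rscript inst/cli/nrmd simulate --preset hypernasal --takes 3 --seed 7 -o captures/
Rscript inst/cli/nrmd measure --excitation excitation.wav --capture in.wav -o tf.csv
Rscript inst/cli/nrmd remove-harmonics tf.csv -o tf_clean.csv
Rscript inst/cli/nrmd nasalance stereo.wav -o summary.json
Rscript inst/cli/nrmd compare --tf-dir tfs/ -o report/
```

## Scope

The package covers the offline signal chain only. Hardware control
(loudspeaker, horn, level calibration), real-time processing, `.wma`
decoding and connected-speech analysis are out of scope; the simulator makes
no claim of physiological fidelity (see the methods vignette).
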