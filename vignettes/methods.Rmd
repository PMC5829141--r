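---
title: "Methods: generative model and analysis decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generative model and analysis decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model behind the synthetic data,
the estimators in the analysis chain, and the numerical decisions that
determine the package's behaviour in edge cases. All analysis code
operates on the `EpochSet` container and is agnostic to whether the
epochs came from a file or a generator.

## 1. The two paradigms

The package models simultaneous multi-region local-field-potential
recordings under two stimulation paradigms:

- **Click trains** for the auditory steady-state response (ASSR): a
  40-Hz click train of 0.5 s duration per trial, epoched −0.5 to 1.0 s
  around train onset. Entrainment is quantified by mean trial power
  (MTP) and the phase-locking factor (PLF) in the 35–45 Hz band over
  50–550 ms.
- **Sound pairs** for inhibitory gating (IG): two identical sounds, a
  conditioning (C) and a test (T) stimulus 500 ms apart, epoched −3.5 to
  1.1 s around C so that a long pre-stimulus control period (−3 to −2 s)
  is available for the significance gate. Gating is quantified as the
  T/C ratio of windowed peak amplitudes.

## 2. Generative model

Each trial is the sum of a deterministic kernel and 1/f ("pink")
background noise.

**Pink noise** (`genPinkNoise`) is synthesised in the frequency domain
with amplitude ∝ f^(−1/2) (power ∝ 1/f), random phases, zero DC, and an
exact rescale to the target standard deviation. Its periodogram slope is
asserted to sit in [−1.2, −0.8] in the tests.

**Sound-pair kernels** (`pairKernel`, `genPairEpochs`) place one
negative and one positive deflection after each sound. A deflection is a
raised-cosine (Hann) bump with compact support ±12 ms, so deflections at
different latencies are exactly separable and noise-free identities hold
to machine precision. The T-sound deflections are the C deflections
scaled by the gating factors `gateN`, `gateP`; the generative T/C ratio
is therefore exactly `gateN` (negative peak) and `gateP` (positive
peak).

**Click-train kernels** (`genAssrEpochs`) are a 40-Hz sinusoid of
amplitude `assrAmp` under a 10-ms raised-cosine on/off ramp envelope,
with a per-trial phase offset drawn from N(0, `assrPhaseJitterSd`²).
Phase jitter lowers PLF without changing single-trial power, which is
what dissociates the two ASSR measures.

### Region × condition presets

`regionPresets()` returns the calibration table
(`inst/extdata/presets.tsv`). Gating factors and peak latencies are the
package's target values per cell; ASSR amplitudes were chosen during
generator design so the derived contrasts (strict AC > HP > AMY > PFC
ordering; ≥ 5× AC/PFC band-summary separation over the noise floor)
hold with margin.

| parameter | units | default | rationale |
|---|---|---|---|
| `fs` | Hz | 1000 | 1-ms resolution resolves 25–75 ms peak latencies and 40-Hz cycles |
| `nTrials` | – | 120 | typical session size; PLF chance level √π/(2√120) ≈ 0.081 |
| `noiseAmp` | µV | 30 | single-trial SNR ≈ 2 for a 60-µV deflection; realistic raw traces |
| `ampN`, `ampP` | µV | −60 / 45 conscious, −51 / 38 anesthetized | large evoked C responses; mild amplitude reduction under anesthesia |
| `width` | s | 0.012 | compact bump support; no overlap between deflection peaks |
| `latN`, `latP` | s | AC 0.025 / 0.040; HP 0.039 / 0.065; AMY 0.037 / 0.065; PFC 0.035 / 0.075 | early AC components (N25/P40), later limbic/frontal components (N35/P70) |
| `gateN`, `gateP` | – | per cell, 0.21–0.92 | generative T/C ratios; gating deepens AC → HP → AMY → PFC and is unaffected by condition beyond small shifts |
| `isi` | s | 0.5 | C–T separation |
| `assrAmp` | µV | AC 28 / 11.2; HP 10 / 4; AMY 5 / 2; PFC 0 / 0 | strict regional ordering; anesthesia reduces entrained amplitude 0.4× |
| `assrPhaseJitterSd` | rad | 0.4 conscious, 0.8 anesthetized | anesthesia degrades phase locking as well as power |
| `fStim`, `trainDur` | Hz, s | 40, 0.5 | gamma-band steady-state driver |

### What the generator does and does not emulate

Emulated: 1/f background spectra, realistic single-trial SNR,
steady-state entrainment with partial phase locking, paired-pulse
suppression with region-specific depth, condition effects on ASSR power
and phase locking, between-session variability (Section 5), continuous
recordings with event sidecars (`genContinuousSession`).

Not emulated: volume conduction or inter-regional correlation, evoked
gamma bursts other than the driven 40-Hz component, non-stationary noise
(movement, drift), harmonics of the stimulation frequency, electrode or
line-noise artefacts, and any within-trial coupling between the ASSR
and gating responses (the two paradigms are simulated independently).

## 3. Time-frequency decomposition

`morletTFR` convolves each trial with complex Morlet wavelets with a
constant 7 cycles (σ_t = nCycles / (2πf); ~11 ms temporal and ~6 Hz
spectral resolution at 40 Hz). Numerical decisions:

- **Normalisation.** The wavelet is scaled by `2 / Σ g` (g the Gaussian
  envelope) so a unit-amplitude sinusoid at `f` yields `|W| = 1` at
  every frequency; `|W|²` therefore reads out power in amplitude-squared
  input units, and MTP values compare across frequencies without a 1/f
  correction of the wavelet itself.
- **FFT convolution.** The kernel is wrapped at index 0 and multiplied
  in the frequency domain at length `nextn(n + 1)`; the tests assert
  agreement with a direct time-domain convolution oracle to a relative
  1e-6.
- **Edge handling.** Samples within half the wavelet support
  (3.5 σ_t) of either epoch boundary are set `NA` rather than being
  contaminated by zero padding; frequencies whose full support exceeds
  the epoch come back entirely `NA`. `bandWindowMean` averages valid
  cells only and errors if the rectangle is empty or all-`NA`.
- **PLF degeneracies.** PLF requires ≥ 2 trials; a zero-magnitude
  coefficient has undefined phase and makes the affected cell `NA`
  rather than silently contributing a zero phasor.
- `assrMaps` computes MTP and PLF by accumulation (never materialising
  the trials × freqs × times array) and is asserted identical to the
  `morletTFR` route.
- `baselineNormalize` (dB re pre-stimulus) exists for visualisation
  only; all quantitative summaries use raw power.

## 4. Peak quantification and the significance gate

`detectPeak` searches the configured window for interior local extrema
of the requested polarity (ties broken toward the earliest latency) and
falls back to the window boundary with a `boundary = TRUE` flag when no
interior extremum exists (flat or monotone waveforms). Amplitude is
measured relative to the waveform value at the sound's onset sample.

**Windowed-amplitude estimator.** `computeIG` quantifies C and T
amplitudes as the mean over ±5 ms around the detected peak latency
rather than the single extremal sample. The extremal sample of a noisy
average rides on the maximum of the local noise and is biased away from
zero; on 200 simulated null-calibration sessions this max-selection bias
inflated weak-gating T/C ratios by ≈ +0.03 (e.g. 0.31 recovered for a
generative 0.28), while the ±5 ms windowed mean was unbiased (0.282 for
0.28) and is identical to the peak value in the noise-free limit. The
same ±5 ms statistic feeds the significance test, so the tested and the
reported quantity coincide. One consequence: the AC N25 and P40
deflections are only 15 ms apart, so their ±5 ms windows pick up ≤ 0.5 %
cross-talk from the neighbouring deflection; AC noise-free identities
hold to 0.005 rather than machine precision (other regions stay exact).

**Significance gate.** `peakSignificance` compares the single-session
distribution of per-trial ±5 ms window means at the peak latency against
the same statistic computed in ±5 ms windows slid at 10-ms steps across
the −3 to −2 s control period (a Welch two-sided t-test; at least 10
control windows are required, otherwise an error). A peak is accepted at
α = 0.01; the type-I error of this gate is asserted within the binomial
95 % band around 1 % on 200 null sessions. Degenerate inputs (both
samples constant, as in noise-free simulations) short-circuit to p = 1
when the means agree and p = 0 when they differ, avoiding `t.test`'s
"data are essentially constant" error. T/C ratios are `NA` — never a
silent 0 — unless both peaks pass the gate and the C amplitude is
nonzero.

## 5. Cohort simulation and group statistics

`simulateCohort` adds two sources of between-session variability on top
of the cell presets: a per-session, per-condition jitter of the gating
factors (sd 0.2, truncated to [0, 1.5]) and a log-normal site amplitude
factor (cv 0.2) shared between the conscious and anesthetized recordings
of one session. A cohort with zero between-session variance would make
the group tests degenerate and is not a faithful emulation of chronic
multi-session recordings; the chosen magnitudes are in the range
reported for sensory-gating test–retest variability. The parameter
recovery contract and the acceptance script use the exact presets,
unjittered.

Group statistics are deliberately textbook: one-way homoskedastic ANOVA
across regions (`stats::aov`) with Tukey HSD contrasts, and two-sided
paired t-tests for the condition effect, both verified against
hand-computed sum-of-squares oracles. Guards: regions with < 2 sessions
are excluded with a warning; zero-variance inputs return F = 0, p = 1
(rather than `aov`'s unstable output); constant paired differences
return t = 0/±∞ with p = 1/0; cells whose paired test cannot run at all
(e.g. too many gated-out ratios) become an `NA` row with a warning
instead of aborting the pipeline.

**Power note.** The expectation that *no* T/C ratio shows a significant
condition effect is a joint acceptance of 8 null hypotheses at α = 0.05:
even under an exact null the probability that all 8 tests accept is at
most 0.95⁸ ≈ 0.66 per cohort, and the presets carry real condition
differences of up to 0.06. This criterion is therefore inherently seed-
dependent; the test suite asserts it at one fixed cohort seed and the
realistic between-session gating variability (sd 0.2) keeps the paired
tests appropriately underpowered for those small true differences,
mirroring the empirical dissociation: anesthesia collapses the ASSR but
leaves gating statistically unchanged.

**Limitations.** No mixed-effects modelling (sessions are treated as
exchangeable units; with repeated animals a random-intercept model would
be more appropriate); no multiple-comparison correction across the four
summary measures; the ANOVA assumes homoskedasticity although regional
variances differ; EDF I/O is single-channel on the write side and 16-bit
by construction.

## 6. Problem sizes and reproducibility

Default sessions are 120 trials × 1501 samples (clicks) or 4601 samples
(pairs) at 1000 Hz; a full 80-session cohort simulates and analyses in
well under a minute. All generators take explicit seeds and restore the
caller's RNG state (`.with_seed`), so `makeSession(..., seed = s)` is
bit-reproducible and composable. File formats: bit-exact CSV
(`%.17g`), 16-bit EDF (exact to one digitisation step by construction),
TSV event sidecars with C/T pairing validation, and a versioned binary
epoch container with a bit-exact round trip.

A command-line interface over the same exported functions lives at
`inst/scripts/assrig.R` (subcommands `simulate`, `assr`, `gating`,
`stats`, `run`); `runPipeline()` writes all session summaries, gating
tables, group statistics, a human-readable report, and the resolved
`RunConfig` into an output directory.
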