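---
title: "Extracting the individual theta frequency from associative-memory EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting the individual theta frequency from associative-memory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itfx)
```

## Why a task-based theta estimate

Theta oscillations (4–8 Hz) are central to associative binding, and
frequency-personalized stimulation protocols (tACS, otDCS) need a
per-person theta frequency to tune to. Resting spectra rarely show a theta
peak, and anchoring theta to the alpha peak (IAF − 5 Hz) assumes a fixed
alpha–theta distance that need not hold. `itfx` therefore estimates the
**individual theta frequency (ITF)** directly from the EEG of *successful
associative encoding*: the frequency whose event-related power increase
dominates while memories that will later be retrieved are being formed.

Because a single time–frequency peak is noisy and its latency varies across
people, the method treats every combination of 19 overlapping post-stimulus
time windows and 6 centroparietal electrodes as a repeated measurement of the
same underlying rhythm. The ITF is the modal peak frequency across those 114
cells (restricted to theta), and the share of theta cells carrying the mode
is reported as the estimate's *reliability* — a direct, per-person index of
how well a stimulation protocol tuned to the ITF would be personalized.

## The pipeline and its assumptions

1. **Conditioning** (`highpass()`, `remove_line_noise()`): zero-phase 2nd
   order Butterworth high-pass at 0.1 Hz, and a zero-phase biquad notch with
   its zero exactly at the line frequency (−3 dB width 1 Hz), which leaves
   bands more than 2 Hz away essentially untouched (< 1 dB). A sine/cosine
   regression alternative (`method = "regression"`) suits phase-stable
   interference. Eye-artifact correction is out of scope: the generator
   produces artifact-free data and real recordings should be pre-cleaned.
2. **Epoching and labeling** (`epoch()`, `label_epochs()`): −1000…2500 ms
   epochs, time-domain baseline mean over −800…0 ms subtracted per trial and
   channel. An encoding trial is *successful* if its intact pair is later
   judged "old", *unsuccessful* if judged "recombined", *unlabeled* if never
   probed intact or without a response (omissions are excluded rather than
   counted as failures). Intervals are half-open `[a, b)` in samples, the
   onset sample counts as post-stimulus, and ms→sample conversion rounds
   half away from zero, so all window boundaries are platform-reproducible.
3. **Artifact rejection** (`reject_epochs()`): the manual screening step is
   replaced by an automated any-channel peak-to-peak criterion
   (default 150 µV) so runs are reproducible; every rejection is logged.
4. **Time–frequency decomposition** (`morlet_power()`): complex Morlet
   wavelets, 7 cycles, 1–15 Hz in 0.5 Hz steps, FFT convolution with
   reflection padding of up to half the longest wavelet. Wavelets are
   normalized to **unit peak frequency-domain gain**, so equal-amplitude
   tones give equal peak power at every frequency (a pure tone of amplitude
   *a* measures *a*²/4) and tone recovery is grid-exact. Samples closer to
   an epoch edge than half a wavelet are flagged; at 2 Hz the 7-cycle
   wavelet (3.5 s) exceeds the epoch, which is why the ERSP is reported
   from 2 Hz while decomposition runs from 1 Hz.
5. **ERSP** (`ersp()`): single-trial power is averaged over trials and
   expressed as a ratio to the mean baseline power per channel and
   frequency. The ratio is applied **after** trial averaging
   (`trial_norm = "average"`). The per-trial variant
   (`trial_norm = "single"`) is provided but not default: at the lowest
   analysis frequencies the 0.8 s baseline spans roughly one wavelet
   autocorrelation length, so a single trial's baseline mean has about one
   effective sample and the expected power/baseline ratio inflates severely
   there, while the averaged order stays near 1 (the test-suite verifies
   the latter on stationary noise). The averaged order also matches the
   ERSP definition above, in which the `1/N Σ|X|²` average is formed first.
6. **Peak matrix and extraction** (`peak_matrix()`, `extract_itf()`): per
   window × electrode cell, ERSP is averaged over the window's time points
   per frequency, and the argmax over the 2–15 Hz grid is stored (ties
   break toward the lower frequency; a max-over-samples variant is
   available via `window_stat = "max"`). The ITF is the mode of cells in
   theta `[4, 8)` — eight candidates 4.0…7.5 Hz; 8.0 Hz counts as alpha,
   matching the convention that observed ITFs range 4–7.5 Hz. Multimodal
   count distributions set `tie = TRUE` and break toward the candidate with
   the larger summed ERSP mass over its cells, then toward the lower
   frequency; all tied candidates are reported.
7. **Reliability classes** (`reliability_class()`): the printed class
   ranges are made half-open so they partition [0, 1] without gaps:
   none [0, 0.15) — below the 1-in-8 chance level —, unreliable
   [0.15, 0.30], reliable (0.30, 0.50], highly reliable (0.50, 0.80],
   singular (0.80, 1].
8. **Fallback** (`fallback_extract()`): "no prominent theta activity" is
   quantified as a theta share below 20% of cells (configurable; 0
   disables); the matrix is then rebuilt with PO7/PO8 appended. The runner
   decomposes the fallback electrodes lazily, only when triggered.
9. **Control** (`segment_resting()`, `run_control()`,
   `compare_conditions()`): eyes-open rest is cut into successive 3500 ms
   pseudo-epochs whose first second provides the baseline, so the
   identical analysis applies; per-subject theta shares are compared
   task-vs-rest with a two-sided Wilcoxon signed-rank test (the printed
   report of the reference analysis states only a significant difference,
   so a distribution-free paired test is the conservative choice).
   Identical paired samples return p = 1 by convention.

No re-referencing is applied: the reference electrode differed across
subjects in the motivating recordings and no policy is stated, so the data
are analyzed as recorded.

## What the synthetic generator emulates

`simulate_session()` produces a 20-channel, 500 Hz session of the
paired-associates design: 42 encoding pairs shown 2000 ms with ISI
1250–1750 ms, 84 recognition trials (half intact, half recombined), a hit
rate of 59.5% and correct rejections at 68.5% (typical young-adult
performance, giving the ~25 successful epochs per session the method
expects), and behavior realized exactly (counts are rounded, the successful
subset is drawn at random). The EEG is a sum of:

* **1/f background** (`noise_exponent` = 1, 10 µV RMS), synthesized
  spectrally; the realized log–log slope matches the parameter within ±0.2.
* **Posterior alpha** at 10 Hz with the classic posterior–anterior gradient
  (PO7/PO8/Oz 100%, parietal 60%, central 30%, frontal 10% of
  `alpha_amp_uv` = 6 µV) and a slow Rayleigh envelope (~1 s correlation
  time). The envelope matters: a *stationary* narrowband process varies too
  little between an epoch's baseline and analysis seconds for alpha cells
  ever to win ratio-ERSP peaks, whereas real eyes-open alpha waxes and
  wanes in second-scale episodes and dominates resting peak matrices.
* **Theta bursts** at `theta_freq_hz` on the six centroparietal channels of
  to-be-successful trials only (encoding the assumption that theta marks
  successful encoding), Hann-windowed with a random phase per trial
  (phase-variable bursts are the conservative case for power-based
  detection), onset 300 ± 50 ms (truncated to 250–350 ms) and duration
  1500 ms — sustained through the scanned 250–1250 ms window and beyond.

The burst duration deserves emphasis. A short burst does not *have* a
frequency resolvable at 0.5 Hz: a 600 ms Hann burst has ≈ 1 Hz of spectral
width, and because the wavelet bandwidth grows with frequency (σ_f = f/7)
while the baseline power falls as 1/f, the noise-free ERSP-ratio argmax of
such a burst lands half a grid step *above* the planted frequency at every
theta grid value. With the 1500 ms default the noise-free argmax is correct
at all eight grid frequencies (the parameter-recovery tests confirm
grid-exact recovery under noise). Burst amplitude is
calibrated per session against the measured background wavelet power at the
planted frequency, so the planted peak ERSP is ≈ 1 + `burst_snr`.

What the generator does **not** emulate: volume conduction and inter-channel
coherence, eye/muscle artifacts, non-stationary arousal drifts,
stimulus-evoked potentials, and any coupling between theta amplitude and
behavior beyond the successful/unsuccessful dichotomy. Passing
parameter-recovery tests therefore shows the *method* is correct and
well-calibrated, not that real recordings will be as benign; on real data
the reliability classes and the PO7/PO8 fallback do the work of flagging
weak theta.

## Numerical choices and degenerate inputs

* FFT lengths are mixed-radix (factors 2/3/5); any circular wrap falls
  inside the reflection pads plus the edge-flagged margin of the 1 Hz
  wavelet, which is excluded from the 2–15 Hz analysis grid anyway.
* Zero baseline power (e.g., an identically zero channel) is a hard error
  naming the offending channel/frequency rather than a silent Inf.
* Epochs that do not fit in the recording are kept with label `rejected`
  and all-NA data, so trial bookkeeping stays aligned with the event table.
* Band shares are computed from integer cell counts, so they sum to 100 to
  within accumulated float rounding (asserted at 1e-9).
* The amplitude-step ERSP calibration in the test-suite ends its baseline
  300 ms *before* the step: the wavelet smears a step backward by ~2 σ_t,
  so a baseline touching the step is inflated by 10–15% at any grid
  frequency and would measure the smearing, not the amplitude² scaling the
  calibration verifies.

## Validation study sizes

The test-suite validates parameter recovery at the full reference design
(42 pairs, 59.5% hit rate → ~25 successful epochs, burst SNR 3) with 50
seeded sessions per planted frequency, and the task-vs-rest contrast with 20
simulated subjects (120 s of rest each). `scripts/acceptance.R` re-runs the
same studies at 6 seeds per frequency and 12 subjects; both sizes are the
package's choices for routine verification, and the helper functions accept
any `n_pairs`/`duration_s` for larger studies.

## Known limitations

* Grid-exact recovery degrades when bursts are genuinely short (< 1 s):
  that is an uncertainty-principle property of the estimand, not an
  implementation artifact, and it will affect real data whose theta
  episodes are brief.
* The reliability share is only meaningful with a reasonable number of
  theta cells; with very few theta cells the mode share is inflated by
  construction. The theta band share and the fallback trigger should be
  read together with the class.
* The resting control inherits edge effects from its 3500 ms pseudo-epochs:
  at alpha frequencies the last ~0.4 s of each pseudo-epoch lies within
  half a wavelet of the epoch edge. The `edge` flags in `eeg_tfr`/`eeg_ersp`
  mark the affected samples.
* EDF support covers continuous recordings with one sampling rate;
  annotation channels are skipped, not parsed.
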