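---
title: "Methods: auditory evoked-response analysis for ear-EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditory evoked-response analysis for ear-EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(earpipe)
```

earpipe implements the analysis chains used to validate ear-centered EEG
acquisition with auditory paradigms: detection of the auditory steady-state
response (ASSR) evoked by an amplitude-modulated tone, measurement of the
P300 event-related potential (ERP) in a two-tone oddball task, and scoring
and comparison of bipolar comfort questionnaires. Because validation studies
of wearable EEG rarely deposit raw recordings, the package ships a
synthetic-data generator that reproduces the statistical structure these
analyses assume, so every stage is exercised and tested end to end against
known ground truth.

## Stimuli

The ASSR stimulus is a sinusoidal carrier at $f_c$ multiplied by a raised
sinusoidal envelope at the modulation rate $f_m$:

$$y(t) = A \sin(2\pi f_c t)\,\frac{\sin(2\pi f_m t) + 1}{2},$$

i.e. 100% amplitude modulation. The product-to-sum identity gives a
three-line spectrum at $f_c - f_m$, $f_c$ and $f_c + f_m$, which the tests
verify together with Parseval's identity on an integer number of modulation
cycles. Defaults follow common audiometric practice: $f_c = 1000$ Hz,
$f_m = 41$ Hz (a 41 Hz envelope completes a whole number of cycles per
1000 ms analysis epoch, so the response falls on an exact FFT bin).
Stimulus waveforms are synthesized at 16 kHz; the generation rate is a
config default, not a claim about any particular hardware.

Oddball tones are gated sinusoids with raised-cosine (Hann) onset/offset
ramps — the standard audiological gating — with 9.9 ms ramps and a 50 ms
plateau (69.8 ms total) by default. The oddball schedule has 40 sequences
of 10 tones, exactly one target per sequence at a position drawn uniformly
from {7, 8, 9, 10}, a 2 s interstimulus interval and a 4 s intersequence
interval. Intervals are interpreted offset-to-next-onset; the
interpretation is centralized in `generate_oddball_schedule()` so it can be
switched if a recording used onset-to-onset timing.

## Synthetic recordings

`simulate_background()` builds each channel as a sum of

* broadband $1/f$ noise, synthesized by spectral shaping of white noise
  with seeded phases (exact control of the spectral exponent; default
  exponent 1, RMS 20 uV),
* a narrowband alpha rhythm with slow amplitude waxing/waning (10 Hz,
  5 uV RMS), and
* a power-line component (60 Hz, 2 uV RMS).

Channels share a configurable common-source fraction (default 0.3) to mimic
nearby electrodes seeing the same cortical activity. ERP deflections are
Gaussian in time — a two-parameter shape that suffices for amplitude and
latency recovery testing — and project onto the channels through a gain
profile (default 0.7/1.0/1.3, averaging one) because cortical generators
reach different electrodes with different strengths and with a topography
distinct from ocular artifacts. Blinks are large half-sine-squared
transients (200 uV, 250 ms, 2/min) with a fixed signed mixing vector
(1 to −0.4 across channels): with a referenced ear montage the ocular
dipole projects with opposite polarity on derivations on either side of its
zero line, and this signed topography is what makes blink components
separable from the all-positive ERP topography at only three channels.
Muscle bursts are 20–45 Hz band-limited noise epochs (30 uV RMS, 1/min).
Every inserted artifact is logged, so rejection sensitivity and specificity
are computable exactly downstream.

What the generator does *not* emulate: volume conduction and electrode
geometry, impedance drift, non-stationary background spectra, and real
blink waveform variability. Passing tests therefore demonstrate that the
pipeline recovers what it is designed to recover under its stated
assumptions, not that any particular hardware meets a performance bar.

The default oddball scenario mirrors the validation study's design: three
exploring channels (reference subtraction assumed already applied) at
1000 Hz, the 40-sequence schedule above with a 2 s pre-roll and tail, a
P300-like positivity on targets (24 uV, 400 ms, 60 ms Gaussian SD, 10 ms
latency jitter) and a small early negativity on every tone (−8 uV at
100 ms). The jitter default deserves a note: the measurement chain has a
deterministic gain below one (high-pass transition ~0.93, 9-tap smoothing
~0.94, blink-projection removal ~0.95), and trial-to-trial latency jitter
multiplies this by $\sigma/\sqrt{\sigma^2 + j^2}$; 10 ms keeps the
recovered grand-average peak within the ±20% recovery band that defines
the scenario's calibration while remaining plausible for a strongly
attended two-tone discrimination.

## ASSR chain

`run_assr()` applies, in order:

1. **Zero-phase FIR band-pass**, 0.1–500 Hz by default. At a 1000 Hz
   acquisition rate the upper edge sits at Nyquist, so the filter
   degenerates to the high-pass alone (a 500 Hz low-pass at 1 kHz sampling
   is a no-op; anti-aliasing is the acquisition hardware's job). High-pass
   kernels are designed by spectral inversion — a unit impulse minus a
   unit-DC-gain windowed-sinc low-pass — which pins the DC gain to exactly
   zero at any order. All filtering is single-pass FFT convolution with the
   symmetric kernel's group delay compensated exactly, i.e. zero net phase.
2. **Settle trim**: `max(order, fs)` samples are discarded at each end
   before segmentation, removing edge transients deterministically.
3. **Sweep extraction**: six contiguous, non-overlapping sweeps of sixteen
   1000-point epochs each. Epochs are not stimulus-locked: the response is
   steady-state and 41 Hz completes whole cycles per 1000 ms epoch, so
   phase alignment is automatic.
4. **Time-domain averaging, then FFT**: the six sweeps are averaged
   pointwise and the mean sweep transformed with a rectangular-window FFT
   (one-sided power in uV², resolution `fs / sweep_length` = 1/16 Hz).
   Averaging sweeps rather than the 96 epochs keeps the finer resolution;
   both interpretations put 41 Hz on an exact bin.
5. **SNR**: target-bin power over the mean of ±60 neighboring bins
   excluding ±2 guard bins (and the target itself). This neighbor-bin
   convention is the common ASSR detection statistic; the neighborhood and
   guard widths are exposed in the interface. A zero noise floor reports
   `Inf` rather than erroring, so noise-free probes behave predictably.

Property tests confirm SNR monotonicity in injected amplitude and
rate-invariance: simulating the same scenario at 1000 and 4000 Hz with
matched duration and spectral resolution changes the mean 41 Hz SNR by
less than 1 dB over 20 seeds.

## ERP chain

`run_erp_participant()` chains:

1. **High-pass 0.1 Hz → resample to 128 Hz → low-pass 30 Hz**, all
   zero-phase FIR so component latencies are preserved. The high-pass
   order (500) is interpreted at the 128 Hz analysis rate and the kernel
   length scaled to the acquisition rate: an order-500 kernel at 128 Hz
   spans 3.9 s and realizes a genuine 0.1 Hz cutoff, whereas the same tap
   count at 1000 Hz spans 0.5 s, smears the transition across 0–4 Hz and
   eats a large fraction of any slow ERP component — a physical
   impossibility the design resolves in favor of the filter doing its
   nominal job. Resampling is an anti-alias low-pass at 0.8× the new
   Nyquist followed by interpolation onto the uniform 128 Hz grid
   (`floor(n·128/fs)` output samples).
2. **ICA blink removal** on the continuous 128 Hz data (continuous rather
   than epoched, so the decomposition sees whole blinks): fixed-point
   negentropy maximization with tanh contrast, PCA whitening, symmetric
   decorrelation and a seeded initial rotation. Blink-component
   identification was a manual step in practice; it is automated as the
   component with the largest 0.5–4 Hz power fraction among components
   with excess kurtosis ≥ 2 and band fraction ≥ 0.4 (blinks are sparse,
   slow and large; the whitened component keeps a broadband floor, hence
   the moderate fraction threshold). The pick can be overridden with an
   explicit component index, and when no component qualifies the data pass
   through untouched.
3. **Epoching** from −500 to 1000 ms around each event (192 samples at
   128 Hz; the onset sample opens the post-stimulus segment) and **baseline
   correction** over the closed-open window [−500, 0) ms. Events whose
   window exceeds the recording are dropped and counted.
4. **Statistical rejection**: the joint-probability criterion scores each
   epoch's mean log-likelihood under the empirical per-channel amplitude
   density (a 100-bin histogram over all epochs pooled — the density
   estimator is a design choice, as only the criterion itself is
   standard), and the kurtosis criterion scores each epoch's excess
   kurtosis; both are z-scored across epochs, per channel and pooled, and
   an epoch is rejected when any |z| exceeds 3 SD. Rejection runs after
   ICA, matching the published order of operations.
5. **Smoothing**: a zero-phase moving-average FIR. "Order 8" is ambiguous
   between 8 and 9 taps; 9 taps (a symmetric order-8 FIR) is adopted so
   the kernel has a center tap and exactly zero phase.
6. **Averaging**: kept epochs are averaged by condition and across
   channels per participant; participants with fewer than two active
   channels are excluded; the grand average is the unweighted mean across
   participants; the difference wave is target minus standard, pointwise;
   the P300 is the difference-wave maximum in 250–600 ms, ties to the
   earliest sample.

## Comfort scoring and statistics

Seven bipolar 1–7 scales with alternating direction: marks on lines 2, 4, 6
map to themselves, lines 1, 3, 5, 7 map $m \mapsto 8 - m$ (an involution),
and the comfort index is the sum, 7 (worst) to 49 (best).

Noninferiority of device A against device B with margin $\varepsilon$
tests $H_0: \mu_A - \mu_B \le -\varepsilon$ with the one-sided two-sample
statistic $t = (\bar{x}_A - \bar{x}_B + \varepsilon)/SE$; nonsuperiority
mirrors it at $+\varepsilon$. The margin convention $\varepsilon = \sigma$
uses the pooled two-sample SD — the study reported only "a margin of one
sigma", so pooled-vs-per-group is a design choice, exposed in the
interface, and the unpaired form matches the "two-sample" label. The
pooled-variance t is the default throughout, with Welch available.

The Friedman rank sum test uses within-subject midranks with the standard
tie correction $C = 1 - \sum (t^3 - t) / (nk(k^2-1))$; the base-R
implementation applies no tie correction, so the statistic is computed
in-package and cross-checked against `stats::friedman.test()` on tie-free
data, where the two coincide exactly. At $k = 2$ the statistic reduces to
$(2m - n)^2/n$ with $m$ the number of subjects preferring one treatment —
a sign test — and its null rejection rate at the $\chi^2_1$ 5% critical
value is the exact binomial tail mass 22/1024 ≈ 0.0215, conservative by
discreteness; the calibration test asserts the Monte-Carlo rate against
that enumerated value rather than against a nominal 5%.

## Numerical choices and edge cases

* Sample counts are `round(duration · fs)`; time axes start at 0 with
  $t = n/f_s$; event onsets map to the nearest sample (half up); sample
  indices are 0-based in documentation, 1-based in R code.
* Seconds in schedules, milliseconds in ERP windows; conversions happen at
  the interfaces, not inside algorithms.
* Every stochastic operation takes one integer seed (R's default
  Mersenne–Twister), restores the session RNG state afterwards, and derives
  sub-seeds arithmetically so composed simulations stay reproducible.
* Degenerate inputs error loudly rather than degrade: one-sample-short
  sweep extraction, zero pooled variance with a nonzero margin,
  rank-deficient ICA input, epochs fewer than eight for rejection,
  recordings outside the declared EDF physical range.
* EDF I/O is implemented directly (fixed-layout ASCII header, 16-bit
  little-endian records, linear physical/digital mapping, 1 s records);
  text recordings use a `# fs=<Hz>` header and are lossless.

## Problem sizes used in tests

The test suite and the acceptance script run the full study scale — 8
participants × 40 sequences per study, 20 independent studies for the ERP
chain; 98 s single-channel recordings for ASSR properties (10 seeds × 4
amplitudes for monotonicity, 20 seeds × 2 rates for rate invariance);
10,000 replicates for type-I calibration — chosen to hold Monte-Carlo
error well below each tolerance they are checked against.

## Known limitations

* With three channels the ICA model is overcomplete for the true source
  count; blink removal necessarily projects out a one-dimensional channel
  subspace, and a few percent of ERP amplitude overlapping that subspace
  goes with it. The measured grand-average recovery gain is ~0.83 overall.
* The probability/kurtosis z-scores use non-robust means and SDs across
  epochs (as the standard criterion does); at contamination rates far
  above ~15% the thresholds would need revisiting.
* The neighbor-bin SNR is a detection statistic, not a calibrated
  amplitude estimate; phase-coherence and Hotelling-T² detection are out
  of scope.
* Comfort statistics treat devices as independent groups; a paired design
  (each participant wearing both devices) would be more powerful but the
  unpaired two-sample form is what is implemented and documented.
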