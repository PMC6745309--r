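---
title: "TEP network profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TEP network profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepnet)
```

This vignette documents the scientific model behind `tepnet`, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The evoked-response model

A single TMS pulse over left M1 (hub electrode C3) evokes a stereotyped
deflection sequence. `tepnet` models and measures four canonical
components — N45, P60, N100, P180 — as sign-constrained extrema inside
literature-conventional search windows (ms, half-open):

| component | polarity | window |
|---|---|---|
| N45 | − | [30, 57) |
| P60 | + | [50, 80) |
| N100 | − | [80, 140) |
| P180 | + | [140, 250) |

From the detected peaks the pipeline computes the early slope
(P60→N100) and late slope (N100→P180) as plain finite differences of
the peak coordinates (µV/ms, no smoothing), their ratio (late/early),
and the charge transfer Q, defined here as the *rectified* trapezoidal
area of the evoked response over 15–300 ms. The 15 ms start excludes
pulse-artifact-interpolated samples; 300 ms is the conventional end of
the TEP. Rectification makes Q additive over window partitions and
polarity-invariant; a signed area would nearly cancel for a biphasic
response.

A peak is only flagged `found` when a sign-consistent local extremum
exists **and** exceeds 3× the evoked pre-stimulus RMS. Without the floor
criterion any noisy evoked — including sham — contains sign-consistent
noise extrema, and "no detectable component" would be unreportable. The
multiplier is exposed (`snr_threshold`, 0 disables).

## Input/output recruitment

The evoked feature (Q by default, peak-to-peak optionally) as a function
of stimulation intensity I (% of maximal stimulator output) is fitted
with the Boltzmann sigmoid standard for TMS recruitment,

$$f(I) = \mathrm{floor} + \frac{\mathrm{span}}{1 + e^{-(I - I_{50})/k}},$$

by an exhaustive grid over $(I_{50}, k)$ — with floor and span solved
linearly at each grid point — followed by Nelder–Mead refinement from the
best grid point. The grid-first scheme makes the fit deterministic and
initialization-independent. A feature that is flat across intensities is
reported as a flat curve (span 0) rather than a saturated sigmoid of
arbitrary span, and fewer than 4 distinct intensity levels skips the fit
with a flag.

## Connectivity

Connectivity is the pairwise Pearson correlation between channel evoked
waveforms restricted to 15–300 ms, computed on each subject's averaged
single-pulse evoked response. Region-level matrices average r over all
cross pairs of the two region-role groups (diagonals: within-group
off-diagonal pairs). Group averaging goes through the Fisher
z-transform, since averaging r directly is biased toward zero; an entry
undefined for any subject (zero-variance channel) stays missing, never
imputed as 0. Group contrasts use unpaired two-sample tests on the
subject-level Fisher-z values, uncorrected by default (Benjamini–
Hochberg optional) — matching the single-comparison reporting style
common in this literature.

## Short-term plasticity

Frequency-patterned stimulation modulates the evoked response. Trials
are classed by train frequency: baseline ≤ 0.5 Hz, inhibitory 1–5 Hz,
excitatory ≥ 20 Hz (closed intervals, config-exposed). STP features are
protocol/baseline ratios of Q and of the late slope, plus their
quotient:

$$\mathrm{STP}_Q = \frac{Q_\mathrm{proto}}{Q_\mathrm{base}}, \quad
  \mathrm{STP}_\mathrm{slope} =
  \frac{\mathrm{late}_\mathrm{proto}}{\mathrm{late}_\mathrm{base}}, \quad
  \mathrm{STP}_\mathrm{ratio} =
  \mathrm{STP}_Q / \mathrm{STP}_\mathrm{slope}.$$

A value of 1 means no modulation. One deliberate asymmetry: when
locating peaks on the *protocol* response, the detector runs
sign-agnostically (largest-magnitude local extremum per window). The
reason is physiological: in the healthy brain the inhibitory protocol
reverses the polarity of the late segment, so the healthy
$\mathrm{STP}_\mathrm{slope}$ is *negative*; insisting on canonical
polarity there would misread the reversal as a detection failure. The
loss of this reversal — positive late-slope STP — is precisely the
abnormal-aging signature, and the demonstration classifier labels a
profile abnormal when the median late-slope STP sign across the 8
region-roles is positive. This rule is a minimal formalization of a
binary step-function observation; it is a demonstration, not a clinical
device.

The baseline evoked used for STP is matched in intensity to the train
intensity (default 45–55 % MSO window around the 50 % trains), so the
ratio is not confounded by recruitment.

## Preprocessing defaults

All defaults are config keys (`default_config()`), chosen where the
underlying methodology leaves them open:

- **Pulse artifact**: samples in (−2, +10) ms around each pulse replaced
  by a natural cubic spline through 5 flanking samples per side — the
  simplest scheme that is exact for locally linear signals and cannot
  ring. Overlapping windows merge with a warning. The operation is
  idempotent.
- **Filtering**: zero-phase Butterworth — low-pass 80 Hz (order 4) at
  the acquisition rate, resampling 5 kHz → 1 kHz by decimation of the
  already-band-limited signal, then high-pass 1 Hz (order 2) and a
  48–52 Hz band-stop notch (EU line frequency). 1–80 Hz preserves N45
  morphology while removing drift and line noise.
- **Epochs**: −500…+500 ms around the pulse, baseline −300…−50 ms
  (ending before any pre-pulse coil-click leakage), per-trial per-channel
  baseline mean subtracted. Windows are half-open `[start, end)`; the
  pulse is at 0 ms.
- **Rejection**: any post-artifact |sample| > 150 µV, or channel
  peak-to-peak < 0.1 µV, drops the trial. Subjects retaining < 50 % of
  trials fail QC with a structured error.

## The synthetic cohort generator

The generator emulates the acquisition protocol (420 pulses: 8 intensity
levels × 25 single pulses at 0.5 Hz, a 110-pulse 2 Hz inhibitory train
and a 110-pulse 20 Hz excitatory train at 50 % MSO; 5 kHz reference
sampling, ±16.384 mV 16-bit range) and the evoked structure: Gaussian
components at 45/60/100/180 ms with widths 8/8/15/25 ms and hub
amplitudes (−3, +4, −8, +5) µV, scaled by a logistic recruitment of the
stimulation intensity, by distance-based spatial attenuation from the
hub (contralateral transfer 0.7), and by protocol-class modulation.
Background noise is a seeded mixture of 1/f and white noise plus 50 Hz
line; each pulse adds a decaying-exponential artifact transient and
lognormal trial-to-trial amplitude jitter. The 2 Hz inhibitory rate sits
inside the 1–5 Hz class while keeping successive train responses outside
each other's 15–300 ms analysis window; 20 Hz trains overlap by nature
and their features are not used in the default profile.

Interhemispheric coherence c ∈ [0, 1] mixes the mirrored hub waveform
with a subject-specific "private" shape on contralateral electrodes:
r(left, right) = 1 at c = 1 and decreases monotonically as c falls. The
contralateral latency shift defaults to 0 ms so that full coherence
yields exactly affine homologous waveforms.

Phenotypes (`young`, `adult`, `elderly`, `md`) encode the qualitative
group directions — amplitude and coherence decline with age; inhibitory
modulation scales N45/P60 by $m_q$ and N100/P180 by a signed
$m_\mathrm{slope}$ ($-0.75$ young … $+0.6$ MD, the sign reversal being
the MD marker). With $|m_\mathrm{slope}| = m_q$ the injected
$\mathrm{STP}_Q$ equals $m_q$ up to Gaussian-overlap cross terms
(verified < 5 % at zero noise). The numeric values of the phenotype
tables are calibration constants invented for the simulator: the source
methodology reports directions of effects, not effect sizes, so
parameter-recovery tests validate the pipeline, not any clinical claim.
What the generator does **not** emulate: biophysical conduction,
realistic head-model topographies, ocular/muscle artifacts beyond the
amplitude-rejection regime, or session-level drifts.

## Problem sizes used in validation

The packaged tests and the acceptance script use: 20 random composites
for the quadrature and argmax oracles; 200 simulated channels at
trial-SNR 5 with 40-trial averages for peak recovery (with the
pipeline's 80 Hz band limit applied); 100 seeded runs for STP recovery;
5 coherence levels × 20 replicates × 3 subjects for connectivity
monotonicity; 10 + 10 subjects for the classifier; 200 runs of an n = 30
test-retest design with a 9:1 variance ratio (expected r = 0.9 by the
attenuation formula); 2000 null replicates for ANOVA type-I calibration;
and one full 4-group × 5-subject cohort (420 pulses each, simulated at
1 kHz) run end to end through the command layer. These sizes keep the
whole validation on one CPU while leaving the binomial acceptance bands
(e.g. ≥ 95 % of 200) statistically meaningful.

## Known limitations

- Peak `found` flags depend on the pre-stimulus noise estimate; evoked
  objects without pre-stimulus samples skip the floor criterion.
- The sign-rule classifier is intentionally primitive — no training, no
  probabilities — and inherits the simulator's idealized separation.
- EDF support is read-only and continuous-recording only; stimulation
  metadata require the BrainVision marker convention
  (`S<intensity>/<frequency>/B<block>`).
- Excitatory-train (≥ 20 Hz) features are computed but overlap-
  contaminated by construction; they are excluded from the default
  profile.
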