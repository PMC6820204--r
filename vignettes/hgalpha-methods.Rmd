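---
title: "Methods: alpha and high-gamma analysis across auditory cortical fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha and high-gamma analysis across auditory cortical fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hgalpha)
```

## The scientific problem

Primary auditory cortex on posteromedial Heschl's gyrus (pmHG) and the
non-primary field on the anterolateral gyrus (alHG) cannot be separated by
anatomy alone in individual brains, but they have distinct physiological
signatures. pmHG phase-locks to fast click trains and produces
short-latency evoked potentials and strong stimulus-driven high-gamma
(70–150 Hz) power. alHG instead carries a strong ongoing ~8 Hz ("alpha")
oscillation that is suppressed during speech listening, more so for
acoustically clear than for noise-vocoded sentences, and the suppression
weakens with distance from alHG across the superior temporal plane.
`hgalpha` implements the full analysis chain for this dissociation —
functional localization, wavelet power, aperiodic/oscillatory spectral
separation, and exact nonparametric inference — together with a synthetic
data generator that encodes the effects as ground truth so that the chain
can be validated end to end.

## The synthetic study

No public recordings exist for this paradigm, so the simulator
(`simulation_params()`, `simulate_dataset()`) is a first-class component.
Per hemisphere it draws contact positions in a simplified 3-D frame (two
clusters along a gyrus axis plus scattered lateral contacts — only
inter-contact distances enter any analysis, so no real anatomy is
modelled) and generates two experiments:

* **Click trains**: 160 ms trains at 25–200 Hz, 50 trials per rate. pmHG
  contacts receive a damped biphasic kernel (~2 ms lobes, 12 ms latency)
  convolved with the click sequence — broadband enough to phase-lock at
  100–200 Hz. alHG contacts receive a slow half-cosine kernel whose width
  (20 ms) nulls its spectrum near and above ~50 Hz, at 30 ms latency, so
  they lock to 25 Hz trains but fail both pmHG criteria.
* **Sentences**: epochs from −1.5 to 6.3 s around onset at 2000 Hz, with
  per-trial durations uniform on [1.223, 4.703] s (the range of the emulated
  sentence set) and conditions clear/vocoded interleaved. Every contact
  carries a `1/f^χ` background (χ = 2) and an 8 Hz oscillator whose
  amplitude is multiplied by `1 − s·exp(−d/λ)·ramp(t)`; the ramp rises
  linearly over the first 0.5 s, holds until sentence offset, and releases
  within 0.1 s. Suppression applies multiplicatively to the oscillator's
  amplitude (an ongoing rhythm being damped), not additively to power.
  pmHG contacts add band-limited 70–150 Hz noise gated by the sentence.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `chi` | 2 | typical cortical LFP aperiodic exponent; recovered by the spectral module within ±0.15 |
| `alpha_freq` | 8 Hz | centre of the 7–10 Hz analysis band |
| `alpha_amp_alHG` / `alpha_amp_pmHG` | 6 / 0.8 | alHG ≫ pmHG; alHG alpha dominates the band so measured dB suppression tracks `20·log10(1−s)` |
| `suppression_clear` / `suppression_vocoded` | 0.6 / 0.4 | clear > vocoded, the condition effect under test |
| `spatial_decay_lambda` | 20 mm | places visible decay across the 0–40 mm contact range |
| `n_hemispheres` | 8 | the paradigm's group size; makes W = 0 give p = 2/256 |
| `n_pm`, `n_al`, `n_other` | 5, 5, 8 | close to the per-hemisphere averages of the emulated cohort's 39/36/162 totals, with lateral coverage thinned — regional statistics average contacts within hemisphere first, so per-hemisphere counts beyond a handful add little |
| `n_trials_per_condition` | 30 | trial-averaged power is stable well below the paradigm's ~55–60 usable trials per condition; hemispheres, not trials, are the unit of inference |
| `sample_rate` | 2000 Hz | acquisition rate, downsampled to 1000 Hz in preprocessing |

Per-hemisphere and per-contact lognormal jitters (SD 0.12 / 0.10) make the
paired differences vary across hemispheres while preserving their sign,
which is what yields the one-sided-extreme signed-rank configurations.

What the generator does *not* emulate: evoked low-frequency transients,
line noise and artifacts, non-stationary alpha bursting, tonic regional
differences in high-gamma baseline, electrode referencing effects, or any
real anatomy. Passing tests therefore show the *analysis chain* is
correct and sensitive under the stated signal model — not that real
recordings would behave this way.

## Preprocessing

Line noise is removed by spectrum interpolation: DFT magnitudes within
±1 Hz of 60, 120 and 180 Hz are replaced by the mean magnitude of the
1–3 Hz flanks, phases kept, Hermitian symmetry preserved. (Demodulated-band-transform line filters used with such recordings are
not fully specified for re-implementation; an interpolating notch meets
the contract the downstream analysis needs — ≥ 20 dB at the line bins,
< 1 dB in the passband.)
Resampling is Fourier-domain spectrum truncation, which is linear, exactly
amplitude-preserving for in-band components, and handles the 2034.5 →
1000 Hz acquisition ratio without rational approximation. `signal`'s
polyphase resampler was measured at ~2.5% passband ripple on a 10 Hz tone,
violating the 1% amplitude contract, hence the in-package implementation.
Epochs are half-open `[start, stop)` on the sample grid with the onset
sample at t = 0, so adjacent epochs tile a recording without
double-counting.

## Functional localization

ITPC is computed over 0–0.2 s (the click-train window) with a Hann taper,
zero-padded to 1 Hz bins so that every click rate falls on an exact bin.
The surrogate chance level phase-randomizes each trial's segment
(amplitudes and Hermitian symmetry preserved), recomputes ITPC, and
averages 100 repetitions; the surrogate SD is kept. A contact is pmHG iff
its 100 Hz ITPC exceeds the surrogate mean by 3 SDs **and** its averaged
evoked potential crosses 3 prestimulus-SDs within 0–20 ms. Both "3 SD"
thresholds are package choices (the field's criteria are qualitative);
3 SD is conservative for 100 surrogates, and the criterion can be relaxed
to any of {100, 125, 150} Hz via `localization_config(rates = ...)`.
Contacts off the gyrus are never classified, and nothing downstream of the
simulator ever reads ground-truth zone labels — all regional statistics
use the localization output.

## Wavelet power

Morlet wavelets with cycles rising linearly 3→12 across 2–30 Hz (0.2 Hz
steps) and fixed at 12 across 40–180 Hz (1 Hz steps); coefficients are
evaluated on a 10 ms grid aligned so t = 0 is a grid point, over −0.6 to
1.2 s; power is the squared magnitude averaged across trials, then
converted to dB against the mean power in −0.6 to −0.1 s (trial averaging
precedes the dB transform; the inverse transform is exact and tested).
Window and band selections include both grid endpoints: 7–10 Hz selects 16
bins, 0.5–1.2 s selects 71 time points.

Numerically, each band is convolved at a reduced internal rate (100 Hz for
the low band, 500 Hz for the high band at a 1000 Hz input) after
band-limited spectrum-truncation resampling of the trimmed epoch segment.
Because the resampling is exact for in-band components this changes
nothing but the cost; wavelets are normalized so that coefficient power is
invariant to the internal rate (for white noise, mean |c|² is flat across
all frequencies of both bands, which the tests check). Wavelet support is
truncated at ±3.5 temporal SDs; epochs must cover the analysis window plus
this support, otherwise the offending frequency is named in an error.

The offset-locked analysis re-epochs each trial around its sentence
offset, computes the 7–10 Hz band only, baselines against 0.1–0.6 s
post-offset and averages −1.2 to −0.5 s pre-offset; trials shorter than
1.2 s are excluded with a warning.

## Spectral decomposition

Windowed spectra are Hann-tapered trial-averaged periodograms, PSD-scaled
(taper energy compensated) and zero-padded to a common 0.5 Hz grid so the
−0.6..−0.1 s and 0.5..1.2 s windows are comparable despite different
lengths. The aperiodic component is an OLS fit of log10 power on log10
frequency over 2–30 Hz; whitening divides by the fitted power law, so an
exact power law maps to 1 and oscillations appear as peaks above 1.
Division (a ratio convention) was chosen over log-subtraction for the
whitened display; the two differ only by the scale on which "residual
power" is read, and the narrowband statistic is the mean whitened value
over 7–10 Hz either way. The alpha peak is *not* excluded from the slope
fit by default; `fit_one_over_f(..., exclude = c(6, 12))` provides the
sensitivity analysis. Two known biases are documented by tests rather
than hidden: a strong alpha peak tilts the unexcluded OLS slope, and
short (0.5–0.7 s) Hann windows over a steep 1/f leave a modest downward
leakage bias in the whitened level. `spectral_dissociation_demo()`
constructs the two single-dissociation scenarios — a pure tilt
(backgrounds pivot-matched at 8 Hz so only the exponent changes) moving
the slope but not whitened alpha, and a pure oscillator gain change doing
the opposite — which is the logic that licenses interpreting the regional
alpha suppression as a genuine narrowband change rather than a slope
artifact.

## Inference

`exact_signed_rank()` ranks |differences| (average ranks on ties), takes
W as the smaller signed rank sum, and computes the two-sided p as
`2·P(W_null ≤ W)` from the exact null distribution built by
dynamic-programming convolution over sign flips — equivalent to
enumerating all 2^N assignments, and cross-checked in the tests against
both `psignrank` and a brute-force enumerator. Zero differences are
dropped with a warning; enumeration is limited to N ≤ 20. This two-sided
convention reproduces, at N = 8, the discrete quantiles
2/256, 4/256, 6/256, 10/256, 38/256, 190/256, 216/256 — i.e. 0.008,
0.016, 0.023, 0.039, 0.148, 0.742, 0.844 after rounding.

`r_equivalent()` converts the one-tailed p to a t quantile with N − 1
degrees of freedom and returns `sqrt(t²/(t²+df))`. With the exact
(unrounded) p this gives r_e = 0.812 for W = 0 at N = 8. Other df conventions exist in the literature and published r-equivalent
values are not always mutually consistent under a single formula, so r_e
comparisons should be read with a ±0.02–0.04 margin.

FDR control is Benjamini–Hochberg step-up via `p.adjust`. Note the
boundary behaviour: in the set {0.004, 0.02, 0.03, 0.05} at q = 0.05 all
four tests pass, because the largest p sits exactly on its threshold
iq/m and step-up admits everything below the largest admissible rank.
Trial-label permutation tests use the difference of group means with
`p = (1 + #{|perm| ≥ |obs|})/(n_perm + 1)`; constant data return p = 1
with a warning. The distance-decay analysis fits per-hemisphere OLS of
contact alpha dB on Euclidean distance to that hemisphere's *assigned*
alHG centroid and tests the slopes against zero with the exact
signed-rank test; hemispheres with fewer than 3 usable contacts are
excluded, and exactly-zero slopes (a degenerate input) short-circuit to
p = 1.

## Pipeline and reproducibility

`run_full_analysis()` chains simulate → preprocess → localize → wavelet →
spectral → inference per hemisphere, then runs the group tests: regional
alpha and high-gamma contrasts (baselined and raw, onset- and
offset-locked), clear vs vocoded in each region, the stimulus-by-region
interaction contrast `(alHG_clear − alHG_voc) − (pmHG_clear − pmHG_voc)`,
spectral slope and whitened-alpha pre/post contrasts, and the
distance-decay regression. All randomness flows from the single run seed
through per-hemisphere sub-seeds, so equal configs give bit-identical
outputs (tested). With the defaults the whole run takes a few minutes on
one core. CSV outputs plus a log with the seed and a config hash are
written when `output_dir` is set; the per-contact
(distance, alpha dB, high-gamma dB) table replaces any volumetric
brain-map rendering, which is visualization rather than inference.

## Limitations

* The simulator's alpha SNR at alHG is deliberately high so that dB
  suppression tracks its analytic target; real whitened alpha peaks are
  far smaller than the simulated alHG peak.
* The simulated aperiodic exponent does not itself change with the
  stimulus; the pipeline's "slope shallower during sound" effect at alHG
  arises from the suppressed alpha peak tilting the unexcluded fit. The
  dissociation demonstration covers the true-tilt case separately.
* Only the synthetic path is wired end to end; reading clinical EDF
  recordings is out of scope for this version.
* The evoked-latency detector assumes a clean prestimulus baseline; it
  will reject contacts whose baseline variance is zero (degenerate) and
  has no artifact handling.
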