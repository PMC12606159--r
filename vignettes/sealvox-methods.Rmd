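---
title: "Methods: measuring and classifying Hawaiian monk seal underwater calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring and classifying Hawaiian monk seal underwater calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealvox)
```

## Overview

`sealvox` implements an analysis pipeline for low-frequency underwater
vocalizations of Hawaiian monk seals recorded by autonomous seafloor
recorders: spectrogram-based measurement of manually boxed calls, a
rule-based call taxonomy with bout segmentation, discriminant
classification of call types with leave-one-out cross-validation, and
diel activity statistics. Because raw field recordings of this species
are not publicly deposited, the package carries a first-class synthetic
generator that emulates the statistical structure of the calls and of
the recording process; every pipeline stage is exercised end-to-end on
generated data.

This vignette records the models, the tunable parameters and their
defaults, and the numerical and design choices made where the
underlying procedure left them open.

## Spectrogram analysis

Spectrograms are one-sided power spectrograms: squared magnitudes of
Hann-windowed DFT frames, kept on a linear energy scale internally (dB
conversion is presentational only) because every percentile-energy
measurement is defined on linear energy. Defaults are an 8192-point
transform with 90% overlap on 96 kHz audio, giving a frequency
resolution of `sample_rate / n_dft` = 11.7 Hz, a Hann 3 dB filter
bandwidth of 1.44 bins = 16.9 Hz, and a hop of
`floor(8192 × 0.1)` = 819 samples = 0.0085 s. The floor convention is
used because an integer hop is required and 819.2 is not integral; the
resulting time step rounds to the conventional 0.0085 s. Frequency bins
are 0-based and labeled by their center `k × Δf`, which avoids
off-by-one ambiguity in percentile frequencies. Analysis is restricted
to a 20–1000 Hz band; out-of-band rows are zeroed (or dropped on
request).

Band-pass filtering is zero-phase (forward–backward) Butterworth
filtering, applied as a high-pass/low-pass cascade rather than a single
band-pass design: at a 96 kHz rate the 20 Hz lower edge corresponds to
a normalized frequency of 4×10⁻⁴, where a joint band-pass polynomial is
numerically ill-conditioned while separate edges are stable. Zero-phase
filtering is chosen so that group delay cannot shift selection
boundaries. The filter family and order (default 4th-order sections,
8th-order effective after the forward–backward pass) are configuration
items, not measurement definitions: the source analysis names only the
band, so the choice is documented rather than inferred. One octave
outside the passband the default attenuates by more than 40 dB.

## Selection measurements

A selection is a time–frequency box. Frames belong to a box when their
center time falls inside it; bins when their center frequency does.

* **Total duration (DUR)** comes from the annotation boundaries, never
  from energy percentiles, mirroring manual selection practice.
* **90% energy duration (DUR90)** is the central interval between the
  first frame at which the cumulative time-marginal energy reaches 5%
  and the first at which it reaches 95%. A single energetic frame gives
  a zero span.
* **Percentile frequencies (F5–F95)** use the discrete
  "first bin reaching q" convention with no interpolation; this makes
  the measures exactly reproducible and monotone in q, at the price of
  bin-width quantization (±11.7 Hz at the default resolution).
* **Bandwidths** are exact identities, `BDW90 = F95 − F5`,
  `BDW50 = F75 − F25`.
* **Peak frequency (Fpeak)** is the bin of the single maximum-energy
  cell, ties broken toward low frequency. Field software does not
  document whether it aggregates over time before taking the maximum;
  the single-cell convention is our documented choice.
* **Aggregate entropy (AE)** is the Shannon entropy, in bits, of the
  normalized energy distribution over all in-box cells. Note that this
  cell-wise convention bounds AE by log2(#cells) and yields larger
  absolute values than a frequency-marginal entropy would; AE is
  therefore comparable within this package but not numerically against
  other software's aggregate-entropy outputs. Relative ordering (tonal
  calls low, broadband calls high) is preserved either way.
* **Quick SNR (SNRNIST)** is a frame-percentile estimate standing in
  for an unpublished vendor algorithm: per-frame power in dB over 20 ms
  frames, signal level = 95th percentile of in-selection frames, noise
  level = 15th percentile of selection-plus-leading-context frames,
  SNR = difference. Frame length and both percentiles are exposed as
  arguments. With no leading context the noise pool falls back to the
  selection, with a warning. The estimate is invariant to joint scaling
  of signal and noise.
* **Harmonic counting** estimates the fundamental as the strongest peak
  of the time-aggregated in-box spectrum (or accepts a hint), then
  counts partials at integer multiples within ±1 bin. A partial is
  counted when it is within −30 dB of the strongest partial *and*
  stands at least 6 dB above the local spectral background (median of
  nearby bins). The original counts were made visually; the −30 dB
  depth reflects what a trained analyst resolves on a spectrogram (a
  fifth partial under 6 dB-per-partial decay sits at −24 dB and is
  plainly visible), and the prominence requirement is what prevents the
  smooth band-edge roll-off of a noise-band call from masquerading as a
  harmonic stack. "Harmonics present" requires at least two partials,
  so a pure tone is not harmonic.

## Call taxonomy and bouts

Labels are parsed by greedy longest-prefix matching over the eight unit
names, with repeats allowed; a label is combinational at two or more
units. Hum and Grunt are rejected as stand-alone labels because they
never occur as discrete calls, but parse freely inside combinational
labels and are excluded from the elemental repertoire count.

Rules with numeric content and their defaults:

| rule | default | note |
|---|---|---|
| Croak/Growl split | 0.5 s | strict `< 0.5` is Croak; the boundary goes to Growl |
| combinational merge gap | 0.1 s | operationalizes "no ambient noise separating them"; configurable |
| bout threshold | 3 s | strictly-less-than on silent gaps (next start − previous end) |
| measurement screening | quality 3, SNR > 10.5 dB | strict inequality; missing SNR excludes with warning |
| minimum exemplars | 5 | types with fewer measured calls leave the classification |

Adjacent calls with differing amplitude class never merge — amplitude
differences indicate different callers — and bout membership requires
two or more calls. Reported percentages round half away from zero
(one decimal in tables, integers in prose-style figures), which is the
convention that reproduces the published percentage formatting.

## Discriminant classification

Correlation pruning removes, from each parameter pair with |Pearson r|
above 0.7, the member with the larger mean absolute correlation to all
other parameters, iterating from the most correlated pair; protected
parameters (by default aggregate entropy, retained for its
classification value despite exceeding the threshold) are never
removed. Pruning is performed once on the full matrix before
cross-validation, following the original sequence; this is a mild
information leak and is documented as such.

The discriminant model takes class priors proportional to class
frequencies. This choice is not arbitrary: the published per-class
chance levels equal class proportions (e.g. 26% for the class with
102 of 394 calls), which is the frequency-prior baseline. Axes are
eigenvectors of `W⁻¹B` scaled to unit pooled within-class variance;
at most `min(K−1, p)` axes exist. Classification uses the Gaussian
shared-covariance rule, and leave-one-out cross-validation refits class
moments for every held-out row. A numerically singular pooled
covariance — possible in folds when a class has only five members —
falls back to a ridge of `1e−8 × trace(W)/p` with a warning.

Derived statistics: overall accuracy with a Clopper–Pearson exact
binomial interval; Cohen's kappa from the confusion marginals;
per-class correct-classification rates with chance levels `n_c/N`
(rounded to integer percent); variance explained per axis as eigenvalue
shares; and per-axis parameter contributions defined as normalized
absolute standardized coefficients (coefficients × pooled within-class
standard deviations, absolute, scaled to 100% per axis) — the original
"contribution" computation is unspecified, so this operationalization
is our documented choice. Welch's heteroscedastic one-way ANOVA (via
`stats::oneway.test`) tests discriminant-score separation, and
parameter stability across sites is summarized as coefficients of
variation sd/mean per (parameter, type, site) cell with medians per
parameter; cells with fewer than two values or non-positive means are
excluded with a warning. Whether the original stability analysis pooled
types is not fully specified; the per-(type, site) grouping used here
is the finest that the published description admits.

## Diel analysis

Only calls starting in the first 5 minutes of each analysed hour are
counted (half-open interval: a call at exactly hh:05:00 is outside).
Hours with no calls are zero-count windows. Hourly profiles report the
mean ± SE of window counts pooled by hour-of-day — the SE is across
windows, not across days, a choice the source presentation leaves open.
Day/night labels come from a sunrise/sunset table when supplied
(day iff sunrise ≤ t < sunset) and otherwise from the fixed
06:00–17:59 / 18:00–05:59 split; windows take the label of their start
time and twilight is not modeled. Sun times are an input table rather
than an astronomical computation, so tests ship a small fixture. The
day/night comparison is a two-sided Wilcoxon rank-sum test with tie and
continuity corrections (appropriate for zero-heavy counts; all-tied
inputs return p = 1 by convention), with Benjamini–Hochberg adjustment
across sites.

## The synthetic generator

The generator's defaults are the study conditions, not tuning knobs.
Archetypes reproduce the published per-type structure: Croak = 0.33 s
noise band centered at 230 Hz (226 Hz wide); Growl = 2.94 s noise band
at 246 Hz; Moan = 0.67 s harmonic stack with an 80 Hz fundamental and
five partials; Whoop = 0.14 s linear upsweep (150→390 Hz); Rumble =
2.21 s broadband pulsed call; Whine = a higher-frequency tonal call
with fewer harmonics. Harmonic stacks decay 6 dB per partial so the
fundamental is always the measured peak frequency. Durations are
Gaussian draws truncated (by redraw) above the 10 ms edge-ramp floor.
Combinational calls concatenate members with a 10 ms crossfade and no
silent gap, so adjacent-call merging reconstructs the label; bouts draw
intra-bout gaps strictly below 3 s.

Whole recordings place bout arrivals as an inhomogeneous Poisson
process over an hour-of-day rate profile whose default mimics the
observed diel pattern (elevated overnight, midday minimum,
late-afternoon rise). Ambient noise is pink (1/f) by default. Per-call
SNR is set on the same scale the screening measurement reports: the
call's amplitude is chosen so that its 95th-percentile 20 ms frame
power sits the target SNR above the ambient 15th-percentile frame
power. Defining generator truth on the measurement's own scale is what
lets truth-recovery tests hold within ±3 dB without bias corrections.
All draws flow through per-call derived seeds, so identical
(configuration, seed) pairs give identical output and adding a call
does not perturb the others' draws. Audio rendering is optional:
long-duration rate and diel simulations use the truth log only, since
count statistics need no waveform.

Feature matrices for classification experiments are independent
Gaussian draws of the six discriminant parameters at the published
per-class means and standard deviations, truncated at physical lower
bounds (duration > 0.01 s; frequencies, bandwidths and entropy > 0) by
resampling. Resampling truncation shifts moments slightly — for the
long-duration Growl the mean rises by about 2.5%, the truncated-normal
expectation — and tests check draws against the analytic truncated
moments. What these matrices deliberately omit: within-call parameter
correlations, site effects, non-Gaussian tails, and individual
identity. Classification results on them show that the *published
class statistics* separate the types as described (the Moan nearly
perfectly; Croak confusable with Whoop; combinational types absorbed
by their constituents); they do not show how a new field dataset would
classify.

## Numerical choices and degenerate inputs

- Empty selections (zero in-box energy) are errors, not NaNs.
- Percentile ties resolve to the lowest bin; peak-frequency ties to the
  lowest frequency.
- Constant parameter columns make Pearson correlation undefined and are
  an error naming the column.
- Expected agreement of 1 makes kappa undefined (error); an empty
  day or night group yields a "not applicable" result rather than an
  error, mirroring sites with no detections.
- A stereo WAV without an explicit channel choice is an error, so
  channel selection is always deliberate.

## Problem sizes in the test suite

Tests synthesize audio at the native 96 kHz in seconds-long clips
(single calls, 30–80 s recordings), run oracle comparisons on 6×6
random matrices, LOOCV-oracle equivalence at n ≤ 12, rate recovery on
100 h truth logs without audio, and diel power/type-I properties with
100 seeded replicates of 50-day window-count simulations (per-window
Poisson means 4 vs 2 at night/day, and 3 vs 3 under the null). These
sizes were chosen to make each statistical property decisive at
desk scale.

## Known limitations

- Selections come from files or generator truth; there is no automated
  call detector.
- The quick-SNR contract is a documented stand-in for an unpublished
  vendor algorithm; absolute SNR values are comparable within the
  package only.
- Absolute aggregate-entropy values use the cell-wise convention (see
  above).
- The published field results that depend on the original recordings
  (exact accuracy, per-site day/night means and p-values, median CVs)
  are covered by structural properties on synthetic data, not by
  numeric reproduction.
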