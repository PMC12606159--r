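# sealvox

Analysis tools for low-frequency (< 1 kHz) underwater vocalizations of
Hawaiian monk seals (*Neomonachus schauinslandi*) recorded by passive
acoustic monitoring. The package implements the full analysis chain used
to characterize a wild phocid vocal repertoire from long-duration
seafloor recordings:

- **Spectrogram measurement** — band-limited one-sided power spectrograms
  (Hann window, 8192-point DFT, 90% overlap; 11.7 Hz × 0.0085 s
  resolution at 96 kHz) and the standard selection measurements: total
  and 90% energy duration, the energy-percentile frequencies
  F5/F25/Fcenter/F75/F95, 50% and 90% bandwidths, peak frequency,
  aggregate entropy, a frame-based quick SNR estimate, and harmonic
  presence/count.
- **Call taxonomy** — six elemental call types (Croak, Growl, Moan,
  Rumble, Whoop, Whine) plus two embedded-only units (Hum, Grunt);
  greedy parsing of concatenated combinational labels (e.g.
  `MoanGrowl`); the 0.5 s Croak/Growl duration rule; merging of
  immediately adjacent calls; bout segmentation at the 3 s silence
  threshold; quality-3 / SNR > 10.5 dB screening; repertoire summary
  tables.
- **Call-type classification** — Pearson correlation pruning (|r| > 0.7,
  aggregate entropy protected), linear discriminant analysis with
  frequency priors, leave-one-out cross-validation, confusion matrices,
  exact binomial accuracy intervals, Cohen's kappa, per-class chance
  levels n_c/N, discriminant variance shares and standardized-coefficient
  contributions, Welch's heteroscedastic ANOVA on discriminant scores,
  and cross-site coefficient-of-variation stability summaries.
- **Diel activity** — first-5-minutes-per-hour subsampling, hourly
  mean ± SE profiles, sunrise/sunset (or fixed 06:00–17:59) day/night
  labeling, Wilcoxon rank-sum day/night comparisons with
  Benjamini–Hochberg adjustment across sites.
- **Synthetic data** — a seeded generator of archetypal seal calls
  (harmonic stacks, noise bands, chirps, pulsed noise at the published
  per-type durations and frequencies), combinational calls, bouts,
  whole annotated recordings with controlled SNR and diel rate
  profiles, and Gaussian feature matrices at the published class
  statistics, so every stage is testable without access to raw
  recordings.

## The statistics at the core

For a selection box `S` on a power spectrogram with cell energies
`e(f, t)`, the percentile frequency `F_q` is the center frequency of the
lowest bin at which the ascending cumulative frequency-marginal energy
reaches `q` of the in-box total; bandwidths are `BDW90 = F95 − F5` and
`BDW50 = F75 − F25`. Aggregate entropy is the Shannon entropy of the
normalized cell energies, `AE = −Σ p_i log2 p_i` with
`p_i = e_i / Σ e_j`. Classification uses Fisher's linear discriminants —
eigenvectors of `W⁻¹B` for pooled within-class covariance `W` and
between-class scatter `B` — with the Gaussian shared-covariance
assignment rule `argmax_c x'W⁻¹m_c − ½m_c'W⁻¹m_c + log π_c`, evaluated by
leave-one-out cross-validation; chance level per class is its sample
share `n_c/N`.

## Worked example

```r
library(sealvox)

## measure a synthetic Moan (tonal, 80 Hz fundamental, 5 harmonics)
cfg  <- spectrogram_config(96000)
moan <- synth_call("Moan", seed = 42)
spec <- compute_spectrogram(moan$samples, 96000, cfg)
sel  <- selection(0, moan$truth$duration, 20, 1000)
fv   <- measure_selection(spec, moan$samples, sel)
round(unlist(fv[1, c("DUR", "F5", "BDW50", "BDW90", "Fpeak", "AE")]), 2)
#>   DUR     F5  BDW50  BDW90  Fpeak     AE
#>  1.11  70.31  58.59 164.06  82.03   9.23
```

The measured peak frequency (82.0 Hz) is the 80 Hz fundamental quantized
to the nearest 11.7 Hz spectrogram bin, and the percentile frequencies
bracket the low harmonic stack.

```r
## classify the ten-type synthetic repertoire drawn at the published
## class means and standard deviations
fm  <- synth_feature_matrix(seed = 1)   # 394 calls, 10 vocal types
res <- run_classify(fm)
round(res$report$accuracy_pct, 1)       #> 66.5
round(res$report$accuracy_ci_pct, 1)    #> lower upper
                                        #>  61.6  71.1
round(res$report$kappa, 2)              #> 0.57
round(res$report$per_class_correct_pct[c("Moan", "Growl", "Whoop", "Croak")])
#>  Moan Growl Whoop Croak
#>    98    74    79    52
```

Even from class means and standard deviations alone, the synthetic
experiment reproduces the structure of the field analysis: the tonal,
low-frequency Moan is nearly perfectly separable, Growls and Whoops
classify well above their chance levels, Croaks confuse with the
similarly short Whoops, and combinational types are absorbed by their
constituent elemental classes.

```r
## repertoire reconstruction from the packaged count table
s <- summarize_repertoire(repertoire_counts())
s$grand_total                  #> 23416
s$combinational$n_detections   #> 421
s$combinational$n_types        #> 19
```

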