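#' Selection box on a spectrogram
#'
#' A time-frequency box delimiting one call, in the style of a selection
#' drawn in an acoustic annotation program.
#'
#' @param start_time,end_time Time bounds in seconds (`start_time < end_time`).
#' @param low_freq,high_freq Frequency bounds in Hz (`low_freq < high_freq`).
#' @return An object of class `selection`.
#' @export
selection <- function(start_time, end_time, low_freq = 0, high_freq = Inf) {
  stopifnot(start_time < end_time, low_freq < high_freq)
  structure(list(start_time = start_time, end_time = end_time,
                 low_freq = low_freq, high_freq = high_freq),
            class = "selection")
}

# Frame/bin indices of a selection box within a spectrogram. Frames are
# assigned by their center time; bins by their center frequency.
box_indices <- function(spec, sel) {
  frames <- which(spec$time >= sel$start_time & spec$time <= sel$end_time)
  if (length(frames) == 0) {
    # very short selections may fall between frame centers; take the nearest
    frames <- which.min(abs(spec$time - (sel$start_time + sel$end_time) / 2))
  }
  bins <- which(spec$freq >= sel$low_freq & spec$freq <= sel$high_freq)
  if (length(bins) == 0) stop("selection frequency band contains no bins")
  list(frames = frames, bins = bins)
}

box_energy <- function(spec, sel) {
  idx <- box_indices(spec, sel)
  spec$energy[idx$bins, idx$frames, drop = FALSE]
}

#' Total duration of a selection
#'
#' Duration of the complete call, taken directly from the manually placed
#' selection boundaries (not from energy percentiles).
#'
#' @param sel A [selection()].
#' @return Duration in seconds.
#' @export
total_duration <- function(sel) {
  sel$end_time - sel$start_time
}

#' Energy duration (90% duration)
#'
#' Duration of the central portion of the call containing the given
#' fraction of the in-box energy: the time between the first frame at
#' which the cumulative time-marginal energy reaches `(1 - fraction)/2`
#' of the total and the first frame at which it reaches `(1 + fraction)/2`
#' (5% and 95% for the default 90% duration).
#'
#' @param spec A spectrogram.
#' @param sel A [selection()].
#' @param fraction Central energy fraction (default 0.9).
#' @return Duration in seconds (0 when all energy lies in a single frame).
#' @export
energy_duration <- function(spec, sel, fraction = 0.9) {
  idx <- box_indices(spec, sel)
  e <- spec$energy[idx$bins, idx$frames, drop = FALSE]
  marg <- colSums(e)
  tot <- sum(marg)
  if (tot <= 0) stop("empty selection: no energy inside the box")
  cum <- cumsum(marg) / tot
  q_lo <- (1 - fraction) / 2
  q_hi <- (1 + fraction) / 2
  t <- spec$time[idx$frames]
  t[which(cum >= q_hi)[1]] - t[which(cum >= q_lo)[1]]
}

#' Energy-percentile frequency
#'
#' Center frequency of the lowest bin at which the frequency-marginal
#' cumulative energy (summed over all frames in the box, ascending
#' frequency) reaches `q` of the total. The discrete "first bin reaching
#' q" convention is used, with no interpolation between bins.
#'
#' @param spec A spectrogram.
#' @param sel A [selection()].
#' @param q Energy fraction in (0, 1).
#' @return Frequency in Hz.
#' @export
percentile_frequency <- function(spec, sel, q) {
  stopifnot(q > 0, q < 1)
  idx <- box_indices(spec, sel)
  e <- spec$energy[idx$bins, idx$frames, drop = FALSE]
  marg <- rowSums(e)
  tot <- sum(marg)
  if (tot <= 0) stop("empty selection: no energy inside the box")
  cum <- cumsum(marg) / tot
  spec$freq[idx$bins][which(cum >= q)[1]]
}

#' Occupied bandwidth from percentile frequencies
#'
#' `BDW90 = F95 - F5` and `BDW50 = F75 - F25`, computed exactly from the
#' percentile fields of a feature vector.
#'
#' @param fv A one-row feature data frame (see [measure_selection()]) or a
#'   named list with fields `F5`, `F25`, `F75`, `F95`.
#' @param which Either 90 or 50.
#' @return Bandwidth in Hz.
#' @export
bandwidth <- function(fv, which = 90) {
  if (which == 90) fv$F95 - fv$F5
  else if (which == 50) fv$F75 - fv$F25
  else stop("which must be 50 or 90")
}

#' Peak frequency
#'
#' Center frequency of the bin holding the single maximum-energy
#' time-frequency cell inside the box. Ties are broken toward the lowest
#' frequency. (The single-cell convention, rather than a peak of the
#' time-aggregated spectrum, is a documented choice.)
#'
#' @param spec A spectrogram.
#' @param sel A [selection()].
#' @return Frequency in Hz.
#' @export
peak_frequency <- function(spec, sel) {
  idx <- box_indices(spec, sel)
  e <- spec$energy[idx$bins, idx$frames, drop = FALSE]
  if (sum(e) <= 0) stop("empty selection: no energy inside the box")
  cell <- arrayInd(which.max(e), dim(e))  # which.max: first (lowest bin) on ties
  spec$freq[idx$bins][cell[1, 1]]
}

#' Aggregate entropy
#'
#' Shannon entropy, in bits, of the normalized energy distribution over
#' all time-frequency cells in the box: low for tonal calls whose energy
#' concentrates in few cells, high for broadband noisy calls. Zero-energy
#' cells contribute nothing.
#'
#' @param spec A spectrogram.
#' @param sel A [selection()].
#' @return Entropy in bits, in `[0, log2(#cells)]`.
#' @export
aggregate_entropy <- function(spec, sel) {
  e <- box_energy(spec, sel)
  tot <- sum(e)
  if (tot <= 0) stop("empty selection: no energy inside the box")
  p <- e[e > 0] / tot
  -sum(p * log2(p))
}

#' Frame-based signal-to-noise ratio estimate
#'
#' A quick frame-percentile SNR in the spirit of the screening measurement
#' used in acoustic annotation software (whose exact vendor algorithm is
#' unpublished; this contract is a documented, tunable stand-in). The
#' audio is partitioned into short frames; the per-frame power in dB is
#' computed; the signal level is a high percentile of the in-selection
#' frames and the noise level a low percentile of the frames spanning the
#' selection plus a leading context segment. The estimate is invariant to
#' joint scaling of signal and noise.
#'
#' @param samples Full waveform containing the selection.
#' @param sel A [selection()] giving time bounds within `samples`.
#' @param sample_rate Sampling rate in Hz.
#' @param frame_s Frame length in seconds (default 0.02).
#' @param signal_quantile Quantile of in-selection frame powers taken as
#'   the signal level (default 0.95).
#' @param noise_quantile Quantile of selection-plus-context frame powers
#'   taken as the noise level (default 0.15).
#' @param context_s Length of leading context before the selection used
#'   for the noise estimate; defaults to the selection duration, truncated
#'   at the start of the audio. If no context frames are available the
#'   noise level falls back to in-selection frames, with a warning.
#' @return SNR estimate in dB.
#' @export
snr_nist_quick <- function(samples, sel, sample_rate, frame_s = 0.02,
                           signal_quantile = 0.95, noise_quantile = 0.15,
                           context_s = NULL) {
  if (is.null(context_s)) context_s <- total_duration(sel)
  nf <- max(1L, as.integer(round(frame_s * sample_rate)))
  sel_a <- max(1L, as.integer(floor(sel$start_time * sample_rate)) + 1L)
  sel_b <- min(length(samples), as.integer(ceiling(sel$end_time * sample_rate)))
  ctx_a <- max(1L, sel_a - as.integer(round(context_s * sample_rate)))

  frame_power_db <- function(a, b) {
    if (b - a + 1L < nf) return(numeric(0))
    starts <- seq(a, b - nf + 1L, by = nf)
    p <- vapply(starts, function(s) mean(samples[s:(s + nf - 1L)]^2), 0)
    10 * log10(pmax(p, .Machine$double.xmin))
  }

  p_sel <- frame_power_db(sel_a, sel_b)
  if (length(p_sel) == 0) p_sel <- 10 * log10(mean(samples[sel_a:sel_b]^2))
  p_ctx <- if (ctx_a < sel_a) frame_power_db(ctx_a, sel_a - 1L) else numeric(0)
  if (length(p_ctx) == 0) {
    warning("no leading context frames; noise estimated from the selection only")
    p_noise_pool <- p_sel
  } else {
    p_noise_pool <- c(p_ctx, p_sel)
  }
  sig <- stats::quantile(p_sel, signal_quantile, names = FALSE, type = 7)
  noi <- stats::quantile(p_noise_pool, noise_quantile, names = FALSE, type = 7)
  sig - noi
}

#' Count harmonics in a selection
#'
#' Estimates the fundamental as the strongest peak of the time-aggregated
#' in-box spectrum (or uses `f0_hint`), then counts partials: spectral
#' energy within one bin of `k * f0` (k = 1, 2, ...) exceeding a relative
#' threshold (default -30 dB re the strongest partial, roughly the depth
#' a trained analyst resolves when counting harmonics on a spectrogram).
#' To be counted, a partial must also be spectrally prominent: at least
#' `prominence_db` above the local background (the median aggregate
#' energy of nearby bins), which narrow partials are and the smooth
#' roll-off of a noise band is not. Harmonic structure is deemed present
#' when at least two partials are found, so a pure tone counts one
#' partial but is not "harmonic".
#'
#' @param spec A spectrogram.
#' @param sel A [selection()].
#' @param f0_hint Optional fundamental frequency hint in Hz.
#' @param threshold_db Relative detection threshold in dB (negative).
#' @param prominence_db Minimum height of a partial above its local
#'   spectral background, in dB.
#' @return A list with `present` (logical) and `n` (partial count).
#' @export
count_harmonics <- function(spec, sel, f0_hint = NULL, threshold_db = -30,
                            prominence_db = 6) {
  idx <- box_indices(spec, sel)
  agg <- rowSums(spec$energy[idx$bins, idx$frames, drop = FALSE])
  freqs <- spec$freq[idx$bins]
  if (sum(agg) <= 0) return(list(present = FALSE, n = 0L))
  f0 <- if (is.null(f0_hint)) freqs[which.max(agg)] else f0_hint
  if (f0 <= 0) return(list(present = FALSE, n = 0L))
  df <- spec$freq_resolution

  partial_at <- function(f) {
    near <- which(abs(freqs - f) <= df)
    if (length(near) == 0) return(c(energy = 0, prominent = 0))
    e <- max(agg[near])
    center <- near[which.max(agg[near])]
    bg_idx <- setdiff(
      which(abs(seq_along(freqs) - center) <= 10),
      which(abs(seq_along(freqs) - center) <= 2))
    bg <- if (length(bg_idx) > 0) stats::median(agg[bg_idx]) else 0
    prom <- if (bg <= 0) TRUE else 10 * log10(e / bg) >= prominence_db
    c(energy = e, prominent = as.numeric(prom))
  }
  k_max <- max(1L, floor(max(freqs) / f0))
  pk <- vapply(seq_len(k_max), function(k) partial_at(k * f0), numeric(2))
  ref <- max(pk["energy", ])
  if (ref <= 0) return(list(present = FALSE, n = 0L))
  detected <- 10 * log10(pk["energy", ] / ref) > threshold_db &
    pk["prominent", ] > 0
  n <- sum(detected)
  list(present = n >= 2L, n = as.integer(n))
}

#' Measure the full feature set for one selection
#'
#' Computes the standard selection measurements: total duration (from the
#' selection boundaries), 90% energy duration, the 5/25/50/75/95%
#' energy-percentile frequencies, the 50% and 90% bandwidths, peak
#' frequency, aggregate entropy, the frame-based SNR estimate, and
#' harmonic presence/count.
#'
#' @param spec A spectrogram of (at least) the selection region.
#' @param samples Waveform the spectrogram was computed from (for the SNR
#'   estimate); may be `NULL` to skip SNR.
#' @param sel A [selection()].
#' @param sample_rate Sampling rate of `samples`, required when SNR is
#'   computed.
#' @param f0_hint Optional fundamental hint for harmonic counting.
#' @return A one-row data frame with columns `DUR`, `DUR90`, `F5`, `F25`,
#'   `Fcenter`, `F75`, `F95`, `BDW50`, `BDW90`, `Fpeak`, `AE`, `SNRNIST`,
#'   `harmonics_present`, `n_harmonics`.
#' @export
measure_selection <- function(spec, samples, sel, sample_rate = NULL,
                              f0_hint = NULL) {
  qs <- c(F5 = 0.05, F25 = 0.25, Fcenter = 0.5, F75 = 0.75, F95 = 0.95)
  pf <- vapply(qs, function(q) percentile_frequency(spec, sel, q), 0)
  harm <- count_harmonics(spec, sel, f0_hint = f0_hint)
  snr <- NA_real_
  if (!is.null(samples)) {
    if (is.null(sample_rate)) sample_rate <- spec$config$sample_rate
    snr <- snr_nist_quick(samples, sel, sample_rate)
  }
  out <- data.frame(
    DUR = total_duration(sel),
    DUR90 = energy_duration(spec, sel, 0.9),
    F5 = pf[["F5"]], F25 = pf[["F25"]], Fcenter = pf[["Fcenter"]],
    F75 = pf[["F75"]], F95 = pf[["F95"]],
    Fpeak = peak_frequency(spec, sel),
    AE = aggregate_entropy(spec, sel),
    SNRNIST = snr,
    harmonics_present = harm$present,
    n_harmonics = harm$n
  )
  out$BDW50 <- bandwidth(out, 50)
  out$BDW90 <- bandwidth(out, 90)
  cols <- c("DUR", "DUR90", "F5", "F25", "Fcenter", "F75", "F95",
            "BDW50", "BDW90", "Fpeak", "AE", "SNRNIST",
            "harmonics_present", "n_harmonics")
  out[, cols]
}

#' Read a Raven-style selection table
#'
#' Tab-separated selection tables with the columns `"Selection"`,
#' `"Begin Time (s)"`, `"End Time (s)"`, `"Low Freq (Hz)"`,
#' `"High Freq (Hz)"`; extra columns are kept as-is.
#'
#' @param path Path to a tab-separated selection table.
#' @return A data frame, one row per selection.
#' @export
read_selection_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Begin Time (s)", "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("selection table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(df[["Begin Time (s)"]] < df[["End Time (s)"]]))
  if (length(bad) > 0) {
    stop("invalid selection at data line ", bad[1], ": begin time not before end time")
  }
  df
}

#' Write a Raven-style selection table
#'
#' @param df Data frame with at least the begin/end time and low/high
#'   frequency columns used by [read_selection_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Convert one selection-table row into a selection object.
selection_from_row <- function(row) {
  selection(row[["Begin Time (s)"]], row[["End Time (s)"]],
            row[["Low Freq (Hz)"]], row[["High Freq (Hz)"]])
}
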