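#' Pipeline configuration defaults
#'
#' Central configuration for the analysis pipeline. The defaults equal
#' the study's stated analysis settings: Hann window, 8192-point DFT,
#' 90% overlap, 20--1000 Hz band; measurement screening at quality 3 and
#' SNR strictly above 10.5 dB with at least 5 exemplars per type;
#' combinational merging at a 0.1 s gap; 3 s bout threshold; correlation
#' pruning at 0.7 with aggregate entropy protected; 5-minute hourly
#' subsampling; 06:00--17:59 fixed day split.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sample_rate = 96000,
    n_dft = 8192L,
    overlap = 0.9,
    window = "hann",
    band_low = 20,
    band_high = 1000,
    quality_min = 3,
    snr_threshold_db = 10.5,
    min_exemplars = 5,
    merge_gap_s = 0.1,
    bout_gap_s = 3,
    cor_threshold = 0.7,
    always_keep = "AE",
    diel_window_min = 5,
    day_start_hour = 6,
    day_end_hour = 17,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop("unknown config key(s): ",
                                paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

config_spectrogram <- function(cfg, sample_rate = NULL) {
  spectrogram_config(sample_rate %||% cfg$sample_rate, cfg$n_dft, cfg$overlap,
                     cfg$window, cfg$band_low, cfg$band_high)
}

#' Measure every selection of a recording
#'
#' Reads a WAV recording and a selection table, band-pass filters the
#' audio, computes the analysis spectrogram, and measures the full
#' feature set for each selection.
#'
#' @param wav Path to a mono PCM WAV file, or a list with `samples` and
#'   `sample_rate`.
#' @param selections Path to a Raven-style selection table, or a data
#'   frame from [read_selection_table()].
#' @param config A [pipeline_config()].
#' @param out_csv Optional path: write the feature table as CSV.
#' @return Feature data frame, one row per selection, with any extra
#'   selection-table columns (e.g. labels) carried through.
#' @export
run_measure <- function(wav, selections, config = pipeline_config(),
                        out_csv = NULL) {
  audio <- if (is.character(wav)) read_wav(wav) else wav
  sels <- if (is.character(selections)) read_selection_table(selections)
          else selections
  filtered <- bandpass(audio$samples, config$band_low, config$band_high,
                       audio$sample_rate)
  if (nrow(sels) == 0) {
    out <- data.frame()
  } else {
    scfg <- config_spectrogram(config, audio$sample_rate)
    spec <- compute_spectrogram(filtered, audio$sample_rate, scfg)
    rows <- lapply(seq_len(nrow(sels)), function(i) {
      sel <- selection_from_row(sels[i, ])
      measure_selection(spec, filtered, sel, audio$sample_rate)
    })
    out <- do.call(rbind, rows)
    extra <- setdiff(names(sels), c("Begin Time (s)", "End Time (s)",
                                    "Low Freq (Hz)", "High Freq (Hz)"))
    for (col in extra) out[[col]] <- sels[[col]]
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Classify measured calls and report
#'
#' Applies the classification stage to a labeled feature table: drops
#' call types with too few exemplars, prunes correlated parameters
#' (aggregate entropy protected), fits the discriminant model and runs
#' leave-one-out cross-validation, and assembles the report with
#' discriminant variance shares and parameter contributions.
#'
#' @param features Feature data frame (or CSV path) with a `label` column
#'   and numeric parameter columns.
#' @param config A [pipeline_config()].
#' @param params Candidate parameter columns; defaults to all numeric
#'   columns except SNR.
#' @param out_json Optional path: write the report as JSON.
#' @return A list with `report` (see [loocv_classify()]), `model`,
#'   `retained_params`, `retained_types`, `variance_explained_pct`,
#'   `contributions_pct`.
#' @export
run_classify <- function(features, config = pipeline_config(), params = NULL,
                         out_json = NULL) {
  df <- if (is.character(features)) utils::read.csv(features) else features
  if (!"label" %in% names(df)) stop("feature table needs a 'label' column")
  if (is.null(params)) {
    params <- names(df)[vapply(df, is.numeric, TRUE)]
    params <- setdiff(params, c("SNRNIST", "snr", "quality", "n_harmonics"))
  }
  types <- filter_min_exemplars(df$label, config$min_exemplars)
  df <- df[df$label %in% types, , drop = FALSE]
  if (length(types) < 2) stop("fewer than 2 call types after filtering")
  keep <- prune_correlated(df[, params, drop = FALSE], config$cor_threshold,
                           always_keep = config$always_keep)
  x <- df[, keep, drop = FALSE]
  model <- fit_lda(x, df$label)
  report <- loocv_classify(x, df$label)
  out <- list(
    report = report,
    model = model,
    retained_params = keep,
    retained_types = types,
    variance_explained_pct = variance_explained(model),
    contributions_pct = ld_contributions(model)
  )
  if (!is.null(out_json)) {
    ser <- list(
      retained_params = keep,
      retained_types = types,
      confusion_counts = report$confusion,
      confusion_pct = report$confusion_pct,
      accuracy_pct = report$accuracy_pct,
      accuracy_ci_pct = report$accuracy_ci_pct,
      kappa = report$kappa,
      per_class_correct_pct = report$per_class_correct_pct,
      chance_levels_pct = report$chance_levels_pct,
      variance_explained_pct = out$variance_explained_pct,
      contributions_pct = out$contributions_pct
    )
    jsonlite::write_json(ser, out_json, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  }
  out
}

#' Summarize a call log into repertoire tables
#'
#' @param log A call-log data frame (or CSV path readable by
#'   [read_call_log()]), or a pre-tabulated count matrix.
#' @return The [summarize_repertoire()] summary, augmented with
#'   `bout_fraction_pct` when the log has a `bout_id` column.
#' @export
run_summarize <- function(log) {
  df <- if (is.character(log)) read_call_log(log) else log
  out <- summarize_repertoire(df)
  if ("bout_id" %in% names(df)) {
    out$bout_fraction_pct <- round_half_up(
      mean(!is.na(df$bout_id)) * 100, 1)
  }
  out
}

#' Diel analysis of a call log
#'
#' Runs the temporal analysis per site: first-minutes-of-hour
#' subsampling, hourly activity profile, day/night labeling (sun table
#' when provided, fixed split otherwise), within-site rank-sum tests and
#' Benjamini--Hochberg adjustment across sites.
#'
#' @param log Call-log data frame with `site` and POSIXct `start` columns.
#' @param analysed_hours Named list: POSIXct vector of analysed hour
#'   starts per site. `NULL` analyses every hour spanned by each site's
#'   log.
#' @param config A [pipeline_config()].
#' @param sun_table Optional sunrise/sunset table (see
#'   [label_day_night()]).
#' @return A list with `profiles` (per-site hourly profile data frames),
#'   `tests` (one row per site: day/night means, SE, statistic, raw and
#'   adjusted p, applicable flag).
#' @export
run_diel <- function(log, analysed_hours = NULL, config = pipeline_config(),
                     sun_table = NULL) {
  sites <- unique(log$site)
  if (length(sites) == 0) stop("empty call log")
  profiles <- list()
  rows <- list()
  for (s in sites) {
    sub <- log[log$site == s, , drop = FALSE]
    hours <- if (is.null(analysed_hours)) NULL else analysed_hours[[s]]
    win <- subsample_first_window(sub, analysed_hours = hours,
                                  window_min = config$diel_window_min,
                                  site = s)
    profiles[[s]] <- hourly_profile(win)
    dn <- label_day_night(win$window_start, sun_table = sun_table, site = s)
    res <- day_night_test(win$n_calls[dn == "day"], win$n_calls[dn == "night"])
    rows[[s]] <- data.frame(
      site = s, day_mean = res$day_mean, day_se = res$day_se,
      night_mean = res$night_mean, night_se = res$night_se,
      statistic = res$statistic, p = res$p, applicable = res$applicable)
  }
  tests <- do.call(rbind, rows)
  tests$p_adjusted <- adjust_bh(tests$p)
  rownames(tests) <- NULL
  list(profiles = profiles, tests = tests)
}
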