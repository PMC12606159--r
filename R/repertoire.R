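#' Elemental call unit names
#'
#' The eight vocal units that can appear in a call label. Croak, Growl,
#' Moan, Rumble, Whoop and Whine occur as stand-alone (elemental) calls;
#' Hum and Grunt occur only embedded inside combinational calls and are
#' therefore excluded from the elemental repertoire count, although the
#' label parser accepts them inside combinational labels.
#'
#' @return Character vector of unit names.
#' @export
call_units <- function() {
  c("Croak", "Growl", "Moan", "Rumble", "Whoop", "Whine", "Hum", "Grunt")
}

#' Decompose a call-type label into elemental units
#'
#' Parses a concatenated label such as `"MoanGrowl"` into its ordered
#' elemental units by greedy longest-prefix matching over the eight unit
#' names; repeats are allowed (`"MoanGrowlMoanWhoop"`). A label is
#' combinational when it contains two or more units. Hum and Grunt are
#' rejected as single-unit labels because they never occur as discrete
#' calls.
#'
#' @param label Call-type label, e.g. `"GrowlRumbleWhoop"`.
#' @return A list with `label`, `units` (ordered character vector) and
#'   `is_combinational` (logical).
#' @export
decompose_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  units_all <- call_units()
  units_all <- units_all[order(nchar(units_all), decreasing = TRUE)]
  rest <- label
  units <- character(0)
  while (nzchar(rest)) {
    hit <- NA_character_
    for (u in units_all) {
      if (startsWith(rest, u)) { hit <- u; break }
    }
    if (is.na(hit)) {
      stop("cannot parse call label '", label, "': unrecognized suffix '",
           rest, "'")
    }
    units <- c(units, hit)
    rest <- substr(rest, nchar(hit) + 1L, nchar(rest))
  }
  if (length(units) == 1 && units %in% c("Hum", "Grunt")) {
    stop("'", label, "' never occurs as a discrete call type")
  }
  list(label = label, units = units, is_combinational = length(units) >= 2)
}

#' Croak/Growl duration rule
#'
#' Croaks are calls shorter than 0.5 s; Growls are calls of 0.5 s or
#' longer (the strict inequality applies to the Croak side, so the exact
#' boundary is assigned to Growl).
#'
#' @param duration Call duration in seconds (> 0).
#' @return `"Croak"` or `"Growl"`.
#' @export
apply_duration_rule <- function(duration) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive")
  }
  if (duration < 0.5) "Croak" else "Growl"
}

# Numeric seconds from either numeric or POSIXct columns.
as_seconds <- function(x) {
  if (inherits(x, "POSIXct")) as.numeric(x) else as.numeric(x)
}

#' Merge immediately adjacent calls into combinational calls
#'
#' Runs of calls with no intervening ambient noise — operationalized as an
#' inter-call gap of at most `max_gap` seconds (default 0.1 s; the
#' original criterion is qualitative, so a small configurable tolerance is
#' used for discrete annotations) — are replaced by a single annotation
#' whose label is the concatenation of the member labels and whose span
#' covers the run. Adjacent calls with differing `amplitude_class` are
#' never merged: amplitude differences indicate different callers.
#'
#' @param annotations Data frame with numeric/POSIXct `start` and `end`
#'   columns, a `label` column, and optionally `amplitude_class`; must
#'   describe a single site/deployment.
#' @param max_gap Maximum silent gap (s) treated as "no separating noise".
#' @return The annotation data frame with merged rows, time-sorted.
#' @export
merge_adjacent <- function(annotations, max_gap = 0.1) {
  if (nrow(annotations) == 0) return(annotations)
  ann <- annotations[order(as_seconds(annotations$start)), , drop = FALSE]
  has_amp <- "amplitude_class" %in% names(ann)
  start_s <- as_seconds(ann$start)
  end_s <- as_seconds(ann$end)

  grp <- integer(nrow(ann))
  grp[1] <- 1L
  for (i in seq_len(nrow(ann))[-1]) {
    gap <- start_s[i] - end_s[i - 1L]
    same_amp <- !has_amp ||
      is.na(ann$amplitude_class[i]) || is.na(ann$amplitude_class[i - 1L]) ||
      ann$amplitude_class[i] == ann$amplitude_class[i - 1L]
    grp[i] <- if (gap <= max_gap && same_amp) grp[i - 1L] else grp[i - 1L] + 1L
  }

  pieces <- lapply(split(seq_len(nrow(ann)), grp), function(ix) {
    row <- ann[ix[1], , drop = FALSE]
    if (length(ix) > 1) {
      row$label <- paste(ann$label[ix], collapse = "")
      row$end <- ann$end[ix[length(ix)]]
    }
    row
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Segment calls into bouts
#'
#' Bouts are maximal runs of two or more calls (elemental or
#' combinational) in which every silent gap — next start minus previous
#' end — is strictly less than `gap_threshold` seconds (default 3 s).
#' Isolated calls receive no bout id.
#'
#' @param annotations Time-sortable annotation data frame with `start` and
#'   `end` columns.
#' @param gap_threshold Bout-breaking silence threshold in seconds.
#' @return The annotations, time-sorted, with an integer `bout_id` column
#'   (`NA` for singletons).
#' @export
segment_bouts <- function(annotations, gap_threshold = 3) {
  ann <- annotations[order(as_seconds(annotations$start)), , drop = FALSE]
  n <- nrow(ann)
  ann$bout_id <- rep(NA_integer_, n)
  if (n == 0) return(ann)
  start_s <- as_seconds(ann$start)
  end_s <- as_seconds(ann$end)

  run <- integer(n)
  run[1] <- 1L
  for (i in seq_len(n)[-1]) {
    gap <- start_s[i] - end_s[i - 1L]
    run[i] <- if (gap < gap_threshold) run[i - 1L] else run[i - 1L] + 1L
  }
  sizes <- table(run)
  bout_runs <- as.integer(names(sizes)[sizes >= 2])
  next_id <- 1L
  for (r in bout_runs) {
    ann$bout_id[run == r] <- next_id
    next_id <- next_id + 1L
  }
  rownames(ann) <- NULL
  ann
}

#' Screen annotations for quantitative measurement
#'
#' Retains only calls rated at the highest subjective quality (3) with a
#' signal-to-noise ratio strictly greater than 10.5 dB. Calls without an
#' SNR value are excluded, with a warning.
#'
#' @param annotations Data frame with `quality` and `snr` columns.
#' @param min_quality Required quality score (default 3).
#' @param snr_threshold SNR threshold in dB, strict (default 10.5).
#' @return The retained subset.
#' @export
screen_for_measurement <- function(annotations, min_quality = 3,
                                   snr_threshold = 10.5) {
  missing_snr <- is.na(annotations$snr)
  if (any(missing_snr)) {
    warning(sum(missing_snr), " annotation(s) without SNR excluded from screening")
  }
  keep <- !missing_snr & annotations$quality == min_quality &
    annotations$snr > snr_threshold
  annotations[keep, , drop = FALSE]
}

#' Retain call types with enough measured exemplars
#'
#' @param labels Character vector of call-type labels, one per measured call.
#' @param minimum Minimum exemplar count (default 5).
#' @return Character vector of retained type labels.
#' @export
filter_min_exemplars <- function(labels, minimum = 5) {
  counts <- table(labels)
  sort(names(counts)[counts >= minimum])
}

# Round half away from zero, the convention used for the reported
# percentages (8212/23416 -> 35.1% / 35%).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a vocal repertoire from call counts or annotations
#'
#' Builds the per-type, per-site repertoire table: counts per (type,
#' site), row totals, percent of grand total (1 decimal, half-up; values
#' below 0.1% flagged), and combinational subtotals derived by parsing
#' each label with [decompose_label()].
#'
#' @param x Either a long annotation data frame with `label` and `site`
#'   columns (one row per detected call), or a pre-tabulated count matrix:
#'   a data frame whose first column (`type` or row names) holds labels
#'   and whose remaining numeric columns are per-site counts.
#' @return A list with `table` (per-type data frame: site counts, `total`,
#'   `pct`, `rare`, `is_combinational`, `n_units`), `grand_total`,
#'   `combinational` (list with `n_detections`, `n_types`, `labels`) and
#'   `elemental` (same shape).
#' @export
summarize_repertoire <- function(x) {
  if (all(c("label", "site") %in% names(x))) {
    counts <- as.data.frame.matrix(table(x$label, x$site))
    counts <- cbind(type = rownames(counts), counts)
    rownames(counts) <- NULL
  } else {
    counts <- as.data.frame(x)
    if (!"type" %in% names(counts)) {
      counts <- cbind(type = rownames(counts), counts)
    }
  }
  site_cols <- names(counts)[vapply(counts, is.numeric, TRUE)]
  counts$total <- rowSums(counts[, site_cols, drop = FALSE])
  grand <- sum(counts$total)

  parsed <- lapply(as.character(counts$type), decompose_label)
  counts$n_units <- vapply(parsed, function(p) length(p$units), 0L)
  counts$is_combinational <- vapply(parsed, function(p) p$is_combinational, TRUE)
  pct <- if (grand > 0) counts$total / grand * 100 else rep(0, nrow(counts))
  counts$pct <- round_half_up(pct, 1)
  counts$rare <- pct < 0.1
  counts <- counts[order(counts$type), , drop = FALSE]
  rownames(counts) <- NULL

  comb <- counts[counts$is_combinational, , drop = FALSE]
  elem <- counts[!counts$is_combinational, , drop = FALSE]
  list(
    table = counts,
    grand_total = grand,
    combinational = list(
      n_detections = sum(comb$total),
      n_types = nrow(comb),
      labels = comb$type
    ),
    elemental = list(
      n_detections = sum(elem$total),
      n_types = nrow(elem),
      labels = elem$type
    )
  )
}

#' Read a call log
#'
#' Comma-separated log with header columns `site`, `deployment_id`,
#' `start_iso`, `end_iso`, `label`, `quality`, `snr_db` and optionally
#' `amplitude_class`; timestamps are ISO-8601 local times interpreted
#' naively (no timezone arithmetic).
#'
#' @param path Path to the CSV log.
#' @return A data frame with POSIXct `start`/`end` columns plus the
#'   remaining log fields (`snr_db` is renamed `snr`).
#' @export
read_call_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "start_iso", "end_iso", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("call log missing column(s): ",
                             paste(miss, collapse = ", "))
  df$start <- as.POSIXct(df$start_iso, tz = "UTC",
                         format = "%Y-%m-%dT%H:%M:%OS")
  df$end <- as.POSIXct(df$end_iso, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("unparseable ISO-8601 timestamp in call log")
  }
  if ("snr_db" %in% names(df)) names(df)[names(df) == "snr_db"] <- "snr"
  df
}

#' Write a call log
#'
#' @param df Annotation data frame with POSIXct `start`/`end` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_call_log <- function(df, path) {
  out <- df
  out$start_iso <- format(df$start, "%Y-%m-%dT%H:%M:%OS3")
  out$end_iso <- format(df$end, "%Y-%m-%dT%H:%M:%OS3")
  if ("snr" %in% names(out)) names(out)[names(out) == "snr"] <- "snr_db"
  out$start <- NULL
  out$end <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Packaged repertoire count matrix
#'
#' The published per-site detection counts for the 25 identified vocal
#' types across the five monitored sites (three Mānana Island deployments
#' reported separately), as shipped in `inst/extdata/repertoire_counts.csv`.
#'
#' @return Data frame with a `type` column and one numeric column per
#'   deployment.
#' @export
repertoire_counts <- function() {
  path <- system.file("extdata", "repertoire_counts.csv", package = "sealvox",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
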