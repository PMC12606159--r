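#' Count calls in the first minutes of each analysed hour
#'
#' Implements the subsampling scheme used to keep effort comparable
#' across sites: only calls starting within the first `window_min`
#' minutes of each hour are counted (half-open interval, so a call at
#' exactly hh:05:00 falls outside a 5-min window). Analysed hours with no
#' calls are included as zero-count windows.
#'
#' @param annotations Data frame with a POSIXct `start` column and
#'   optionally `site`.
#' @param analysed_hours POSIXct vector of hour starts to analyse. When
#'   `NULL`, every whole hour from the first to the last annotation is
#'   analysed.
#' @param window_min Window length in minutes (default 5).
#' @param site Site label for the output (taken from the annotations when
#'   absent).
#' @return Data frame with `site`, `window_start` (POSIXct), `hour`
#'   (0--23) and `n_calls`.
#' @export
subsample_first_window <- function(annotations, analysed_hours = NULL,
                                   window_min = 5, site = NULL) {
  stopifnot(window_min > 0)
  if (is.null(analysed_hours)) {
    if (nrow(annotations) == 0) stop("no annotations and no analysed_hours")
    rng <- range(annotations$start)
    analysed_hours <- seq(trunc(rng[1], "hours"), trunc(rng[2], "hours"),
                          by = "hour")
  }
  if (is.null(site)) {
    site <- if ("site" %in% names(annotations) && nrow(annotations) > 0)
      annotations$site[1] else "site"
  }
  win_s <- window_min * 60
  starts <- as.numeric(annotations$start)
  h0 <- as.numeric(analysed_hours)
  n_calls <- vapply(h0, function(h)
    sum(starts >= h & starts < h + win_s), 0L)
  data.frame(
    site = site,
    window_start = analysed_hours,
    hour = as.integer(format(analysed_hours, "%H")),
    n_calls = as.integer(n_calls)
  )
}

#' Hourly diel activity profile
#'
#' Mean and standard error of the per-window call count for each hour of
#' day, pooling all analysed windows that share an hour-of-day (the SE is
#' across windows, not across days).
#'
#' @param windows Output of [subsample_first_window()].
#' @return Data frame with `hour`, `mean`, `se` and `n_windows`.
#' @export
hourly_profile <- function(windows) {
  agg <- stats::aggregate(windows$n_calls, by = list(hour = windows$hour),
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  m <- agg$x
  se <- ifelse(m[, "n"] > 1, m[, "sd"] / sqrt(m[, "n"]), 0)
  data.frame(hour = agg$hour, mean = m[, "mean"], se = se,
             n_windows = as.integer(m[, "n"]))
}

#' Classify a timestamp as day or night
#'
#' With a sunrise/sunset table, a time is "day" when
#' `sunrise <= t < sunset` for its date (and site, when the table has a
#' site column). Without a table — or for dates the table does not cover,
#' with a warning — a fixed split is used: 06:00--17:59 is day,
#' 18:00--05:59 is night. Twilight is not treated separately.
#'
#' @param timestamps POSIXct vector.
#' @param sun_table Optional data frame with `date` (YYYY-MM-DD),
#'   `sunrise_local`, `sunset_local` (HH:MM or HH:MM:SS) and optionally
#'   `site` columns.
#' @param site Site to match in the sun table.
#' @return Character vector of `"day"` / `"night"`.
#' @export
label_day_night <- function(timestamps, sun_table = NULL, site = NULL) {
  hours <- as.integer(format(timestamps, "%H"))
  fixed <- ifelse(hours >= 6 & hours <= 17, "day", "night")
  if (is.null(sun_table)) return(fixed)
  tab <- sun_table
  if (!is.null(site) && "site" %in% names(tab)) {
    tab <- tab[tab$site == site, , drop = FALSE]
  }
  dates <- format(timestamps, "%Y-%m-%d")
  idx <- match(dates, as.character(tab$date))
  out <- fixed
  covered <- !is.na(idx)
  if (any(!covered)) {
    warning(sum(!covered), " timestamp(s) outside the sun table: fixed split used")
  }
  if (any(covered)) {
    sr <- as.POSIXct(paste(dates[covered], tab$sunrise_local[idx[covered]]),
                     tz = "UTC")
    ss <- as.POSIXct(paste(dates[covered], tab$sunset_local[idx[covered]]),
                     tz = "UTC")
    out[covered] <- ifelse(timestamps[covered] >= sr & timestamps[covered] < ss,
                           "day", "night")
  }
  out
}

#' Day/night rank-sum comparison of window counts
#'
#' Two-sided Wilcoxon rank-sum (Mann--Whitney) test on per-window call
#' counts, with tie and continuity corrections (normal approximation for
#' larger samples), as appropriate for zero-heavy non-normal counts. An
#' empty group yields a "not applicable" result rather than an error.
#'
#' @param day_counts,night_counts Integer vectors of per-window counts.
#' @return A list with `statistic` (rank-sum W), `p`, `day_mean`,
#'   `day_se`, `night_mean`, `night_se`, `applicable`.
#' @export
day_night_test <- function(day_counts, night_counts) {
  mean_se <- function(v) {
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  }
  d <- mean_se(day_counts)
  n <- mean_se(night_counts)
  if (length(day_counts) == 0 || length(night_counts) == 0) {
    return(list(statistic = NA_real_, p = NA_real_,
                day_mean = d[1], day_se = d[2],
                night_mean = n[1], night_se = n[2], applicable = FALSE))
  }
  if (all(c(day_counts, night_counts) == c(day_counts, night_counts)[1])) {
    # all values tied: no evidence of any difference
    return(list(statistic = length(day_counts) * length(night_counts) / 2,
                p = 1, day_mean = d[1], day_se = d[2],
                night_mean = n[1], night_se = n[2], applicable = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(day_counts, night_counts, alternative = "two.sided",
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       day_mean = d[1], day_se = d[2], night_mean = n[1], night_se = n[2],
       applicable = TRUE)
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across sites, with enforced
#' monotonicity, capped at 1.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\]; `NA`s pass through.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
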