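# Construct a minimal spectrogram object directly from an energy matrix,
# for toy-matrix tests of the measurement operations.
make_spec <- function(energy, freq_resolution = 10, time_step = 0.1) {
  structure(
    list(
      energy = energy,
      freq = (seq_len(nrow(energy)) - 1) * freq_resolution,
      time = (seq_len(ncol(energy)) - 1) * time_step,
      freq_resolution = freq_resolution,
      time_step = time_step,
      start_offset = 0,
      config = NULL
    ),
    class = "spectrogram"
  )
}

# Selection covering an entire toy spectrogram.
full_box <- function(spec) {
  selection(min(spec$time) - 1e-9, max(spec$time) + 1e-9,
            min(spec$freq) - 1e-9, max(spec$freq) + 1e-9)
}

# Brute-force cumulative-sum oracle for the energy-percentile frequency:
# center frequency of the lowest bin whose ascending cumulative
# frequency-marginal energy reaches q of the total.
oracle_percentile_frequency <- function(energy, freq, q) {
  marg <- rowSums(energy)
  cum <- 0
  for (i in seq_along(marg)) {
    cum <- cum + marg[i]
    if (cum >= q * sum(marg)) return(freq[i])
  }
  freq[length(freq)]
}

# Brute-force oracle for the central-interval energy duration.
oracle_energy_duration <- function(energy, times, fraction = 0.9) {
  marg <- colSums(energy)
  tot <- sum(marg)
  q_lo <- (1 - fraction) / 2 * tot
  q_hi <- (1 + fraction) / 2 * tot
  cum <- 0
  t_lo <- t_hi <- NA_real_
  for (i in seq_along(marg)) {
    cum <- cum + marg[i]
    if (is.na(t_lo) && cum >= q_lo) t_lo <- times[i]
    if (is.na(t_hi) && cum >= q_hi) { t_hi <- times[i]; break }
  }
  t_hi - t_lo
}

# Naive leave-one-out discriminant oracle: per held-out row, recompute
# class means, pooled covariance and priors from scratch and apply the
# Gaussian shared-covariance rule via stats::mahalanobis.
oracle_loocv <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  pred <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    xt <- x[-i, , drop = FALSE]
    lt <- labels[-i]
    classes <- sort(unique(lt))
    ns <- table(factor(lt, classes))
    W <- matrix(0, ncol(x), ncol(x))
    for (cl in classes) {
      xc <- xt[lt == cl, , drop = FALSE]
      if (nrow(xc) >= 2) W <- W + crossprod(sweep(xc, 2, colMeans(xc)))
    }
    W <- W / (nrow(xt) - length(classes))
    scores <- vapply(classes, function(cl) {
      m <- colMeans(xt[lt == cl, , drop = FALSE])
      -0.5 * stats::mahalanobis(x[i, , drop = FALSE], m, W) +
        log(ns[[cl]] / nrow(xt))
    }, 0)
    pred[i] <- classes[which.max(scores)]
  }
  pred
}

# Welch's one-way F statistic by direct formula.
oracle_welch_f <- function(values, groups) {
  groups <- as.factor(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  vi <- tapply(values, groups, stats::var)
  wi <- ni / vi
  k <- length(ni)
  mw <- sum(wi * mi) / sum(wi)
  num <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- 3 * sum((1 - wi / sum(wi))^2 / (ni - 1)) / (k^2 - 1)
  num / (1 + 2 * lam * (k - 2) / 3)
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
oracle_ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  ra <- sum(rank(pooled)[seq_along(a)])
  combos <- utils::combn(n, length(a))
  stats <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(stats - mu) >= abs(ra - mu) - 1e-9)
}

# A feature matrix engineered so that correlation pruning at 0.7 removes
# the centre frequency, the 25/75/95% frequencies and the 90% duration,
# while aggregate entropy exceeds the threshold but is protected.
make_pruning_fixture <- function(n = 400, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    DUR <- rnorm(n, 2, 1)
    # correlation design: DUR-DUR90 ~ 0.8, DUR90-AE ~ 0.8, DUR-AE ~ 0.64,
    # so both redundant pairs exceed 0.7 but the retained DUR/AE pair does not
    DUR90 <- 0.8 * DUR + rnorm(n, 0, 0.6)
    AE <- 2 + 0.5 * DUR90 + rnorm(n, 0, 0.375)
    F5 <- rnorm(n, 150, 50)
    F25 <- 1.2 * F5 + rnorm(n, 0, 12)
    F75 <- 1.3 * F25 + rnorm(n, 0, 12)
    F95 <- 1.2 * F75 + rnorm(n, 0, 12)
    Fcenter <- (F25 + F75) / 2 + rnorm(n, 0, 6)
    BDW50 <- rnorm(n, 100, 40)
    BDW90 <- rnorm(n, 250, 80)
    Fpeak <- rnorm(n, 230, 60)
    data.frame(DUR, DUR90, F5, F25, Fcenter, BDW50, F75, F95, BDW90,
               Fpeak, AE)
  })
}

# Window counts for a day/night Poisson simulation: n_days days of
# hourly windows, with fixed-split day hours at rate_day and night hours
# at rate_night calls per window.
simulate_window_counts <- function(rate_day, rate_night, n_days) {
  hours <- rep(0:23, n_days)
  is_day <- hours >= 6 & hours <= 17
  counts <- integer(length(hours))
  counts[is_day] <- rpois(sum(is_day), rate_day)
  counts[!is_day] <- rpois(sum(!is_day), rate_night)
  list(day = counts[is_day], night = counts[!is_day])
}
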