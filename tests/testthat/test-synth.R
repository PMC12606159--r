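test_that("the generator is deterministic and seed-isolated", {
  a <- synth_call("Moan", seed = 3)
  b <- synth_call("Moan", seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$samples, synth_call("Moan", seed = 4)$samples))

  fm1 <- synth_feature_matrix(sizes = c(Moan = 10, Whoop = 10), seed = 6)
  fm2 <- synth_feature_matrix(sizes = c(Moan = 10, Whoop = 10), seed = 6)
  expect_identical(fm1, fm2)

  cfg <- synth_config(hourly_rate = rep(10, 24))
  r1 <- synth_recording(cfg, duration_h = 3, seed = 7, render_audio = FALSE)
  r2 <- synth_recording(cfg, duration_h = 3, seed = 7, render_audio = FALSE)
  expect_identical(r1$truth, r2$truth)

  # the generator restores the caller's RNG state
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(synth_call("Croak", seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("archetype defaults land on the published call structure", {
  cfg <- spectrogram_config(96000)
  df <- frequency_resolution(cfg)

  moan <- synth_call("Moan", seed = 12)
  spec <- compute_spectrogram(moan$samples, 96000, cfg)
  sel <- selection(0, moan$truth$duration, 20, 1000)
  expect_lt(abs(peak_frequency(spec, sel) - 80), df + 1e-9)

  # Whoop at the mean duration: measured DUR within 2 hops of 0.14 s
  whoop <- synth_call("Whoop", seed = 12, overrides = list(dur_sd = 0))
  expect_lt(abs(whoop$truth$duration - 0.14), 2 * time_resolution(cfg))

  # tonal Moan has lower aggregate entropy than broadband pulsed Rumble
  rumble <- synth_call("Rumble", seed = 12)
  spec_r <- compute_spectrogram(rumble$samples, 96000, cfg)
  sel_r <- selection(0, rumble$truth$duration, 20, 1000)
  expect_lt(aggregate_entropy(spec, sel), aggregate_entropy(spec_r, sel_r))
})

test_that("combinational synthesis concatenates members without silence", {
  cb <- synth_combinational("MoanGrowl", seed = 2)
  members <- cb$truth$members
  expect_equal(members$unit, c("Moan", "Growl"))
  # total duration = member durations minus one 10 ms crossfade
  dur_members <- sum(members$end - members$start)
  expect_equal(length(cb$samples) / cb$sample_rate, dur_members - 0.01,
               tolerance = 1e-6)

  big <- synth_combinational("MoanHumGrowlRumbleWhoop", seed = 2)
  expect_equal(nrow(big$truth$members), 5)

  # merging the truth member boundaries reproduces the label
  ann <- data.frame(start = members$start, end = members$end,
                    label = members$unit)
  expect_equal(merge_adjacent(ann)$label, "MoanGrowl")

  expect_error(synth_combinational("Moan", seed = 1), "not combinational")
  expect_error(synth_combinational("MoanXyz", seed = 1), "Xyz")
})

test_that("bout synthesis round-trips through bout segmentation", {
  bt <- synth_bout(c("Whoop", "Whoop", "Whoop", "Whoop"), seed = 5,
                   gap_range = c(0.1, 0.45))
  seg <- segment_bouts(bt$truth)
  expect_equal(seg$bout_id, rep(1L, 4))
  gaps <- bt$truth$start[-1] - bt$truth$end[-4]
  expect_true(all(gaps < 0.5))

  # a forced 3.1 s gap breaks the pair into singletons
  apart <- data.frame(start = c(0, 3.6), end = c(0.5, 4.1), label = "Whoop")
  expect_true(all(is.na(segment_bouts(apart)$bout_id)))

  expect_error(synth_bout("Whoop", seed = 1), "at least 2")
  expect_error(synth_bout(c("Whoop", "Whoop"), gap_range = c(1, 4)), "below 3")
})

test_that("arrivals follow the configured Poisson rates", {
  cfg0 <- synth_config(hourly_rate = rep(0, 24))
  empty <- synth_recording(cfg0, duration_h = 5, seed = 2,
                           render_audio = FALSE)
  expect_equal(nrow(empty$truth), 0)

  lambda <- 3
  cfg <- synth_config(hourly_rate = rep(lambda, 24))
  rec <- synth_recording(cfg, duration_h = 100, seed = 31,
                         render_audio = FALSE)
  n_events <- length(unique(rec$truth$event))
  expect_lt(abs(n_events - 100 * lambda), 3 * sqrt(100 * lambda))

  # truth labels always parse; bout ids respect the generator structure
  expect_silent(lapply(rec$truth$label, decompose_label))
  expect_true(all(rec$truth$end > rec$truth$start))
})

test_that("generated calls recover their archetype parameters", {
  cfg <- spectrogram_config(96000)
  arch <- call_archetypes()
  for (name in c("Croak", "Moan", "Whoop")) {
    durs <- numeric(50)
    fpeaks <- numeric(50)
    for (i in 1:50) {
      call <- synth_call(name, seed = 1000 + i)
      durs[i] <- call$truth$duration
      if (name == "Moan") {
        sp <- compute_spectrogram(call$samples, 96000, cfg)
        fpeaks[i] <- peak_frequency(
          sp, selection(0, call$truth$duration, 20, 1000))
      }
    }
    a <- arch[[name]]
    # truncation at the ramp floor biases short types slightly upward
    se <- a$dur_sd / sqrt(50)
    expect_lt(abs(mean(durs) - a$dur_mean), 3 * se + 0.01)
    if (name == "Moan") {
      expect_lt(abs(mean(fpeaks) - 80), frequency_resolution(cfg))
    }
  }
})

test_that("feature draws match the published class statistics", {
  fm <- synth_feature_matrix(sizes = c(Growl = 10000), seed = 17)
  # resampling truncation at the 0.01 s bound shifts the Growl duration
  # moments analytically; the draws must match the truncated-normal oracle
  a <- (0.01 - 2.94) / 1.44
  lambda <- dnorm(a) / (1 - pnorm(a))
  trunc_mean <- 2.94 + 1.44 * lambda
  trunc_sd <- 1.44 * sqrt(1 + a * lambda - lambda^2)
  expect_lt(abs(mean(fm$DUR) - trunc_mean) / trunc_mean, 0.02)
  expect_lt(abs(sd(fm$DUR) - trunc_sd) / trunc_sd, 0.05)
  expect_lt(abs(mean(fm$DUR) - 2.94) / 2.94, 0.04)  # bias stays small

  fm2 <- synth_feature_matrix(sizes = c(Moan = 500, Whoop = 500), seed = 18)
  expect_lt(mean(fm2$Fpeak[fm2$label == "Moan"]),
            mean(fm2$Fpeak[fm2$label == "Whoop"]))
  expect_true(all(fm2$DUR > 0.01) && all(fm2$AE > 0) && all(fm2$F5 > 0))
  expect_error(synth_feature_matrix(sizes = c(Bark = 5)), "unknown class")
})

test_that("rendered recordings support the full measurement round trip", {
  cfg <- synth_config(hourly_rate = rep(120, 24), snr_range = c(14, 20),
                      bout_sizes = 1:2, bout_size_probs = c(0.6, 0.4),
                      elemental_menu = c(Croak = 0.4, Moan = 0.3, Whoop = 0.3))
  rec <- synth_recording(cfg, duration_h = 40 / 3600, seed = 23,
                         render_audio = TRUE)
  expect_gt(nrow(rec$truth), 0)
  expect_equal(length(rec$samples), 40 * rec$sample_rate)

  filt <- bandpass(rec$samples, 20, 1000, rec$sample_rate)
  spec <- compute_spectrogram(filt, rec$sample_rate,
                              spectrogram_config(rec$sample_rate))
  for (j in seq_len(nrow(rec$truth))) {
    sel <- selection(rec$truth$start_s[j], rec$truth$end_s[j], 20, 1000)
    fv <- measure_selection(spec, filt, sel)
    expect_true(fv$F5 <= fv$F25 && fv$F25 <= fv$Fcenter &&
                  fv$Fcenter <= fv$F75 && fv$F75 <= fv$F95)
    expect_identical(fv$BDW90, fv$F95 - fv$F5)
    expect_gte(fv$AE, 0)
  }
  # bout structure in the truth log survives segmentation
  seg <- segment_bouts(rec$truth)
  gen_bouts <- unique(rec$truth$bout_id[!is.na(rec$truth$bout_id)])
  rec_bouts <- unique(seg$bout_id[!is.na(seg$bout_id)])
  expect_gte(length(rec_bouts), length(gen_bouts))
})

test_that("injected calls carry their target SNR", {
  cfg <- synth_config(hourly_rate = rep(90, 24), snr_range = c(15, 15),
                      bout_sizes = 1, bout_size_probs = 1,
                      elemental_menu = c(Croak = 0.5, Whoop = 0.5))
  rec <- synth_recording(cfg, duration_h = 80 / 3600, seed = 41,
                         render_audio = TRUE)
  filt <- bandpass(rec$samples, 20, 1000, rec$sample_rate)
  ests <- vapply(seq_len(nrow(rec$truth)), function(j) {
    sel <- selection(rec$truth$start_s[j], rec$truth$end_s[j], 20, 1000)
    snr_nist_quick(filt, sel, rec$sample_rate)
  }, 0)
  expect_gt(length(ests), 0)
  expect_true(all(abs(ests - 15) <= 3))
})
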