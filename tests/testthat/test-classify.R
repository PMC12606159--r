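test_that("correlation pruning removes the redundant percentile family", {
  x <- make_pruning_fixture()
  kept <- prune_correlated(x, threshold = 0.7, always_keep = "AE")
  expect_setequal(setdiff(names(x), kept),
                  c("Fcenter", "F25", "F75", "F95", "DUR90"))
  expect_true("AE" %in% kept)
  # AE exceeded the threshold (against a pruned partner) yet was retained
  expect_gt(max(abs(cor(x$AE, x[, setdiff(names(x), kept)]))), 0.7)

  # independent columns: nothing removed
  set.seed(1)
  indep <- as.data.frame(matrix(rnorm(300), ncol = 3))
  expect_equal(prune_correlated(indep, 0.7), names(indep))

  # constant column is an error naming the column
  bad <- data.frame(a = rnorm(10), b = rep(2, 10))
  expect_error(prune_correlated(bad), "b")
})

test_that("the fitted discriminant recovers the Fisher direction", {
  set.seed(21)
  n <- 200
  x <- rbind(matrix(rnorm(2 * n), ncol = 2),
             sweep(matrix(rnorm(2 * n), ncol = 2), 2, c(4, 1), "+"))
  labels <- rep(c("a", "b"), each = n)
  model <- fit_lda(x, labels)

  expect_equal(ncol(model$scaling), 1)          # K - 1 axes
  expect_equal(variance_explained(model), 100)

  # closed-form Fisher direction: W^-1 (m1 - m2)
  m1 <- colMeans(x[labels == "a", ]); m2 <- colMeans(x[labels == "b", ])
  S <- (crossprod(sweep(x[labels == "a", ], 2, m1)) +
          crossprod(sweep(x[labels == "b", ], 2, m2))) / (2 * n - 2)
  fisher <- solve(S, m1 - m2)
  cosine <- abs(sum(fisher * model$scaling[, 1])) /
    sqrt(sum(fisher^2) * sum(model$scaling[, 1]^2))
  expect_gt(cosine, 0.99)

  # class swap: same axis up to sign
  model2 <- fit_lda(x, rev(labels))
  ratio <- model2$scaling[, 1] / model$scaling[, 1]
  expect_equal(abs(ratio[1]), abs(ratio[2]), tolerance = 1e-6)

  # independent cross-check against the reference implementation
  skip_if_not_installed("MASS")
  ref <- MASS::lda(x, grouping = labels)
  scores_ours <- predict_scores(model, x)[, 1]
  scores_ref <- (x %*% ref$scaling)[, 1]
  expect_gt(abs(cor(scores_ours, scores_ref)), 0.9999)
})

test_that("LOOCV classification equals the naive refit oracle on small data", {
  set.seed(33)
  for (rep in 1:5) {
    n_per <- sample(3:4, 3, replace = TRUE)
    x <- do.call(rbind, lapply(seq_along(n_per), function(k)
      matrix(rnorm(2 * n_per[k], mean = 3 * k), ncol = 2)))
    labels <- rep(letters[seq_along(n_per)], n_per)
    rpt <- loocv_classify(x, labels)
    oracle_pred <- oracle_loocv(x, labels)
    oracle_conf <- table(actual = factor(labels, sort(unique(labels))),
                         predicted = factor(oracle_pred, sort(unique(labels))))
    expect_equal(rpt$confusion, unclass(oracle_conf))
  }
})

test_that("perfect separation gives perfect scores; report is coherent", {
  x <- rbind(matrix(rnorm(40), ncol = 2),
             matrix(rnorm(40, mean = 50), ncol = 2))
  labels <- rep(c("a", "b"), each = 20)
  rpt <- loocv_classify(x, labels)
  expect_equal(rpt$accuracy_pct, 100)
  expect_equal(rpt$kappa, 1)
  expect_equal(unname(rowSums(rpt$confusion)), c(20, 20))
  expect_equal(unname(rowSums(rpt$confusion_pct)), c(100, 100))
  expect_equal(sum(diag(rpt$confusion)) / rpt$n * 100, rpt$accuracy_pct)
})

test_that("shuffled labels classify near the proportional-chance rate", {
  set.seed(44)
  n_class <- 10
  x <- matrix(rnorm(500 * 3), ncol = 3)
  labels <- sample(rep(letters[1:n_class], each = 50))
  rpt <- loocv_classify(x, labels)
  expect_lt(abs(rpt$accuracy_pct - 10), 3)  # sum of squared priors = 10%
})

test_that("kappa matches the direct formula", {
  expect_equal(cohens_kappa(diag(c(5, 8, 2))), 1)
  # confusion equal to the outer product of its marginals: kappa 0
  m <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(cohens_kappa(m), 0)
  # hand formula: po = 0.7, pe = 0.5 -> kappa 0.4
  expect_equal(cohens_kappa(matrix(c(40, 20, 10, 30), 2)), 0.4)
  expect_error(cohens_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")
})

test_that("the accuracy interval is the exact binomial interval", {
  expect_equal(accuracy_ci(0, 50)[["lower"]], 0)
  expect_equal(accuracy_ci(50, 50)[["upper"]], 100)
  # independent oracle: binom.test's Clopper-Pearson interval
  ours <- accuracy_ci(248, 394)
  ref <- binom.test(248, 394)$conf.int * 100
  expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
})

test_that("chance levels are rounded class proportions", {
  sizes <- c(Croak = 82, Growl = 102, GrowlRumbleWhoop = 7, Moan = 40,
             MoanGrowl = 24, MoanGrowlRumbleWhoop = 5, MoanHumGrowl = 5,
             MoanWhine = 8, MoanWhoop = 7, Whoop = 114)
  cl <- chance_levels(sizes)
  expect_equal(cl[["Growl"]], 26)
  expect_equal(cl[["Moan"]], 10)
  expect_equal(cl[["Whoop"]], 29)
  expect_equal(cl[["Croak"]], 21)
  expect_equal(unname(chance_levels(c(a = 5, b = 5, c = 5, d = 5))),
               rep(25, 4))
})

test_that("variance shares and contributions behave by construction", {
  set.seed(60)
  # three classes separated along one dominant direction
  x <- rbind(matrix(rnorm(100 * 2), ncol = 2),
             sweep(matrix(rnorm(100 * 2), ncol = 2), 2, c(6, 0.3), "+"),
             sweep(matrix(rnorm(100 * 2), ncol = 2), 2, c(12, 0.6), "+"))
  labels <- rep(c("a", "b", "c"), each = 100)
  model <- fit_lda(x, labels)
  ve <- variance_explained(model)
  expect_equal(sum(ve), 100, tolerance = 1e-6)
  expect_gt(ve[1], ve[2])

  # classes separated only by the first parameter: it dominates LD1
  colnames(x) <- c("DUR", "AE")
  model_d <- fit_lda(x, labels)
  contrib <- ld_contributions(model_d)
  expect_equal(unname(colSums(contrib)), rep(100, ncol(contrib)),
               tolerance = 1e-9)
  expect_gt(contrib["DUR", 1], 90)
})

test_that("Welch's ANOVA matches its direct formula", {
  set.seed(71)
  vals <- c(rnorm(10, 0, 1), rnorm(12, 0.5, 2), rnorm(9, 2, 0.5))
  grps <- rep(c("a", "b", "c"), c(10, 12, 9))
  res <- welch_anova(vals, grps)
  expect_equal(res$F, oracle_welch_f(vals, grps), tolerance = 1e-10)

  # identical group means: tiny F, large p
  same <- c(rnorm(20), rnorm(20))
  g2 <- rep(c("a", "b"), each = 20)
  r2 <- welch_anova(same, g2)
  # two groups: F equals the squared Welch t statistic
  tt <- t.test(same[g2 == "a"], same[g2 == "b"])
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
})

test_that("parameter stability CVs respond to planted site variation", {
  set.seed(80)
  grid <- expand.grid(label = c("Moan", "Growl"),
                      site = c("A", "B", "C"), i = 1:10)
  feats <- data.frame(
    label = grid$label, site = grid$site,
    DUR = 1 + rnorm(nrow(grid), 0, 0.4),   # noisy
    Fpeak = 200 + rnorm(nrow(grid), 0, 4)  # stable
  )
  st <- parameter_stability(feats)
  expect_gt(st$median_cv[["DUR"]], st$median_cv[["Fpeak"]])
  expect_true(all(st$cells$cv >= 0))

  # constant measurements: CV exactly 0
  feats0 <- data.frame(label = "Moan", site = rep(c("A", "B"), each = 3),
                       DUR = 2)
  expect_equal(unname(parameter_stability(feats0)$median_cv[["DUR"]]), 0)

  # scale invariance
  feats10 <- feats; feats10$DUR <- feats10$DUR * 10
  expect_equal(parameter_stability(feats10)$median_cv[["DUR"]],
               st$median_cv[["DUR"]])
})

test_that("report statistics are invariant to row order and rescaling", {
  fm <- synth_feature_matrix(sizes = c(Croak = 20, Growl = 20, Moan = 15),
                             seed = 5)
  x <- fm[, -1]
  r1 <- loocv_classify(x, fm$label)
  perm <- sample(nrow(x))
  r2 <- loocv_classify(x[perm, ], fm$label[perm])
  expect_equal(r1$accuracy_pct, r2$accuracy_pct)
  expect_equal(r1$kappa, r2$kappa)
  expect_equal(r1$chance_levels_pct, r2$chance_levels_pct)

  x_scaled <- x
  x_scaled$Fpeak <- x_scaled$Fpeak * 1000 + 5
  r3 <- loocv_classify(x_scaled, fm$label)
  expect_equal(r1$accuracy_pct, r3$accuracy_pct, tolerance = 1e-8)
  expect_equal(r1$kappa, r3$kappa, tolerance = 1e-8)
})

test_that("synthetic repertoire classification shows the field's structure", {
  fm <- synth_feature_matrix(seed = 101)
  rpt <- loocv_classify(fm[, -1], fm$label)

  per_class <- rpt$per_class_correct_pct
  elemental <- c("Croak", "Growl", "Moan", "Whoop")
  # the tonal low-frequency Moan is the most distinctive elemental type
  expect_equal(names(which.max(per_class[elemental])), "Moan")

  # combinational calls are absorbed by their constituent elementals:
  # more errors flow to constituent than to non-constituent classes
  conf <- rpt$confusion
  for (lbl in c("MoanGrowl", "GrowlRumbleWhoop", "MoanWhoop")) {
    units <- unique(decompose_label(lbl)$units)
    constituents <- intersect(colnames(conf), setdiff(units, lbl))
    others <- setdiff(colnames(conf), c(lbl, constituents))
    expect_gt(max(conf[lbl, constituents]), max(conf[lbl, others]))
  }

  # all but (possibly) the two rarest classes beat their chance levels
  sizes <- rowSums(rpt$confusion)
  rare2 <- names(sort(sizes))[1:2]
  check <- setdiff(names(sizes), rare2)
  expect_true(all(per_class[check] > rpt$chance_levels_pct[check]))
})
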