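#' Prune highly correlated parameters
#'
#' Iteratively resolves every parameter pair whose absolute Pearson
#' correlation exceeds `threshold` by removing, from the most correlated
#' offending pair, the member with the larger mean absolute correlation to
#' all other parameters. Parameters in `always_keep` are never removed
#' (aggregate entropy is conventionally retained despite exceeding the
#' threshold, for its classification value).
#'
#' @param x Numeric data frame or matrix of parameters (columns named).
#' @param threshold Absolute correlation above which a pair is redundant.
#' @param always_keep Character vector of protected parameter names.
#' @return Character vector of retained parameter names, in input order.
#' @export
prune_correlated <- function(x, threshold = 0.7, always_keep = character(0)) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  x <- x[, num, drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 numeric parameters")
  sds <- vapply(x, stats::sd, 0)
  if (any(sds == 0)) {
    stop("constant column(s), correlation undefined: ",
         paste(names(x)[sds == 0], collapse = ", "))
  }
  keep <- names(x)
  repeat {
    r <- abs(stats::cor(x[, keep, drop = FALSE]))
    diag(r) <- 0
    removable <- !(keep %in% always_keep)
    cand <- r
    # a pair is actionable only if at least one member can be removed
    cand[!removable, !removable] <- 0
    if (max(cand) <= threshold) break
    ij <- arrayInd(which.max(cand), dim(cand))
    pair <- keep[c(ij[1, 1], ij[1, 2])]
    pair <- pair[!(pair %in% always_keep)]
    mean_abs <- colMeans(r)[pair]
    drop_name <- pair[which.max(mean_abs)]
    keep <- setdiff(keep, drop_name)
    if (length(keep) < 2) break
  }
  keep
}

# Class means, pooled within-class covariance and priors for a labeled
# numeric matrix. Ridge regularization (eps = 1e-8 * trace/p) is applied
# on demand when the pooled covariance is numerically singular.
lda_moments <- function(x, labels, ridge = TRUE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  n <- nrow(x)
  p <- ncol(x)
  if (length(classes) < 2) stop("need at least 2 classes")
  means <- t(vapply(classes, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                    numeric(p)))
  W <- matrix(0, p, p)
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    if (nrow(xi) < 2) next
    W <- W + crossprod(sweep(xi, 2, colMeans(xi)))
  }
  W <- W / (n - length(classes))
  ok <- tryCatch({ solve(W); TRUE },
                 error = function(e) FALSE)
  ridged <- FALSE
  if (!ok || kappa(W) > 1e12) {
    if (!ridge) stop("pooled within-class covariance is singular")
    W <- W + diag(1e-8 * sum(diag(W)) / p, p)
    ridged <- TRUE
  }
  priors <- as.numeric(table(factor(labels, classes))) / n
  names(priors) <- classes
  list(classes = classes, means = means, W = W, priors = priors,
       n = n, p = p, ridged = ridged)
}

#' Fit a linear discriminant model
#'
#' Computes the discriminant axes as the leading eigenvectors of
#' `W^-1 B`, where `W` is the pooled within-class covariance and `B` the
#' between-class scatter of the class means (weighted by class size).
#' Axes are scaled to unit pooled within-class variance and sorted by
#' descending eigenvalue; there are at most `min(K - 1, p)` axes. Class
#' priors are the observed class proportions. A numerically singular `W`
#' triggers a small ridge fallback with a warning (tiny classes can
#' degenerate), unless `ridge = FALSE`, in which case it is an error.
#'
#' @param x Numeric matrix/data frame of parameters.
#' @param labels Class label per row (coerced to character).
#' @param ridge Allow the ridge fallback for singular covariances.
#' @return An object of class `dfa_model`: `classes`, `means`, `W`,
#'   `priors`, `scaling` (p x d axis matrix), `eigenvalues`, `svd_ridged`.
#' @export
fit_lda <- function(x, labels, ridge = TRUE) {
  x <- as.matrix(x)
  mom <- lda_moments(x, labels, ridge = ridge)
  if (mom$ridged) warning("singular pooled covariance: ridge fallback applied")
  K <- length(mom$classes)
  grand <- colSums(mom$means * mom$priors)
  B <- matrix(0, mom$p, mom$p)
  for (i in seq_len(K)) {
    d <- mom$means[i, ] - grand
    B <- B + mom$priors[i] * tcrossprod(d)
  }
  M <- solve(mom$W, B)
  eg <- eigen(M)
  d <- min(K - 1L, mom$p)
  vals <- Re(eg$values)[seq_len(d)]
  vecs <- Re(eg$vectors)[, seq_len(d), drop = FALSE]
  # scale each axis a so that a' W a = 1
  for (j in seq_len(d)) {
    s <- sqrt(drop(t(vecs[, j]) %*% mom$W %*% vecs[, j]))
    vecs[, j] <- vecs[, j] / s
  }
  vals <- pmax(vals, 0)
  ord <- order(vals, decreasing = TRUE)
  colnames(vecs) <- paste0("LD", seq_len(d))
  structure(
    list(classes = mom$classes, means = mom$means, W = mom$W,
         priors = mom$priors, scaling = vecs[, ord, drop = FALSE],
         eigenvalues = vals[ord], ridged = mom$ridged,
         feature_names = colnames(x)),
    class = "dfa_model"
  )
}

# Gaussian linear discriminant scores (shared covariance, class priors):
# delta_c(x) = x' W^-1 m_c - m_c' W^-1 m_c / 2 + log prior_c.
lda_predict <- function(mom, newx) {
  newx <- as.matrix(newx)
  Winv_m <- solve(mom$W, t(mom$means))          # p x K
  const <- -0.5 * colSums(t(mom$means) * Winv_m) + log(mom$priors)
  scores <- newx %*% Winv_m + matrix(const, nrow(newx), length(mom$classes),
                                     byrow = TRUE)
  mom$classes[max.col(scores, ties.method = "first")]
}

#' Project data onto discriminant axes
#'
#' @param model A fitted [fit_lda()] model.
#' @param x Numeric matrix/data frame with the model's parameters.
#' @return Matrix of discriminant scores (rows x axes).
#' @export
predict_scores <- function(model, x) {
  as.matrix(x) %*% model$scaling
}

#' Leave-one-out cross-validated discriminant classification
#'
#' Classifies every row with a discriminant model fitted to all other
#' rows (Gaussian rule with shared covariance and frequency priors), and
#' assembles the full classification report: confusion matrix (counts and
#' row-normalized percentages), overall accuracy with an exact binomial
#' confidence interval, Cohen's kappa, per-class correct-classification
#' rates and chance levels. Fold-level singular covariances fall back to
#' a small ridge, with one warning.
#'
#' @param x Numeric matrix/data frame of parameters.
#' @param labels Class label per row; every class needs at least 2 rows.
#' @param conf_level Confidence level for the accuracy interval.
#' @return An object of class `dfa_report`: `confusion` (counts, actual x
#'   predicted), `confusion_pct` (row-normalized, integer-rounded),
#'   `accuracy_pct`, `accuracy_ci_pct`, `kappa`, `per_class_correct_pct`,
#'   `chance_levels_pct`, `n`.
#' @export
loocv_classify <- function(x, labels, conf_level = 0.95) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (any(table(labels) < 2)) stop("every class needs at least 2 rows")
  n <- nrow(x)
  pred <- character(n)
  ridged_any <- FALSE
  for (i in seq_len(n)) {
    mom <- lda_moments(x[-i, , drop = FALSE], labels[-i])
    ridged_any <- ridged_any || mom$ridged
    pred[i] <- lda_predict(mom, x[i, , drop = FALSE])
  }
  if (ridged_any) warning("ridge fallback applied in at least one fold")
  classes <- sort(unique(labels))
  confusion <- table(actual = factor(labels, classes),
                     predicted = factor(pred, classes))
  correct <- sum(diag(confusion))
  acc <- correct / n * 100
  ci <- accuracy_ci(correct, n, conf_level)
  per_class <- diag(confusion) / rowSums(confusion) * 100
  structure(
    list(confusion = unclass(confusion),
         confusion_pct = round_half_up(sweep(unclass(confusion), 1,
                                             rowSums(confusion), "/") * 100, 0),
         accuracy_pct = acc,
         accuracy_ci_pct = ci,
         kappa = cohens_kappa(confusion),
         per_class_correct_pct = per_class,
         chance_levels_pct = chance_levels(rowSums(confusion)),
         n = n),
    class = "dfa_report"
  )
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement and `p_e` the agreement expected from the row and
#' column marginals.
#'
#' @param confusion Square count matrix (actual x predicted).
#' @return Kappa (unitless).
#' @export
cohens_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  stopifnot(nrow(m) == ncol(m))
  total <- sum(m)
  if (total <= 0) stop("empty confusion matrix")
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (p_e >= 1) stop("expected agreement is 1: kappa undefined")
  (p_o - p_e) / (1 - p_e)
}

#' Exact binomial confidence interval for classification accuracy
#'
#' Clopper--Pearson interval, computed from beta quantiles, returned in
#' percent.
#'
#' @param correct Number of correctly classified samples.
#' @param total Total samples.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)` in percent.
#' @export
accuracy_ci <- function(correct, total, level = 0.95) {
  stopifnot(correct >= 0, correct <= total, total > 0)
  a <- (1 - level) / 2
  lower <- if (correct == 0) 0 else stats::qbeta(a, correct, total - correct + 1)
  upper <- if (correct == total) 1 else
    stats::qbeta(1 - a, correct + 1, total - correct)
  c(lower = lower * 100, upper = upper * 100)
}

#' Chance classification levels from class sizes
#'
#' Baseline correct-classification rate per class under frequency-prior
#' assignment: the class's share of the sample, in percent, rounded half
#' away from zero to integers (102 of 394 -> 26%).
#'
#' @param sizes Named vector of class sizes.
#' @return Named numeric vector of percentages.
#' @export
chance_levels <- function(sizes) {
  stopifnot(all(sizes > 0))
  round_half_up(sizes / sum(sizes) * 100, 0)
}

#' Variance explained per discriminant axis
#'
#' @param model A fitted [fit_lda()] model.
#' @return Percent of between-class variance captured by each axis
#'   (eigenvalue shares, summing to 100).
#' @export
variance_explained <- function(model) {
  ev <- model$eigenvalues
  ev / sum(ev) * 100
}

#' Parameter contributions to each discriminant axis
#'
#' Contribution of each parameter to an axis, defined as its normalized
#' absolute standardized coefficient: coefficients are standardized by the
#' pooled within-class standard deviations, and the absolute values on
#' each axis are scaled to sum to 100%.
#'
#' @param model A fitted [fit_lda()] model.
#' @return Matrix (parameter x axis) of percentages; columns sum to 100.
#' @export
ld_contributions <- function(model) {
  sds <- sqrt(diag(model$W))
  std <- abs(model$scaling * sds)
  out <- sweep(std, 2, colSums(std), "/") * 100
  rownames(out) <- model$feature_names
  out
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' One-way ANOVA not assuming equal group variances, used to test whether
#' discriminant scores differ among call types.
#'
#' @param values Numeric response vector.
#' @param groups Group label per value; at least 2 groups with at least 2
#'   members each.
#' @return A list with `F`, `df1`, `df2` and `p`.
#' @export
welch_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  if (all(tapply(values, groups, stats::var) == 0)) {
    stop("zero within-group variance in every group")
  }
  fit <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = fit$p.value)
}

#' Parameter stability across sites as coefficients of variation
#'
#' For each (parameter, call type, site) cell with at least `min_n`
#' measurements and a positive mean, computes the coefficient of
#' variation sd/mean, then summarizes each parameter by the median CV
#' over all (type, site) cells. Stable parameters (e.g. peak frequency,
#' aggregate entropy) show low median CVs; duration and bandwidth
#' measures are typically more variable.
#'
#' @param features Data frame with `label`, `site` and numeric parameter
#'   columns.
#' @param params Parameter column names; defaults to all numeric columns.
#' @param min_n Minimum measurements per cell (default 2).
#' @return A list with `cells` (long data frame: parameter, label, site,
#'   n, mean, sd, cv) and `median_cv` (named vector per parameter).
#' @export
parameter_stability <- function(features, params = NULL, min_n = 2) {
  if (is.null(params)) {
    params <- names(features)[vapply(features, is.numeric, TRUE)]
    params <- setdiff(params, c("quality", "snr"))
  }
  rows <- list()
  skipped <- 0L
  for (pm in params) {
    agg <- stats::aggregate(features[[pm]],
                            by = list(label = features$label,
                                      site = features$site),
                            FUN = function(v) c(n = length(v), mean = mean(v),
                                                sd = stats::sd(v)))
    stats_m <- agg$x
    for (i in seq_len(nrow(agg))) {
      n_i <- stats_m[i, "n"]
      mean_i <- stats_m[i, "mean"]
      if (n_i < min_n) next
      if (mean_i <= 0) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pm, label = agg$label[i], site = agg$site[i],
        n = n_i, mean = mean_i, sd = stats_m[i, "sd"],
        cv = stats_m[i, "sd"] / mean_i)
    }
  }
  if (skipped > 0) warning(skipped, " cell(s) with non-positive mean excluded")
  cells <- do.call(rbind, rows)
  med <- tapply(cells$cv, cells$parameter, stats::median)
  list(cells = cells, median_cv = med[params[params %in% names(med)]])
}
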