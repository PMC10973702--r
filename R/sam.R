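#' Configuration for classifier-based (statistical agnostic) selection
#'
#' Per-feature relevance is scored by feeding each feature alone into a
#' supervised linear classifier over many balanced resamples, correcting the
#' resubstitution accuracy by the one-dimensional concentration bound, and
#' ranking features with a proportion test against the mean accuracy.
#'
#' @param n_permutations balanced resamples per feature (study setting: 1000;
#'   scale down for quick runs).
#' @param classifier `"svm"` (linear SVM) or `"lda"` (closed-form univariate
#'   Gaussian discriminant, orders of magnitude faster and equivalent for a
#'   single standardized feature).
#' @param eta significance level of the d = 1 bound.
#' @param corrected use bound-corrected accuracies (default) or raw
#'   resubstitution accuracies throughout.
#' @param seed master seed.
#' @return a `sam_config` list.
#' @export
sam_config <- function(n_permutations = 1000, classifier = c("svm", "lda"),
                       eta = 0.05, corrected = TRUE, seed = 1L) {
  stopifnot(n_permutations >= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 classifier = match.arg(classifier), eta = eta,
                 corrected = isTRUE(corrected), seed = as.integer(seed)),
            class = "sam_config")
}

fit_univariate_lda <- function(x, y) {
  # midpoint rule between class means; direction from the mean ordering
  m1 <- mean(x[y == 1]); m0 <- mean(x[y == 0])
  w <- if (m1 >= m0) 1 else -1
  structure(list(w = w, b = w * (m1 + m0) / 2, levels = c(0L, 1L)),
            class = "linear_separator")
}

#' Bound-corrected single-feature classification accuracy
#'
#' Mean over `n_permutations` balanced draws of the resubstitution accuracy
#' of a linear classifier trained on the single feature, minus the
#' concentration bound at d = 1 (when `corrected`). Each draw takes
#' `min(n1, n0)` subjects per class without replacement ("randomly modifying
#' the position of the samples" with balancing), so the resample — not a
#' label shuffle — is the randomness source.
#'
#' @param table a [feature_table()]. @param feature column name or index.
#' @param config a [sam_config()].
#' @return mean (corrected) accuracy pi-hat.
#' @export
per_feature_accuracy <- function(table, feature, config = sam_config()) {
  y <- table$labels
  if (length(unique(y)) < 2) stop("need both classes", call. = FALSE)
  x <- table$values[, feature]
  n_bal <- min(sum(y == 1), sum(y == 0))
  mu1 <- if (config$corrected)
    concentration_bound(2 * n_bal, 1, config$eta) else 0
  set.seed(config$seed)
  acc <- vapply(seq_len(config$n_permutations), function(i) {
    idx <- c(sample(which(y == 1), n_bal), sample(which(y == 0), n_bal))
    xs <- matrix(x[idx], ncol = 1); ys <- y[idx]
    model <- if (config$classifier == "svm")
      fit_linear_svm(xs, ys) else fit_univariate_lda(xs, ys)
    mean(predict_class(model, xs) == ys)
  }, 0)
  mean(acc) - mu1
}

#' Accuracies for every feature
#' @param table a [feature_table()]. @param config a [sam_config()].
#' @return named numeric vector of pi-hat per feature.
#' @export
sam_accuracies <- function(table, config = sam_config()) {
  out <- vapply(seq_along(table$feature_names), function(j) {
    cfg <- config
    cfg$seed <- config$seed + j # independent stream per feature
    per_feature_accuracy(table, j, cfg)
  }, 0)
  names(out) <- table$feature_names
  out
}

#' Proportion test over per-feature accuracies
#'
#' The reference proportion `pi0` is the mean of all accuracies, `l` the
#' number of accuracies strictly above it, `sigma0 = sqrt(pi0 (1 - pi0) / l)`,
#' and each feature's statistic `z = (pi_hat - pi0) / sigma0`, with an
#' upper-tail standard-normal p-value (relevance means accuracy above the
#' average).
#'
#' @param accuracies named numeric vector of per-feature accuracies in [0,1]
#'   (bound-corrected values may dip below 0; the test only uses their
#'   ordering around the mean). `pi0` must lie in (0, 1).
#' @return data.frame: feature, pi_hat, pi0, l, sigma0, z, p_value.
#' @export
proportion_test <- function(accuracies) {
  stopifnot(length(accuracies) >= 2)
  pi0 <- mean(accuracies)
  l <- sum(accuracies > pi0)
  if (l == 0) stop("degenerate: no accuracy above the mean", call. = FALSE)
  if (pi0 <= 0 || pi0 >= 1)
    stop("mean accuracy outside (0, 1); sigma0 undefined", call. = FALSE)
  sigma0 <- sqrt(pi0 * (1 - pi0) / l)
  z <- (accuracies - pi0) / sigma0
  data.frame(feature = names(accuracies), pi_hat = unname(accuracies),
             pi0 = pi0, l = l, sigma0 = sigma0, z = unname(z),
             p_value = stats::pnorm(unname(z), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Select features by the proportion test
#' @param results output of [proportion_test()].
#' @param threshold keep `p_value < threshold`.
#' @return selected rows, descending z (ties broken by feature name).
#' @export
select_sam <- function(results, threshold = 0.05) {
  stopifnot(nrow(results) > 0)
  ord <- order(-results$z, results$feature)
  out <- results[ord, , drop = FALSE]
  out[out$p_value < threshold, , drop = FALSE]
}

#' Partition two selected-feature sets
#'
#' @param parametric_set,sam_set character vectors of feature names.
#' @return `list(both, parametric_only, sam_only, union)`.
#' @export
combine_selections <- function(parametric_set, sam_set) {
  list(both = sort(intersect(parametric_set, sam_set)),
       parametric_only = sort(setdiff(parametric_set, sam_set)),
       sam_only = sort(setdiff(sam_set, parametric_set)),
       union = sort(union(parametric_set, sam_set)))
}
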