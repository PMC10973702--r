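#' Concentration-inequality upper bound for linear classifiers
#'
#' The worst-case gap between resubstitution (training) error and actual
#' error of a linear classifier, at significance level `eta`:
#' \deqn{\mu = \sqrt{\frac{1}{2n}\,\ln\frac{2\sum_{k=0}^{d-1}\binom{n-1}{k}}{\eta}}}
#' where `n` is the sample count and `d` the feature dimension. The binomial
#' sum is evaluated in log space (log-sum-exp over `lchoose`), since e.g.
#' C(111, 8) is ~4.4e11; an exact-integer path is available for cross-checks.
#' At `d = 1` the sum collapses to 1 and the expression reduces to the
#' Hoeffding bound `sqrt(ln(2/eta)/(2n))`.
#'
#' The bound is strictly increasing in `d` and decreasing in `n` in the
#' regimes used here, which is what drives the preference for few features
#' under bound-corrected resubstitution.
#'
#' @param n sample count (>= 2).
#' @param d feature dimension, `1 <= d <= n`.
#' @param eta significance level in (0, 1), default 0.05.
#' @param method `"log"` (default, log-sum-exp) or `"exact"` (integer
#'   arithmetic via cumulative sums of doubles, valid for small n).
#' @return the bound, per unit (multiply by 100 for percentage points).
#' @export
concentration_bound <- function(n, d, eta = 0.05, method = c("log", "exact")) {
  method <- match.arg(method)
  stopifnot(n >= 2, eta > 0, eta < 1)
  if (d < 1 || d > n) stop("require 1 <= d <= n", call. = FALSE)
  k <- 0:(d - 1)
  if (method == "log") {
    lb <- lchoose(n - 1, k)
    mx <- max(lb)
    log_sum <- mx + log(sum(exp(lb - mx)))
  } else {
    log_sum <- log(sum(choose(n - 1, k)))
  }
  sqrt((log(2) + log_sum - log(eta)) / (2 * n))
}

#' PAC-Bayes dropout bound
#'
#' Upper bound on the actual loss of a stochastic (dropout-regularized)
#' classifier, minimized over a grid of k inverse-temperature values
#' \eqn{\lambda}:
#' \deqn{\mu = \min_i \frac{1}{1 - 1/(2\lambda_i)}\hat L_Q +
#'   \frac{1}{1 - 1/(2\lambda_i)} \frac{\lambda_i L_{max}}{n}
#'   \left(\frac{(1-\alpha)^q}{2}\lVert\Theta\rVert^2 + \ln\frac{k}{\eta}\right)}
#' The dropout rate \eqn{\alpha} attenuates the parameter-norm complexity
#' term; at \eqn{\alpha = 1} the norm drops out entirely. The exponent `q` on
#' `(1 - alpha)` is configurable (`dropout_exponent`, default 1).
#'
#' @param L_hat empirical loss in `[0, L_max]`.
#' @param theta_norm_sq squared L2 norm of the flattened parameter vector.
#' @param n sample count.
#' @param alpha dropout rate in `[0, 1]`.
#' @param lambda_grid grid of lambda values, all > 1/2; default 20 evenly
#'   spaced values on (0.5, 10].
#' @param eta significance level, default 0.05.
#' @param L_max loss ceiling, default 1.
#' @param dropout_exponent exponent on `(1 - alpha)`, default 1.
#' @return `list(bound, lambda, per_lambda)`: the minimized bound, the
#'   minimizing lambda, and the full grid evaluation.
#' @export
pac_bayes_bound <- function(L_hat, theta_norm_sq, n, alpha = 0.5,
                            lambda_grid = seq(0.5 + 1e-6, 10, length.out = 20),
                            eta = 0.05, L_max = 1, dropout_exponent = 1) {
  stopifnot(length(lambda_grid) >= 1, alpha >= 0, alpha <= 1,
            L_hat >= 0, L_hat <= L_max, n >= 1)
  if (any(lambda_grid <= 0.5)) stop("all lambda must exceed 1/2", call. = FALSE)
  k <- length(lambda_grid)
  fac <- 1 / (1 - 1 / (2 * lambda_grid))
  complexity <- ((1 - alpha)^dropout_exponent / 2) * theta_norm_sq + log(k / eta)
  vals <- fac * L_hat + fac * (lambda_grid * L_max / n) * complexity
  i <- which.min(vals)
  list(bound = vals[i], lambda = lambda_grid[i], per_lambda = vals)
}

#' Confusion matrix from labels and predictions
#' @param truth,predicted binary vectors (1 = positive/case).
#' @return `list(TP, TN, FP, FN)`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(TP = sum(truth == 1 & predicted == 1),
       TN = sum(truth == 0 & predicted == 0),
       FP = sum(truth == 0 & predicted == 1),
       FN = sum(truth == 1 & predicted == 0))
}

#' Rank-based AUC with midrank tie handling
#' @param decision numeric scores, higher = more case-like.
#' @param truth binary labels.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(decision, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes for AUC", call. = FALSE)
  r <- rank(decision, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-derived performance metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), balanced accuracy
#' (their mean), and rank-statistic AUC when decision values are supplied.
#' The positive class is the case group.
#'
#' @param cm a [confusion_matrix()].
#' @param decision optional decision values for AUC.
#' @param truth labels matching `decision`.
#' @return `list(balanced_accuracy, sensitivity, specificity, auc)`.
#' @export
compute_metrics <- function(cm, decision = NULL, truth = NULL) {
  if (cm$TP + cm$FN == 0 || cm$TN + cm$FP == 0)
    stop("metrics undefined without both classes", call. = FALSE)
  sens <- cm$TP / (cm$TP + cm$FN)
  spec <- cm$TN / (cm$TN + cm$FP)
  auc <- if (!is.null(decision)) rank_auc(decision, truth) else NA_real_
  list(balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec, auc = auc)
}

#' Stratified k-fold assignments
#'
#' Subjects are shuffled within class and dealt round-robin, so per-fold
#' class counts are within one of proportional and every subject lands in
#' exactly one test fold. Deterministic given the seed.
#'
#' @param labels binary vector.
#' @param k folds (each class must have >= k members).
#' @param seed integer seed.
#' @return integer fold id per subject.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1L) {
  if (min(table(labels)) < k)
    stop("each class needs at least k samples", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    # continue the round-robin across classes so remainders land on
    # different folds and fold sizes stay within one of each other
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}

#' Stratified k-fold cross-validation of a classifier
#'
#' `model_factory(X, y)` must return a fitted model understood by
#' [decision_values()] and [predict_class()]. When `d_reduce` is given, a PLS
#' model with that many components is fitted per fold on the training part
#' only and both parts are projected through it, so test labels never touch
#' the reduction (`leaky = TRUE` deliberately fits the reduction on the full
#' table first — a cautionary mode demonstrating selection leakage).
#'
#' @param table a normalized, NA-free [feature_table()].
#' @param model_factory function `(X, y) -> model`.
#' @param k folds, default 10.
#' @param seed fold-assignment seed.
#' @param d_reduce optional PLS component count applied per fold.
#' @param leaky fit the reduction on all data first (default FALSE).
#' @return class `validation_report`: per-fold train/test metrics plus their
#'   mean and SD.
#' @export
stratified_kfold_validate <- function(table, model_factory, k = 10, seed = 1L,
                                      d_reduce = NULL, leaky = FALSE) {
  y <- table$labels
  fold <- stratified_folds(y, k, seed)
  X_all <- table$values
  pls_all <- if (!is.null(d_reduce) && leaky) fit_pls(table, d_reduce) else NULL
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f; te <- !tr
    Xtr <- X_all[tr, , drop = FALSE]; Xte <- X_all[te, , drop = FALSE]
    if (!is.null(d_reduce)) {
      if (leaky) {
        Xtr <- pls_transform(pls_all, Xtr); Xte <- pls_transform(pls_all, Xte)
      } else {
        pm <- fit_pls_matrix(Xtr, y[tr], d_reduce)
        Xtr <- pls_transform(pm, Xtr); Xte <- pls_transform(pm, Xte)
      }
    }
    model <- model_factory(Xtr, y[tr])
    ev <- function(X, yy) {
      dv <- decision_values(model, X)
      compute_metrics(confusion_matrix(yy, predict_class(model, X)), dv, yy)
    }
    list(train = ev(Xtr, y[tr]), test = ev(Xte, y[te]))
  })
  summarize_folds <- function(which) {
    m <- do.call(rbind, lapply(per_fold, function(f) unlist(f[[which]])))
    list(mean = colMeans(m), sd = apply(m, 2, stats::sd), per_fold = m)
  }
  structure(list(scheme = sprintf("%d-fold", k),
                 train = summarize_folds("train"),
                 test = summarize_folds("test"),
                 folds = fold),
            class = "validation_report")
}

#' Resubstitution with upper-bound correction (RUB)
#'
#' Fits the model on the entire sample, measures resubstitution (training)
#' metrics, and subtracts an analytic worst-case generalization-gap bound to
#' report "actual" worst-case performance. Corrected values are reported
#' as-is — not floored at chance — since the bound is a worst case, not an
#' estimate. Sensitivity and specificity receive the same subtraction as
#' balanced accuracy (a documented heuristic: their errors track the
#' classification error); AUC is reported uncorrected.
#'
#' @param table a normalized [feature_table()].
#' @param model_factory function `(X, y) -> model`.
#' @param bound either a precomputed numeric bound or `NULL` to compute the
#'   concentration bound at `d = ncol` and `n = nrow`.
#' @param eta significance level for the computed bound.
#' @param d_reduce optional PLS components fitted on the full table (RUB uses
#'   all data by construction, so there is no held-out part to protect).
#' @return class `validation_report` with empirical and corrected metrics and
#'   the bound value used.
#' @export
rub_validate <- function(table, model_factory, bound = NULL, eta = 0.05,
                         d_reduce = NULL) {
  y <- table$labels
  X <- table$values
  if (!is.null(d_reduce)) {
    pm <- fit_pls_matrix(X, y, d_reduce)
    X <- pls_transform(pm, X)
  }
  if (is.null(bound)) bound <- concentration_bound(nrow(X), ncol(X), eta)
  model <- model_factory(X, y)
  dv <- decision_values(model, X)
  emp <- compute_metrics(confusion_matrix(y, predict_class(model, X)), dv, y)
  corrected <- emp
  for (nm in c("balanced_accuracy", "sensitivity", "specificity"))
    corrected[[nm]] <- emp[[nm]] - bound
  structure(list(scheme = "RUB", empirical = emp, corrected = corrected,
                 bound_value = bound, d = ncol(X), n = nrow(X)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", x$scheme, "\n")
  if (x$scheme == "RUB") {
    cat(sprintf("  bound mu = %.4f (n=%d, d=%d)\n", x$bound_value, x$n, x$d))
    cat(sprintf("  empirical bal.acc %.3f -> corrected %.3f\n",
                x$empirical$balanced_accuracy, x$corrected$balanced_accuracy))
  } else {
    cat(sprintf("  test bal.acc %.3f +/- %.3f\n",
                x$test$mean["balanced_accuracy"], x$test$sd["balanced_accuracy"]))
  }
  invisible(x)
}

#' Balanced subsampling permutation harness
#'
#' Repeats an end-to-end evaluation on balanced subsamples: each iteration
#' draws, without replacement, `min(n1, n0)` subjects per class (e.g. 112 of
#' 114), runs `pipeline_fn` on the subsample, and records the metrics it
#' returns. Reported as mean and SD over iterations.
#'
#' @param table a [feature_table()].
#' @param pipeline_fn function `(feature_table) -> named numeric vector`.
#' @param n_permutations iterations, default 1000.
#' @param seed master seed; per-iteration seeds derive from it.
#' @return `list(mean, sd, per_iteration)`.
#' @export
balanced_permutation_harness <- function(table, pipeline_fn,
                                         n_permutations = 1000, seed = 1L) {
  stopifnot(n_permutations >= 1)
  y <- table$labels
  n_bal <- min(sum(y == 1), sum(y == 0))
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, n_permutations)
  rows <- lapply(seq_len(n_permutations), function(i) {
    set.seed(iter_seeds[i])
    idx <- c(sample(which(y == 1), n_bal), sample(which(y == 0), n_bal))
    sub <- feature_table(table$values[idx, , drop = FALSE], y[idx],
                         table$subject_ids[idx], table$feature_names,
                         normalized = table$normalized)
    pipeline_fn(sub)
  })
  m <- do.call(rbind, rows)
  list(mean = colMeans(m),
       sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, ncol(m)),
       per_iteration = m)
}

#' Sweep PLS component count under CV and RUB
#'
#' For each d, evaluates the classifier on d PLS components under stratified
#' k-fold CV (reduction refit per fold) and under RUB with the concentration
#' bound at that d. The bound grows with d while empirical accuracy
#' plateaus, so corrected accuracy eventually decreases — the mechanism
#' favouring parsimonious representations at small n.
#'
#' @param table normalized [feature_table()].
#' @param d_range component counts to evaluate.
#' @param model_factory classifier factory, default linear SVM.
#' @param k CV folds. @param eta bound significance level. @param seed seed.
#' @return data.frame: d, cv test balanced accuracy (mean, sd), empirical and
#'   corrected RUB balanced accuracy, bound.
#' @export
sweep_components <- function(table, d_range, model_factory = svm_factory(),
                             k = 10, eta = 0.05, seed = 1L) {
  stopifnot(all(d_range >= 1), all(d_range < ncol(table$values)))
  rows <- lapply(d_range, function(d) {
    cv <- stratified_kfold_validate(table, model_factory, k, seed, d_reduce = d)
    rub <- rub_validate(table, model_factory, eta = eta, d_reduce = d)
    data.frame(d = d,
               cv_test_bacc = unname(cv$test$mean["balanced_accuracy"]),
               cv_test_sd = unname(cv$test$sd["balanced_accuracy"]),
               rub_empirical_bacc = rub$empirical$balanced_accuracy,
               rub_corrected_bacc = rub$corrected$balanced_accuracy,
               bound = rub$bound_value)
  })
  do.call(rbind, rows)
}

#' Sweep balanced sample size at fixed dimensionality
#'
#' Draws repeated balanced subsamples of each size, evaluates RUB (and
#' optionally CV) at a fixed PLS dimension, and averages. The bound shrinks
#' with n at fixed d, so corrected accuracy rises with sample size on data
#' with a stable effect.
#'
#' @param table normalized [feature_table()].
#' @param sizes even total sample sizes (>= 4).
#' @param d PLS components, default 4.
#' @param model_factory classifier factory.
#' @param n_rep subsample draws per size. @param eta,seed as elsewhere.
#' @return data.frame: size, mean empirical and corrected RUB balanced
#'   accuracy, bound at that size.
#' @export
sweep_sample_size <- function(table, sizes, d = 4, model_factory = svm_factory(),
                              n_rep = 10, eta = 0.05, seed = 1L) {
  stopifnot(all(sizes %% 2 == 0), all(sizes >= 4))
  y <- table$labels
  set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    per <- replicate(n_rep, {
      idx <- c(sample(which(y == 1), sz / 2), sample(which(y == 0), sz / 2))
      sub <- feature_table(table$values[idx, , drop = FALSE], y[idx],
                           normalized = table$normalized)
      r <- rub_validate(sub, model_factory, eta = eta, d_reduce = d)
      c(emp = r$empirical$balanced_accuracy,
        corr = r$corrected$balanced_accuracy)
    })
    data.frame(size = sz,
               rub_empirical_bacc = mean(per["emp", ]),
               rub_corrected_bacc = mean(per["corr", ]),
               bound = concentration_bound(sz, d, eta))
  })
  do.call(rbind, rows)
}
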