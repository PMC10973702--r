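#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]: data source (a CSV
#' path or a [sim_config()]), preprocessing, selection mode, classifier,
#' validation schemes, bound settings, and the master seed. Defaults mirror
#' the study design: 10 folds, eta 0.05, 1000 permutations (scale
#' `n_permutations` down for quick runs), 18 MLP epochs at learning rate
#' 0.001.
#'
#' @param data a [sim_config()], a [feature_table()], or a CSV path readable
#'   by [read_feature_table()].
#' @param preprocess a [preprocess_config()], or `NULL` to skip the exclusion
#'   cascade (data already clean; it is then only renormalized if needed).
#' @param selection one of `"parametric"`, `"sam"`, `"both"`, `"pls"`.
#' @param classifier `"svm"` or `"mlp"`.
#' @param schemes validation schemes, subset of `c("cv", "rub")`.
#' @param d_pls PLS components when `selection = "pls"`.
#' @param selection_threshold p-value threshold for selected features.
#' @param n_permutations SAM permutations.
#' @param sam_classifier classifier inside SAM scoring (`"lda"` default for
#'   speed; `"svm"` matches the heavier study setting).
#' @param k CV folds. @param eta bound significance level.
#' @param seed master seed for all stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(data, preprocess = preprocess_config(),
                            selection = c("both", "parametric", "sam", "pls"),
                            classifier = c("svm", "mlp"),
                            schemes = c("cv", "rub"),
                            d_pls = 4, selection_threshold = 0.05,
                            n_permutations = 1000,
                            sam_classifier = "lda",
                            k = 10, eta = 0.05, seed = 1L) {
  selection <- match.arg(selection)
  classifier <- match.arg(classifier)
  stopifnot(all(schemes %in% c("cv", "rub")), length(schemes) >= 1)
  structure(list(data = data, preprocess = preprocess, selection = selection,
                 classifier = classifier, schemes = schemes, d_pls = d_pls,
                 selection_threshold = selection_threshold,
                 n_permutations = n_permutations,
                 sam_classifier = sam_classifier,
                 k = k, eta = eta, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_table <- function(data) {
  if (inherits(data, "feature_table")) data
  else if (inherits(data, "sim_config")) simulate_table(data)
  else if (is.character(data)) read_feature_table(data)
  else stop("unsupported data source", call. = FALSE)
}

pipeline_factory <- function(config) {
  if (config$classifier == "svm") svm_factory()
  else mlp_factory(mlp_spec(seed = config$seed))
}

#' Run the end-to-end analysis
#'
#' Preprocess, select or extract features per the configured mode, classify,
#' and validate under the requested schemes. RUB uses the concentration
#' bound at the post-selection dimensionality. Every random stage is seeded
#' from the master seed; reruns with the same config are identical.
#'
#' @param config a [pipeline_config()].
#' @return `list(table, report, selected, results)` where `results` is a
#'   named list of `validation_report`s per scheme, each stage error tagged
#'   with its stage name.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  raw <- stage("data", resolve_table(config$data))
  if (!is.null(config$preprocess) && !raw$normalized) {
    pp <- stage("preprocess", apply_exclusions(raw, config$preprocess))
    table <- pp$table; report <- pp$report
  } else {
    table <- if (raw$normalized) raw else stage("preprocess", renormalize(raw))
    report <- NULL
  }

  selected <- NULL
  d_used <- NULL
  if (config$selection == "pls") {
    work <- table
    d_used <- config$d_pls
  } else {
    par_set <- sam_set <- character(0)
    if (config$selection %in% c("parametric", "both")) {
      uni <- stage("univariate_selection", univariate_selection(table))
      par_set <- rank_features(uni, config$selection_threshold)$feature
    }
    if (config$selection %in% c("sam", "both")) {
      acc <- stage("sam_selection", sam_accuracies(
        table, sam_config(n_permutations = config$n_permutations,
                          classifier = config$sam_classifier,
                          eta = config$eta, seed = config$seed)))
      sam_set <- select_sam(proportion_test(acc),
                            config$selection_threshold)$feature
    }
    selected <- combine_selections(par_set, sam_set)
    keep <- switch(config$selection,
                   parametric = par_set, sam = sam_set, both = selected$union)
    if (!length(keep)) stop("[selection] no feature passed the threshold",
                            call. = FALSE)
    work <- feature_table(table$values[, keep, drop = FALSE], table$labels,
                          table$subject_ids, keep, normalized = TRUE)
  }

  factory <- pipeline_factory(config)
  results <- list()
  if ("cv" %in% config$schemes) {
    results$cv <- stage("validation", stratified_kfold_validate(
      work, factory, k = config$k, seed = config$seed, d_reduce = d_used))
  }
  if ("rub" %in% config$schemes) {
    results$rub <- stage("validation", rub_validate(
      work, factory, eta = config$eta, d_reduce = d_used))
  }
  list(table = table, report = report, selected = selected,
       results = results, config = config)
}

#' Compare the PAC-Bayes dropout bound across dropout rates
#'
#' Fits the classifier on the full sample, measures the empirical
#' (resubstitution) balanced error, and evaluates the PAC-Bayes dropout
#' bound at each dropout rate alongside the concentration bound at the same
#' (n, d) — the two corrections a practitioner would weigh against each
#' other. Reported as corrected accuracies (empirical minus bound).
#'
#' @param table a normalized [feature_table()].
#' @param model_factory classifier factory.
#' @param alphas dropout rates in [0, 1].
#' @param eta significance level.
#' @param lambda_grid grid for the PAC-Bayes minimization.
#' @return data.frame: alpha, pac_bound, pac_corrected_bacc, plus attributes
#'   `"concentration_bound"` and `"empirical_bacc"`.
#' @export
compare_bounds <- function(table, model_factory = svm_factory(),
                           alphas = c(0, 0.25, 0.5, 0.75, 0.95),
                           eta = 0.05,
                           lambda_grid = seq(0.5 + 1e-6, 10, length.out = 20)) {
  if (!length(alphas)) stop("empty alpha list", call. = FALSE)
  if (any(alphas < 0 | alphas > 1)) stop("alpha outside [0, 1]", call. = FALSE)
  X <- table$values; y <- table$labels
  model <- model_factory(X, y)
  emp <- compute_metrics(confusion_matrix(y, predict_class(model, X)))
  L_hat <- 1 - emp$balanced_accuracy
  tn2 <- theta_norm_sq(model)
  rows <- lapply(alphas, function(a) {
    pb <- pac_bayes_bound(L_hat, tn2, nrow(X), alpha = a,
                          lambda_grid = lambda_grid, eta = eta)
    data.frame(alpha = a, pac_bound = pb$bound,
               pac_corrected_bacc = emp$balanced_accuracy - pb$bound)
  })
  out <- do.call(rbind, rows)
  # for d >= n the linear-dichotomy count saturates at 2^(n-1), which is the
  # d = n value, so capping d at n evaluates the bound exactly
  attr(out, "concentration_bound") <-
    concentration_bound(nrow(X), min(ncol(X), nrow(X)), eta)
  attr(out, "empirical_bacc") <- emp$balanced_accuracy
  out
}
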