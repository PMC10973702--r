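test_that("log-space and exact-integer bound evaluations agree", {
  for (n in c(20, 50, 112, 500)) {
    for (d in c(1, 2, 4, 9, min(15, n))) {
      expect_equal(concentration_bound(n, d, 0.05, method = "log"),
                   concentration_bound(n, d, 0.05, method = "exact"),
                   tolerance = 1e-12)
    }
  }
})

test_that("the bound collapses to the Hoeffding form at d = 1", {
  for (n in c(20, 112, 200, 1000)) {
    expect_equal(concentration_bound(n, 1, 0.05),
                 sqrt(log(2 / 0.05) / (2 * n)), tolerance = 1e-12)
  }
  expect_equal(round(concentration_bound(200, 1, 0.05), 4), 0.0960)
})

test_that("the bound is increasing in d and decreasing in n", {
  mus_d <- sapply(1:20, function(d) concentration_bound(112, d, 0.05))
  expect_true(all(diff(mus_d) > 0))
  for (d in c(1, 4, 9)) {
    mus_n <- sapply(c(20, 30, 40, 64, 88, 112, 500), function(n)
      concentration_bound(n, d, 0.05))
    expect_true(all(diff(mus_n) < 0))
  }
  expect_error(concentration_bound(10, 11, 0.05), "d <= n")
  expect_error(concentration_bound(50, 0, 0.05), "d")
})

test_that("PAC-Bayes bound matches a brute-force grid oracle and its algebraic limits", {
  grid <- seq(0.5 + 1e-6, 10, length.out = 20)
  spec <- list(n = 112, L_hat = 0.3, theta = 4, alpha = 0.5, eta = 0.05)
  got <- pac_bayes_bound(spec$L_hat, spec$theta, spec$n, spec$alpha, grid, spec$eta)
  # independent exhaustive evaluation
  k <- length(grid)
  oracle <- min(sapply(grid, function(lam) {
    fac <- 1 / (1 - 1 / (2 * lam))
    fac * spec$L_hat + fac * (lam / spec$n) *
      (((1 - spec$alpha) / 2) * spec$theta + log(k / spec$eta))
  }))
  expect_equal(got$bound, oracle, tolerance = 1e-10)
  # alpha = 1 eliminates the parameter-norm term entirely
  a1 <- pac_bayes_bound(0.2, 1e6, 112, alpha = 1, grid)
  a1_ref <- pac_bayes_bound(0.2, 0, 112, alpha = 0, grid)
  # with alpha = 1 the norm is irrelevant; compare to norm-zero evaluation
  expect_equal(a1$bound, a1_ref$bound, tolerance = 1e-12)
  # zero loss, zero norm: pure ln(k/eta)/n scaling, strictly positive
  z <- pac_bayes_bound(0, 0, 112, alpha = 0.3, grid)
  expect_gt(z$bound, 0)
  # the bound never undercuts the empirical loss
  expect_gte(got$bound, spec$L_hat)
  expect_error(pac_bayes_bound(0.1, 1, 100, lambda_grid = c(0.4, 2)), "exceed")
})

test_that("confusion metrics follow their definitions and the AUC rank statistic", {
  m <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0),
                       decision = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                       truth = rep(c(1, 0), each = 5))
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$auc, 1)
  m2 <- compute_metrics(list(TP = 40, TN = 40, FP = 16, FN = 18))
  expect_equal(m2$sensitivity, 0.6897, tolerance = 1e-4)
  expect_equal(m2$specificity, 0.7143, tolerance = 1e-4)
  expect_equal(m2$balanced_accuracy, 0.7020, tolerance = 1e-4)
  # constant decision values give AUC 1/2 under midranks
  expect_equal(rank_auc(rep(2, 10), rep_len(0:1, 10)), 0.5)
  expect_error(compute_metrics(list(TP = 0, TN = 3, FP = 2, FN = 0)),
               "both classes")
})

test_that("AUC is invariant under strictly monotone transformation and matches a library", {
  set.seed(71)
  dv <- rnorm(60); y <- rep_len(0:1, 60)
  a <- rank_auc(dv, y)
  expect_equal(rank_auc(exp(dv), y), a, tolerance = 1e-12)
  expect_equal(rank_auc(dv * 100 - 3, y), a, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, dv, quiet = TRUE,
                                                 direction = "<"))),
               tolerance = 1e-12)
})

test_that("stratified folds partition subjects with near-proportional class counts", {
  y <- rep(c(1L, 0L), c(58, 56))
  fold <- stratified_folds(y, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  sizes <- table(fold)
  expect_true(all(sizes %in% c(11, 12)))
  per_class <- table(fold, y)
  expect_true(all(abs(per_class[, "1"] - 5.8) <= 1))
  expect_true(all(abs(per_class[, "0"] - 5.6) <= 1))
  # every subject in exactly one fold, deterministic given seed
  expect_equal(length(fold), 114)
  expect_identical(fold, stratified_folds(y, 10, seed = 3))
  expect_false(identical(fold, stratified_folds(y, 10, seed = 4)))
  expect_error(stratified_folds(rep(c(1L, 0L), c(5, 100)), 10), "at least k")
})

test_that("cross-validation reaches ceiling on separable data and reports fold dispersion", {
  tab <- make_effect_table(n_per_class = 30, n_regions = 4, delta = 6,
                           n_effects = 2, seed = 72)
  rep_cv <- stratified_kfold_validate(tab, svm_factory(), k = 10, seed = 1)
  expect_equal(unname(rep_cv$test$mean["balanced_accuracy"]), 1)
  expect_equal(nrow(rep_cv$test$per_fold), 10)
  rep_cv2 <- stratified_kfold_validate(tab, svm_factory(), k = 10, seed = 1)
  expect_identical(rep_cv$test$per_fold, rep_cv2$test$per_fold)
})

test_that("RUB subtracts the bound without flooring", {
  tab <- make_effect_table(n_per_class = 28, n_regions = 3, delta = 6,
                           n_effects = 2, seed = 73)
  r <- rub_validate(tab, svm_factory(), bound = 0.2675)
  expect_equal(r$corrected$balanced_accuracy,
               r$empirical$balanced_accuracy - 0.2675)
  r2 <- rub_validate(tab, svm_factory(), bound = 0.3695)
  expect_equal(r2$corrected$balanced_accuracy,
               r2$empirical$balanced_accuracy - 0.3695)
  # a weak model minus a large bound goes sub-chance, reported as-is
  noise <- make_effect_table(n_per_class = 20, n_regions = 3, delta = 0,
                             seed = 74)
  rn <- rub_validate(noise, svm_factory(), bound = 0.3695)
  expect_lt(rn$corrected$balanced_accuracy, 0.5)
  # computed bound defaults to the concentration bound at (n, d)
  r3 <- rub_validate(tab, svm_factory())
  expect_equal(r3$bound_value, concentration_bound(56, 9, 0.05))
})

test_that("corrected accuracy approaches the empirical ceiling as n grows at d = 1", {
  accs <- sapply(c(50, 200, 1000), function(n) {
    tab <- make_effect_table(n_per_class = n / 2, n_regions = 1, delta = 8,
                             n_effects = 1, seed = 75)
    one <- feature_table(tab$values[, 1, drop = FALSE], tab$labels,
                         normalized = TRUE)
    rub_validate(one, svm_factory())$corrected$balanced_accuracy
  })
  expect_true(all(diff(accs) > 0))
  expect_gt(accs[3], 0.95)
})

test_that("the balanced permutation harness draws balanced subsamples and concentrates", {
  tab <- make_effect_table(n_per_class = 29, n_regions = 3, delta = 1.5,
                           n_effects = 2, seed = 76)
  # unbalance: drop one case
  keep <- c(which(tab$labels == 1)[-1], which(tab$labels == 0))
  tab <- feature_table(tab$values[keep, ], tab$labels[keep],
                       normalized = TRUE)
  pipe <- function(sub) {
    stopifnot(sum(sub$labels == 1) == sum(sub$labels == 0))
    r <- rub_validate(sub, svm_factory())
    c(bacc = r$empirical$balanced_accuracy)
  }
  one <- balanced_permutation_harness(tab, pipe, n_permutations = 1, seed = 1)
  expect_equal(unname(one$sd), 0)
  h1 <- balanced_permutation_harness(tab, pipe, n_permutations = 60, seed = 1)
  h2 <- balanced_permutation_harness(tab, pipe, n_permutations = 60, seed = 2)
  expect_lt(abs(h1$mean - h2$mean), 0.02)
})

test_that("label-shuffled data scores at chance under cross-validation", {
  set.seed(77)
  tab <- make_effect_table(n_per_class = 50, n_regions = 3, delta = 0, seed = 78)
  pipe <- function(sub) {
    cv <- stratified_kfold_validate(sub, svm_factory(), k = 5, seed = 11)
    c(bacc = unname(cv$test$mean["balanced_accuracy"]))
  }
  h <- balanced_permutation_harness(tab, pipe, n_permutations = 30, seed = 5)
  se <- unname(h$sd) / sqrt(30)
  expect_lt(abs(unname(h$mean) - 0.5), max(3 * se, 0.05))
})

test_that("component sweep shows the bound-driven parsimony effect", {
  tab <- make_effect_table(n_per_class = 56, n_regions = 25, delta = 1,
                           n_effects = 4, seed = 79)
  sw <- sweep_components(tab, c(2, 4, 10, 20), k = 5, seed = 3)
  expect_true(all(diff(sw$bound) > 0))
  # empirical resubstitution accuracy plateaus while the bound grows, so
  # corrected accuracy at moderate d beats corrected accuracy at d = 20
  expect_gt(sw$rub_corrected_bacc[sw$d == 4], sw$rub_corrected_bacc[sw$d == 20])
  expect_error(sweep_components(tab, 0), "d_range")
})

test_that("sample-size sweep shows corrected accuracy rising with n", {
  tab <- make_effect_table(n_per_class = 150, n_regions = 10, delta = 1.2,
                           n_effects = 4, seed = 80)
  sw <- sweep_sample_size(tab, c(20, 40, 88, 112, 240), d = 4, n_rep = 5, seed = 4)
  expect_true(all(diff(sw$bound) < 0))
  expect_gt(sw$rub_corrected_bacc[5], sw$rub_corrected_bacc[1])
  expect_error(sweep_sample_size(tab, c(2)), "sizes")
  expect_error(sweep_sample_size(tab, c(21)), "2 == 0")
})
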