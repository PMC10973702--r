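#!/usr/bin/env Rscript

# Model-agnostic explanation of the deployed classifier: train the MLP on the
# selected feature set from script 03 (the full-feature model memorizes the
# training data and generalizes at chance at this sample size, so explaining
# it would explain noise), explain correctly classified held-out test samples
# from a stratified split with kernel-estimated Shapley values, and export
# the ranked feature-impact table and dependence pairs. A local sparse
# surrogate explanation of one sample per class is printed alongside.

library(sulcalclass)

tab <- read_feature_table("results/cohort_clean.csv", normalized = TRUE)
sel <- lapply(jsonlite::read_json("results/selected_features.json",
                                  simplifyVector = TRUE),
              function(v) as.character(unlist(v)))
feats <- sel$union
X <- tab$values[, feats, drop = FALSE]
y <- tab$labels

fold <- stratified_folds(y, 10, seed = 21L)
test <- fold == 1
model <- fit_mlp(X[!test, ], y[!test],
                 mlp_spec(hidden = c(32, 16), epochs = 18, seed = 22L))
pred <- predict_class(model, X[test, ])
correct <- which(pred == y[test])
cat(sprintf("MLP on %d selected features; held-out fold: %d/%d correctly classified\n",
            length(feats), length(correct), sum(test)))

bg <- X[!test, ]
test_idx <- which(test)[correct]
results <- lapply(test_idx, function(i) {
  kernel_shap(model, X[i, ], bg, n_coalitions = 600, seed = 23L)
})
summ <- summarize_attributions(results, X = X[test_idx, , drop = FALSE],
                               top_k = 10)
write.csv(summ$ranking, "results/shap_ranking.csv", row.names = FALSE)
dep <- do.call(rbind, lapply(names(summ$dependence), function(f)
  cbind(feature = f, summ$dependence[[f]])))
write.csv(dep, "results/shap_dependence.csv", row.names = FALSE)
cat("ten features with the largest mean |SHAP| on explained test samples:\n")
print(summ$ranking, row.names = FALSE, digits = 3)

# local surrogate view of one correctly classified sample per class
for (cls in c(1L, 0L)) {
  i <- test_idx[y[test_idx] == cls][1]
  if (is.na(i)) next
  ex <- explain_local(model, X[i, ], n_perturbations = 800,
                      perturb_sd = 0.5, top_k = 5, seed = 24L)
  cat(sprintf("\nlocal surrogate, subject %s (%s):\n", tab$subject_ids[i],
              if (cls == 1) "case" else "control"))
  print(ex, row.names = FALSE, digits = 3)
}
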