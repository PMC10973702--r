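#!/usr/bin/env Rscript

# Classification of the clean cohort under the two validation schemes:
# stratified 10-fold CV and resubstitution with upper-bound correction (RUB).
# Three views:
#   (a) PLS component sweep (1-20) — how the concentration bound penalizes
#       dimensionality while CV stays flat;
#   (b) sample-size sweep at 4 components — the bound tightens with n;
#   (c) the report grid for the selected-feature sets from script 03.

library(sulcalclass)

tab <- read_feature_table("results/cohort_clean.csv", normalized = TRUE)

## (a) component sweep
sw <- sweep_components(tab, 1:20, svm_factory(), k = 10, seed = 11L)
write.csv(sw, "results/pls_component_sweep.csv", row.names = FALSE)
best_d <- sw$d[which.max(sw$rub_corrected_bacc)]
cat(sprintf("component sweep: RUB-corrected accuracy peaks at d = %d (%.3f); at d = 20 it is %.3f\n",
            best_d, max(sw$rub_corrected_bacc),
            sw$rub_corrected_bacc[sw$d == 20]))

## (b) sample-size sweep at d = 4, capped at a fully balanced subsample
sizes <- c(20, 30, 40, 64, 88, 2 * min(table(tab$labels)))
sn <- sweep_sample_size(tab, sizes, d = 4, svm_factory(), n_rep = 25, seed = 12L)
write.csv(sn, "results/sample_size_sweep.csv", row.names = FALSE)
cat(sprintf("sample-size sweep at d = 4: corrected accuracy %.3f at n = %d -> %.3f at n = %d\n",
            sn$rub_corrected_bacc[1], sizes[1],
            sn$rub_corrected_bacc[nrow(sn)], sizes[length(sizes)]))

## (c) report grid over selection modes, balanced subsamples per iteration
selected <- lapply(jsonlite::read_json("results/selected_features.json",
                                       simplifyVector = TRUE),
                   function(v) as.character(unlist(v)))
modes <- list(parametric = union(selected$both, selected$parametric_only),
              classifier = union(selected$both, selected$sam_only),
              ensemble = selected$union)
modes <- modes[vapply(modes, length, 1L) > 0]
grid <- do.call(rbind, lapply(names(modes), function(mode) {
  feats <- modes[[mode]]
  sub <- feature_table(tab$values[, feats, drop = FALSE], tab$labels,
                       tab$subject_ids, feats, normalized = TRUE)
  harness <- balanced_permutation_harness(sub, function(s) {
    cv <- stratified_kfold_validate(s, svm_factory(), k = 10, seed = 13L)
    rub <- rub_validate(s, svm_factory())
    c(cv_bacc = unname(cv$test$mean["balanced_accuracy"]),
      cv_auc = unname(cv$test$mean["auc"]),
      rub_bacc = rub$corrected$balanced_accuracy)
  }, n_permutations = 100, seed = 14L)
  data.frame(mode = mode, d = length(feats),
             cv_bacc = harness$mean["cv_bacc"], cv_bacc_sd = harness$sd["cv_bacc"],
             cv_auc = harness$mean["cv_auc"],
             rub_bacc = harness$mean["rub_bacc"],
             bound = concentration_bound(2 * min(table(tab$labels)),
                                         length(feats), 0.05))
}))
write.csv(grid, "results/classification_grid.csv", row.names = FALSE)
print(grid, row.names = FALSE, digits = 3)
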