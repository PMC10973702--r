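#!/usr/bin/env Rscript

# Two independent feature-relevance analyses on the clean table:
#   (a) parametric path — Shapiro-Wilk routing into two-sample t or
#       Mann-Whitney per feature, ranked by raw p;
#   (b) classifier-based path — per-feature linear-classifier accuracy over
#       balanced resamples, corrected by the d = 1 concentration bound, then
#       ranked by the proportion test.
# The two selected sets are then partitioned into both / parametric-only /
# classifier-only.

library(sulcalclass)

tab <- read_feature_table("results/cohort_clean.csv", normalized = TRUE)

uni <- univariate_selection(tab)
cat(sprintf("normality routing: %d features to t-test, %d to Mann-Whitney\n",
            sum(uni$routed_test == "t-test"),
            sum(uni$routed_test == "mann-whitney")))
write.csv(uni[order(uni$p_value), ], "results/univariate_results.csv",
          row.names = FALSE)
sel_par <- rank_features(uni, 0.05)
cat(sprintf("parametric path: %d features at p < 0.05 (%d at p < 0.1)\n",
            nrow(sel_par), nrow(rank_features(uni, 0.1))))

# classifier-based path; 1000 balanced resamples per feature as in the
# study design (the fast closed-form univariate discriminant scores each
# feature; swap sam_classifier for "svm" to mirror the heavier original)
acc <- sam_accuracies(tab, sam_config(n_permutations = 1000,
                                      classifier = "lda", seed = 7L))
sam_res <- proportion_test(acc)
write.csv(sam_res[order(-sam_res$z), ], "results/sam_results.csv",
          row.names = FALSE)
sel_sam <- select_sam(sam_res, 0.05)
cat(sprintf("classifier path: %d features at p < 0.05; top feature %s (pi-hat %.3f)\n",
            nrow(sel_sam), sel_sam$feature[1], sel_sam$pi_hat[1]))

cmb <- combine_selections(sel_par$feature, sel_sam$feature)
cat(sprintf("overlap: %d in both, %d parametric-only, %d classifier-only, union %d\n",
            length(cmb$both), length(cmb$parametric_only),
            length(cmb$sam_only), length(cmb$union)))
jsonlite::write_json(cmb, "results/selected_features.json", auto_unbox = TRUE)
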