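#!/usr/bin/env Rscript

# Exclusion cascade on the raw cohort: drop subjects with too many
# misdetected regions, drop the insulae by name, drop any region still
# carrying a misdetection, z-score, then drop subjects with any |z| > 6.

library(sulcalclass)

raw <- read_feature_table("results/cohort_raw.csv")
res <- apply_exclusions(raw, preprocess_config())
print(res$report)

write_feature_table(res$table, "results/cohort_clean.csv")
write_preprocess_report(res$report, "results/preprocess_report.json")
cat(sprintf("clean table: %d x %d (%d regions)\n",
            nrow(res$table$values), ncol(res$table$values),
            ncol(res$table$values) / 3))
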