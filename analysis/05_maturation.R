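#!/usr/bin/env Rscript
# Confound structure and the random-forest maturation index.
# Requires: results/idp_table.csv (from 03)
# Writes: results/confound_variance_explained.csv,
#         results/maturation_report.csv, results/brain_age_deltas.csv,
#         results/feature_importance.csv

suppressPackageStartupMessages(library(fbgrowth))
dir.create("results", showWarnings = FALSE)
stopifnot(file.exists("results/idp_table.csv"))
tab <- read.csv("results/idp_table.csv", stringsAsFactors = FALSE)

# per-confound variance explained on the standardised features
X <- scale(as.matrix(tab[, idp_names()]))
enc <- encode_confounds(tab, c("sex", "site", "hemisphere"))
ve <- do.call(rbind, lapply(unique(enc$groups), function(cf) {
  v <- variance_explained(X, enc$V, cf, groups = enc$groups)
  cbind(data.frame(confound = cf), v)
}))
write.csv(ve, "results/confound_variance_explained.csv", row.names = FALSE)

model <- fit_maturation_model(tab, seed = 13L)
report <- evaluate_maturation(model)
print(report)
write.csv(data.frame(mae_days = report$mae_days,
                     pearson_r = report$pearson_r, icc = report$icc,
                     n_scans = nrow(report$deltas)),
          "results/maturation_report.csv", row.names = FALSE)
write.csv(report$deltas, "results/brain_age_deltas.csv", row.names = FALSE)

fi <- feature_importance(model, n_perm = 1L)
write.csv(fi, "results/feature_importance.csv", row.names = FALSE)
cat("Top five features by impurity importance:\n")
print(head(fi, 5))
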