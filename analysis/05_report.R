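#!/usr/bin/env Rscript

# Stage 5 — regional dose-pattern maps.
#
# Assembles the per-group mean and coefficient-of-variation maps of the 198
# dose features (no xerostomia / injury-with-recovery / injury-without-
# recovery), joins the max-T significance flags and the normalized model
# importances into one table per feature, and renders diagnostic heat-map
# panels (subvolume x Dx).

suppressPackageStartupMessages(library(xerosubvol))

out <- "results/study"
tab <- read_feature_table(file.path(out, "features.csv"))

gs <- group_summaries(tab)
write_table_units(gs, file.path(out, "group_summaries.csv"),
                  "mean: cGy; cv: dimensionless (sd/mean)")
cat("group sizes:\n")
print(unique(gs[, c("group", "n")]))

rep <- jsonlite::read_json(file.path(out, "model_report.json"), simplifyVector = TRUE)
imp <- data.frame(feature = dose_feature_names(), stringsAsFactors = FALSE)
imp$importance_injury <- unlist(rep$injury$importance)[imp$feature]
imp$importance_recovery <- unlist(rep$recovery$importance)[imp$feature]
for (oc in c("injury", "recovery")) {
  pr <- read_table_units(file.path(out, paste0("permtest_", oc, ".csv")))
  imp[[paste0("significant_", oc)]] <- pr$significant[match(imp$feature, pr$feature)]
}
write_table_units(imp, file.path(out, "importance_maps.csv"),
                  "importance: normalized to [-100, 100]; significant: logical")
xerosubvol:::render_importance_figure(imp, file.path(out, "importance_maps.png"))

inj_top <- imp$feature[which.max(abs(imp$importance_injury))]
rec_top <- imp$feature[which.max(abs(imp$importance_recovery))]
cat(sprintf("strongest injury importance sits at %s; strongest recovery importance at %s\n",
            inj_top, rec_top))
cat(sprintf("injury model: %d significant features carry mean |importance| %.0f\n",
            sum(imp$significant_injury),
            mean(abs(imp$importance_injury[imp$significant_injury]))))
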