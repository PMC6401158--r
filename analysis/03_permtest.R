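#!/usr/bin/env Rscript

# Stage 3 — max-T permutation screening of the dose features.
#
# For each outcome, tests all 198 subvolume Dx features for a one-sided mean
# difference with single-step max-T family-wise error control over 1000
# label permutations: injury tests for higher dose among the injured;
# recovery tests for higher dose among the non-recovered (the direction in
# which dose is expected to impair recovery).

suppressPackageStartupMessages(library(xerosubvol))

out <- "results/study"
tab <- read_feature_table(file.path(out, "features.csv"))
seed <- 21L

for (oc in c("injury", "recovery")) {
  pop <- model_population(tab, oc)
  res <- maxT_permutation_test(pop$X[, dose_feature_names()], pop$y,
                               n_perm = 1000,
                               direction = if (oc == "injury") "greater" else "less",
                               seed = seed)
  write_table_units(as.data.frame(res), file.path(out, paste0("permtest_", oc, ".csv")),
                    "T: normalized mean-difference statistic; p: permutation-adjusted")
  sig <- res[res$significant, ]
  cat(sprintf("%s: %d of 198 features significant at adjusted p < 0.05 (n = %d)\n",
              oc, nrow(sig), length(pop$y)))
  if (nrow(sig) > 0) {
    top_sv <- sort(table(sub("_D[0-9]+$", "", sig$feature)), decreasing = TRUE)
    cat("  significant features concentrate in:",
        paste(names(top_sv), collapse = ", "), "\n")
  }
}
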