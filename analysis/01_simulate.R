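#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort at a realistic single-institution
# study size (n = 258 head-and-neck patients): ellipsoidal salivary-gland anatomy with
# per-patient jitter, an ipsilateral-skewed Gaussian dose field, clinical
# covariates, and longitudinal CTCAE xerostomia timelines driven by the
# configured dose-to-outcome mechanism. Writes the assembled feature table
# (198 dose + 16 clinical columns + labels), the assessment timelines, and
# the latent truth labels under results/study/.

suppressPackageStartupMessages(library(xerosubvol))

out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20L

cfg <- cohort_config(n_patients = 258, seed = seed)
cat(sprintf("simulating %d patients (seed %d)...\n", cfg$n_patients, seed))
cohort <- generate_cohort(cfg)
tab <- cohort_feature_table(cohort)

write_table_units(tab, file.path(out, "features.csv"),
                  "dose features: cGy; vol_*: cc; labels/dummies: 0/1")
assess <- do.call(rbind, lapply(cohort$patients, function(p)
  data.frame(patient_id = p$patient_id, days_post_rt = p$timeline$days_post_rt,
             ctcae_grade = p$timeline$ctcae_grade)))
write_table_units(assess, file.path(out, "assessments.csv"),
                  "days_post_rt: days; ctcae_grade: CTCAE 0-3")
truth <- do.call(rbind, lapply(cohort$patients, function(p)
  data.frame(patient_id = p$patient_id, injury = p$latent$injury,
             recovery = p$latent$recovery)))
write_table_units(truth, file.path(out, "truth.csv"), "labels: 0/1")

cat(sprintf("cohort: %d injured (%.0f%%), %d of them recovered (%.0f%%)\n",
            sum(tab$injury), 100 * mean(tab$injury),
            sum(tab$recovery == 1, na.rm = TRUE),
            100 * mean(tab$recovery[tab$injury == 1])))
cat(sprintf("dose features span %.0f-%.0f cGy\n",
            min(as.matrix(tab[, dose_feature_names()])),
            max(as.matrix(tab[, dose_feature_names()]))))
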