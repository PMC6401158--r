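#!/usr/bin/env Rscript

# Stage 2 — xerostomia prevalence over follow-up.
#
# Computes the fraction of assessed patients with grade >= 2 xerostomia in
# each follow-up window (on-treatment visit through 18 months) from the
# simulated assessment timelines: the prevalence typically peaks around the
# on-treatment visit and falls through 18 months as patients recover.

suppressPackageStartupMessages(library(xerosubvol))

out <- "results/study"
assess <- read_table_units(file.path(out, "assessments.csv"))
timelines <- lapply(split(assess, assess$patient_id), function(a)
  assessment_timeline(a$patient_id[1], a$days_post_rt, a$ctcae_grade))

prev <- prevalence_curve(timelines)
write_table_units(prev, file.path(out, "prevalence.csv"),
                  "lo/hi: days post-RT; prevalence: proportion of assessed patients")
print(prev)
cat(sprintf("grade >= 2 prevalence: %.0f%% at the on-treatment visit, %.0f%% at 18 months\n",
            100 * prev$prevalence[prev$window == "OTV"],
            100 * prev$prevalence[prev$window == "m18"]))
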