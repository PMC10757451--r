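#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 20 people with aphasia + 20 controls on a 40 x 48 x 40 mm template
# (2 mm voxels): mirrored perisylvian-analogue and control ROIs, a single
# left-hemisphere lesion per patient, graded perilesional hypoperfusion
# (x0.85 / x0.95 / x1.00 over 0-5 / 5-10 / 10-15 mm), a planted adjusted
# deficit in left ROIs 1-2, and WAB scores coupled to adjusted perfusion of
# left ROIs 3-4. Volumes are NIfTI and land under scratch/ (binary data);
# the cohort table is CSV.

library(perfband)

seed <- 20
out_dir <- "scratch/cohort"

cfg <- cohort_config()  # the default study conditions
cohort <- simulate_cohort(cfg, seed = seed)
write_cohort(cohort, out_dir)

tab <- cohort$table
message(sprintf("cohort written to %s: %d aphasia + %d controls", out_dir,
                sum(tab$group == "aphasia"), sum(tab$group == "control")))
message(sprintf("lesion volumes (mm^3): %s",
                paste(range(tab$lesion_volume[tab$group == "aphasia"]),
                      collapse = " - ")))
message(sprintf("WAB AQ in patients: %.1f +/- %.1f",
                mean(tab$aq[tab$group == "aphasia"]),
                sd(tab$aq[tab$group == "aphasia"])))
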