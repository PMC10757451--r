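#!/usr/bin/env Rscript
# Stage 4: perfusion-language modelling in the aphasia group.
#
# Partial correlations between adjusted ROI perfusion and the six WAB
# outcomes under two covariate sets (demographics + lesion volume, and
# additionally the ROI's own lesion load), then the lasso over all left-ROI
# perfusion values, perilesional bands and lesion loads with leave-one-out
# cross-validated penalty selection.

library(perfband)

cohort <- validate_and_load("scratch/cohort")
metrics <- read.csv("results/metrics.csv", stringsAsFactors = FALSE)
dir.create("results", showWarnings = FALSE)

outcomes <- c("information_content", "fluency", "repetition", "naming",
              "auditory_comprehension", "aq")

pc <- rbind(
  correlate_language(metrics, cohort$table, cohort$lookup, "lesion_volume",
                     outcomes),
  correlate_language(metrics, cohort$table, cohort$lookup,
                     "lesion_volume_and_load", outcomes))
write.csv(pc, "results/partial_correlations.csv", row.names = FALSE)
sig <- pc[pc$significant & pc$covariate_set == "lesion_volume", ]
message("Bonferroni-significant perfusion-language cells (lesion-volume set): ",
        if (nrow(sig)) paste(paste(sig$name, sig$outcome, sep = "*"),
                             collapse = ", ") else "none")

fits <- lapply(outcomes, function(o)
  suppressWarnings(fit_language_lasso(metrics, cohort$table, cohort$lookup, o)))
names(fits) <- outcomes
tab <- lasso_table(fits)
write.csv(tab, "results/lasso_table.csv", row.names = FALSE)

for (f in fits)
  message(sprintf("%-24s lambda %.3g  R2 %.2f  RMSE %.2f  nonzero %d",
                  f$outcome, f$lambda_selected, f$r_squared, f$rmse,
                  sum(f$coefficients != 0)))
message("lasso table written to results/lasso_table.csv ",
        "(penalties follow the 1/(2n) objective convention)")
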