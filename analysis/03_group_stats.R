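#!/usr/bin/env Rscript
# Stage 3: group-level statistics.
#
# Between-group comparisons per ROI (normality-gated cascade, Bonferroni at
# 0.05 / ROIs-per-hemisphere), paired left-vs-right tests, asymmetry
# comparisons, lesioned-vs-spared splits, Spearman lesion-load correlations
# and perilesional band contrasts.

library(perfband)

cohort <- validate_and_load("scratch/cohort")
metrics <- read.csv("results/metrics.csv", stringsAsFactors = FALSE)
dir.create("results", showWarnings = FALSE)

gc_ <- suppressWarnings(compare_groups_all_rois(metrics, cohort$lookup))
write.csv(gc_, "results/group_comparison.csv", row.names = FALSE)
adj <- gc_[gc_$measure == "adjusted", ]
message("adjusted-scale group differences (Bonferroni ",
        signif(adj$bonferroni_threshold[1], 2), "): ",
        paste(adj$name[adj$significant], collapse = ", "))

lr <- compare_left_right(metrics, cohort$lookup)
write.csv(lr, "results/left_right.csv", row.names = FALSE)

asym_tests <- compare_asymmetry(metrics, cohort$lookup)
write.csv(asym_tests, "results/asymmetry_tests.csv", row.names = FALSE)

llc <- lesionload_correlations(metrics, cohort$lookup)
write.csv(llc, "results/lesionload_correlations.csv", row.names = FALSE)
message("lesion-load Spearman rho range: ",
        paste(round(range(llc$rho, na.rm = TRUE), 2), collapse = " to "))

peri <- compare_perilesional_bands(metrics)
write.csv(peri, "results/perilesional_tests.csv", row.names = FALSE)
print(peri[, c("comparison", "mean_1", "mean_2", "test", "p_value")])

# lesioned-vs-spared per left ROI where both subgroups exist
left <- cohort$lookup[cohort$lookup$hemisphere == "L", ]
for (lab in left$label) {
  res <- tryCatch(lesioned_vs_spared(lab, metrics, cohort$lookup),
                  error = function(e) NULL)
  if (is.null(res) || is.null(res$left)) next
  message(sprintf("ROI %s lesioned(%d) vs spared(%d): left p = %.3g, right p = %s",
                  left$name[left$label == lab], res$n_lesioned, res$n_spared,
                  res$left$p_value,
                  if (is.null(res$right)) "-" else format(res$right$p_value,
                                                          digits = 3)))
}
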