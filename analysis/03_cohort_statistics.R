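#!/usr/bin/env Rscript
# Step 3: paired cohort statistics. Aggregates the per-patient metrics into
# the study-style summary: mean +/- SD per phase, medians and quartiles of
# the paired after-minus-before differences, direction counts, Shapiro-Wilk
# normality checks, and exact two-sided Wilcoxon signed-rank tests. No
# multiple-testing correction is applied.
#
# Input:  results/patient_metrics.tsv   (from 02_analyze_cohort.R)
# Output: results/table1_style.tsv, results/cohort_summary.tsv,
#         results/narrative_stats.tsv

library(hyperskin)

records <- read.table(file.path("results", "patient_metrics.tsv"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
summ <- summarize_cohort(records)
write_report(records, "results", summary = summ)

print(summ)
s <- summ$summary
pick <- function(met, col) s[s$metric == met, col]
cat(sprintf("\nBrightness rose in %d/12 patients (%.0f%%); median paired shift %+.2f gray levels (p = %.3g).\n",
            pick("brightness", "n_increase"),
            100 * pick("brightness", "prop_increase"),
            pick("brightness", "median_diff"), pick("brightness", "wilcoxon_p")))
cat(sprintf("GLCM contrast fell in %d/12 (%.0f%%); homogeneity rose in %d/12 (%.0f%%).\n",
            pick("contrast", "n_decrease"), 100 * pick("contrast", "prop_decrease"),
            pick("homogeneity", "n_increase"),
            100 * pick("homogeneity", "prop_increase")))
cat(sprintf("654 nm ROI-mean reflectance: median %.0f -> %.0f c.u. (p = %.3g); max-min range: no significant change (p = %.3g).\n",
            pick("refl_mean_cu", "median_before"),
            pick("refl_mean_cu", "median_after"),
            pick("refl_mean_cu", "wilcoxon_p"),
            pick("refl_range_cu", "wilcoxon_p")))
cat(sprintf("Shapiro-Wilk on brightness before/after: p = %.3g / %.3g.\n",
            pick("brightness", "shapiro_p_before"),
            pick("brightness", "shapiro_p_after")))
cat("\nTables -> results/table1_style.tsv, cohort_summary.tsv, narrative_stats.tsv\n")
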