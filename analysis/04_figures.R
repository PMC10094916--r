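#!/usr/bin/env Rscript
# Step 4: reporting figures for the first three patients - the maximum /
# average / minimum reflectance line profiles (blue / red / green) and the
# 3-D gray-level brightness surfaces, before and after treatment.
#
# Input:  scratch/cohort/manifest.tsv
# Output: results/figures/profile_*.png, results/figures/surface_*.png

library(hyperskin)

manifest <- read_manifest(file.path("scratch", "cohort", "manifest.tsv"))
subset <- manifest[1:3, ]
attr(subset, "white") <- attr(manifest, "white")

records <- analyze_cohort(subset, keep_profiles = TRUE, keep_gray = TRUE)
write_report(records, file.path("results", "figures"),
             summary = NULL,
             profiles = attr(records, "profiles"),
             gray_images = attr(records, "gray_images"))

made <- list.files(file.path("results", "figures"), pattern = "\\.png$")
cat(sprintf("Wrote %d figures under results/figures:\n", length(made)))
cat(paste0("  ", made, collapse = "\n"), "\n")
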