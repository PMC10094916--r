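#!/usr/bin/env Rscript
# Step 2: run the measurement pipeline on the simulated cohort. Every cube is
# read back from its ENVI pair, calibrated against the white reference
# (reflectance in c.u., 1023 = 100%), cropped to the manifest ROI and reduced
# to five per-ROI metrics: gray-level brightness, GLCM contrast and
# homogeneity (d = 1, theta = 0, G = 256, ordered right-neighbour pairs), and
# the ROI-mean reflectance and max-min range at the band nearest 654 nm.
#
# Input:  scratch/cohort/manifest.tsv   (from 01_simulate_cohort.R)
# Output: results/patient_metrics.tsv

library(hyperskin)

manifest <- read_manifest(file.path("scratch", "cohort", "manifest.tsv"))
records <- analyze_cohort(manifest, params = glcm_params(), lambda_nm = 654)

dir.create("results", showWarnings = FALSE)
write.table(records, file.path("results", "patient_metrics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Analyzed %d ROIs (%d patients x 2 phases) at band %.1f nm\n",
            nrow(records), length(unique(records$patient_id)),
            records$lambda_nm[1]))
cat("Per-patient metrics -> results/patient_metrics.tsv\n\n")
print(records[, c("patient_id", "phase", "brightness", "contrast",
                  "homogeneity", "refl_mean_cu", "refl_range_cu")],
      digits = 4)
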