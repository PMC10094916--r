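#!/usr/bin/env Rscript
# Step 1: materialize the packaged 12-patient before/after cohort as ENVI
# cubes on disk. Each patient gets a 64 x 64 x 204 cube per phase (400-1000
# nm, 2.941 nm steps) plus a shared flat white-reference cube; the per-patient
# texture and 654 nm reflectance targets come from the frozen preset table.
#
# Output: scratch/cohort/ (binary cubes + manifest.tsv) - regenerate at will.

library(hyperskin)

out <- file.path("scratch", "cohort")
preset <- paper_cohort_preset()
cat(sprintf("Preset '%s': %d patients, cubes %dx%dx%d, seed %d\n",
            preset$name, nrow(preset$patients), preset$shape[1],
            preset$shape[2], preset$shape[3], preset$seed))

manifest <- build_cohort(preset, out)
cat(sprintf("Wrote %d cubes + white reference under %s\n",
            2L * nrow(manifest), out))
cat("Manifest:", attr(manifest, "path"), "\n")

# the preset targets themselves already satisfy the study-design summaries;
# print them for the record
s <- summarize_targets(preset)
print(s)
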