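#!/usr/bin/env Rscript
# Extract the 12 image features per slide (tumor-tile detection, up to 100
# random 1024 px patches, Delaunay interaction fractions, densities, TSR)
# and aggregate to patient level.
suppressPackageStartupMessages(library(tmebenefit))

seed <- 42L
paths <- list.files("scratch/study/cellmaps", pattern = "\\.csv$",
                    full.names = TRUE)
stopifnot(length(paths) > 0)
cat(sprintf("Extracting features from %d slides...\n", length(paths)))
slide_rows <- do.call(rbind, lapply(paths, function(p) {
  m <- read_cell_map(p)
  slide_features(m, seed = stage_seed(seed, m$slide_id))
}))
patient_rows <- patient_features(slide_rows)
dir.create("results", showWarnings = FALSE)
write.csv(slide_rows, "results/features_slide.csv", row.names = FALSE, na = "")
write.csv(patient_rows, "results/features_patient.csv", row.names = FALSE,
          na = "")
cat(sprintf("Patients: %d; mean patches/slide: %.1f\n",
            nrow(patient_rows), mean(slide_rows$n_patches_used)))
cat(sprintf("Mean tumor-tumor interaction:  %.3f\n",
            mean(patient_rows$interaction_tumor_tumor)))
cat(sprintf("Mean tumor-stroma interaction: %.3f\n",
            mean(patient_rows$interaction_tumor_stroma)))
cat(sprintf("Median tumor/stroma ratio:     %.2f\n",
            median(patient_rows$tsr, na.rm = TRUE)))
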