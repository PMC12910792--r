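#!/usr/bin/env Rscript

# Simulate a two-genotype imaging cohort: 12 wild-type-like and 12
# knockout-like fields (the knockout condition carries 1.4x as many
# condensates per nucleus with a 30% lower log-mean area), written to disk
# as 16-bit TIFFs with ground-truth label maps and object tables.

suppressPackageStartupMessages(library(condensatr))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

wt_spec <- synthetic_spec(field_size_px = c(512L, 512L))
ko_spec <- knockout_spec(wt_spec)

cohort <- generate_cohort(wt_spec, ko_spec, n_per_group = 12, seed = 20260901)

manifest <- data.frame()
for (i in seq_len(nrow(cohort$meta))) {
  prefix <- file.path(out_dir, cohort$meta$subject_id[i])
  paths <- write_field(cohort$fields[[i]], prefix)
  manifest <- rbind(manifest, data.frame(
    path = unname(paths["image"]),
    subject_id = cohort$meta$subject_id[i],
    group = cohort$meta$group[i]))
}
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

truth_counts <- vapply(cohort$fields, function(f) nrow(f$truth$objects),
                       numeric(1))
cat(sprintf("Wrote %d fields to %s\n", nrow(manifest), out_dir))
cat(sprintf("Ground-truth condensates per field: WT %.1f, cKO %.1f (means)\n",
            mean(truth_counts[cohort$meta$group == "WT"]),
            mean(truth_counts[cohort$meta$group == "cKO"])))
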