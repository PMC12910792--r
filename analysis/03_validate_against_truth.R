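#!/usr/bin/env Rscript

# Validate the pipeline against the simulator's ground truth: per-field
# recall, precision and recovered-vs-true mean area, on the cohort written
# by 01_simulate_cohort.R.

suppressPackageStartupMessages(library(condensatr))

manifest <- read.csv("results/cohort/manifest.csv", stringsAsFactors = FALSE)

rows <- lapply(seq_len(nrow(manifest)), function(i) {
  img <- read_image_tiff(manifest$path[i], 0.173)
  truth <- read.csv(sub("\\.tif$", "_objects.csv", manifest$path[i]))
  res <- process_field(img, subject_id = manifest$subject_id[i],
                       group = manifest$group[i])
  mt <- match_to_truth(res$records, truth, 0.173)
  data.frame(subject_id = manifest$subject_id[i], group = manifest$group[i],
             n_truth = mt$n_truth, n_detected = mt$n_detected,
             recall = mt$recall, precision = mt$precision,
             mean_area_det = mean(mt$pairs$area_det_um2),
             mean_area_true = mean(mt$pairs$area_true_um2))
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/validation.csv", row.names = FALSE)

cat(sprintf("Across %d fields: recall %.3f, precision %.3f\n",
            nrow(tab), mean(tab$recall), mean(tab$precision)))
cat(sprintf("Recovered mean area %.3f um^2 vs true %.3f um^2 (%+.1f%%)\n",
            mean(tab$mean_area_det), mean(tab$mean_area_true),
            100 * (mean(tab$mean_area_det) / mean(tab$mean_area_true) - 1)))
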