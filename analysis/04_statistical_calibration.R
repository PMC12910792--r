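#!/usr/bin/env Rscript

# Statistical calibration of the per-bin two-group comparison, using the
# generative model directly (no image rendering): family-wise false-
# positive rate under the null and power to detect the knockout contrast
# (1.4x counts, 30% lower log-mean area) at n = 12 fields per group,
# over 100 replicate cohorts each.

suppressPackageStartupMessages(library(condensatr))

set.seed(42)
seed_pool <- sample.int(.Machine$integer.max, 2e4)
si <- 0L
next_seed <- function() { si <<- si + 1L; seed_pool[si] }

cohort_cmp <- function(spec_a, spec_b) {
  mk <- function(spec, grp, i) {
    areas <- sample_truth_areas(spec, seed = next_seed())
    histogram_areas(data.frame(area_um2 = areas,
                               accepted = rep(TRUE, length(areas))),
                    1:5, subject_id = paste0(grp, i), group = grp)
  }
  compare_groups(c(lapply(1:12, function(i) mk(spec_a, "WT", i)),
                   lapply(1:12, function(i) mk(spec_b, "cKO", i))))
}

wt <- synthetic_spec()
ko <- knockout_spec(wt)

null_any <- vapply(1:100, function(r)
  any(cohort_cmp(wt, wt)$per_bin$p_adj < 0.05), logical(1))
eff <- vapply(1:100, function(r) {
  cmp <- cohort_cmp(wt, ko)
  c(bin1 = cmp$per_bin$p_adj[1] < 0.05, total = cmp$total$p < 0.05)
}, logical(2))

tab <- data.frame(
  quantity = c("null_familywise_rate", "power_bin_1_2_um2", "power_total_count"),
  value = c(mean(null_any), mean(eff["bin1", ]), mean(eff["total", ])),
  replicates = 100)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/calibration.csv", row.names = FALSE)
print(tab, row.names = FALSE)
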