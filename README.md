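# condensatr

Quantification of bright nuclear protein condensates (puncta) in calibrated
fluorescence tissue images, with a ground-truth synthetic-image simulator
for validating every stage.

## What it is for

Perturbations of chromatin-associated proteins such as MeCP2 can change how
many sub-nuclear condensates a brain region carries and how large they are.
Measuring that from microscopy takes a chain of image operations and a
per-size-bin statistical comparison between genotypes, and each link needs
auditing. `condensatr` implements the whole chain as composable R
functions:

1. **EDF projection** of a Z-stack by the local-variance method: per pixel,
   the slice maximising the population variance in a (2r+1)² window is
   selected (ties to the lowest slice), the index map is median-smoothed,
   and neighbouring slices are blended with geometrically decaying weights.
2. **Enhancement**: rolling-ball background subtraction (grayscale opening
   by a spherical-cap element, default radius 10 px) followed by a
   difference-of-Gaussians band-pass, `G(σ=2)∗I − G(σ=10)∗I`.
3. **Segmentation**: robust thresholding (median + 3·1.4826·MAD inside the
   ROI), maxima-seeded priority-flood watershed, per-object area at the
   0.35-of-own-peak contour, areas in µm² as `pixels × pixel_size²`
   (default 0.173 µm/pixel).
4. **False-positive rejection** by explicit rules (area range, solidity,
   local contrast with a density-scaled requirement in crowded regions),
   every rejection retained with its reason.
5. **Statistics**: per-subject area histograms on fixed µm² bins
   (default edges 1–5, open top bin), unpaired Student t per bin with
   Holm–Šídák step-down adjustment
   `p̃(j) = max_{i≤j} [1 − (1 − p(i))^(m−i+1)]`, and a separate
   uncorrected test on total counts. The subject, not the condensate, is
   the statistical unit.

A synthetic-data module (`synthetic_spec()`, `generate_plane()`,
`generate_stack()`, `generate_cohort()`) simulates tissue fields — nuclei
at sparse (cerebellum-like) or dense (hippocampus-like) density, log-normal
condensate sizes, Gaussian PSF, background gradient, Poisson + Gaussian
noise, per-slice defocus — and emits exact ground truth, so recall,
precision, area bias and statistical calibration are all measurable. The
Y-maze spontaneous-alternation score (`spontaneous_alternation()`),
`alternations / (entries − 2) × 100` over overlapping arm-entry triplets,
is included for the behavioural side of such studies.

## Worked example

Simulate a two-genotype cohort (12 fields per group; the knockout-like
condition has 1.4× as many condensates with a 30% lower log-mean area),
process it, and compare the groups:

```r
library(condensatr)

wt  <- synthetic_spec(field_size_px = c(512L, 512L))
ko  <- knockout_spec(wt)                      # more, smaller condensates
coh <- generate_cohort(wt, ko, n_per_group = 12, seed = 20260901)

out <- run_cohort(coh, bin_edges_um2 = 1:5)
out$comparison
```

```
Group comparison: WT (n = 12) vs cKO (n = 12)
Total count: WT 34.8 vs cKO 45.8, t = -4.243, df = 22.0, p = 0.0003335
Per-bin tests (Holm-Sidak adjusted):
     bin mean_a  sem_a  mean_b  sem_b       t df     p_raw     p_adj
   [1,2) 18.750 1.4361 30.1667 1.4711 -5.5532 22 1.396e-05 6.979e-05
   [2,3) 11.083 0.8744 11.7500 1.1489 -0.4617 22 6.488e-01 9.567e-01
   [3,4)  3.667 0.3761  2.7500 0.5094  1.4478 22 1.618e-01 5.063e-01
   [4,5)  1.083 0.2599  0.9167 0.3362  0.3922 22 6.987e-01 9.567e-01
 [5,Inf)  0.250 0.1794  0.1667 0.1124  0.3936 22 6.977e-01 9.567e-01
```

The knockout-like group shows a significant increase in total condensate
count and, after multiple-testing correction, an excess specifically in the
1–2 µm² bin — the "more and smaller condensates" signature the pipeline is
designed to detect — while the larger-area bins stay flat. Validating the
same cohort against its ground truth (`match_to_truth()`) gives recall
0.992, precision 0.997 and a recovered mean area within 2.4% of truth.

The `analysis/` directory holds the same workflow as numbered scripts
(simulate → process → validate → calibrate), each writing its tables under
`results/`. The pipeline also runs over files on disk from a YAML config
via `run_pipeline()`, writing records, histograms, comparison tables and a
provenance JSON that captures every parameter and seed.

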