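---
title: "Quantifying nuclear condensates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear condensates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensatr)
```

## The problem

Proteins such as MeCP2 form bright sub-nuclear condensates (puncta) in
brain tissue, and experimental perturbations can shift both how many
condensates a region carries and how large they are. Quantifying that shift
from fluorescence microscopy requires a chain of image operations — focus
projection, background removal, blob enhancement, segmentation,
false-positive rejection — followed by calibrated measurement and
per-size-bin statistics between genotypes. Each link has free choices, and
raw tissue images rarely come with ground truth against which to audit
them. This package implements the full chain and pairs it with a synthetic
tissue-image simulator whose ground truth makes every stage testable.

## The pipeline

### Extended depth of field (variance method)

Tissue sections are acquired as Z-stacks; a single all-in-focus plane is
reconstructed before analysis. The focus measure is the local intensity
variance: for slice $z$ and pixel $(x,y)$,

$$V_z(x,y) = \frac{1}{(2r+1)^2}\sum_{(u,v)\in W_r(x,y)} I_z(u,v)^2 -
\Big(\frac{1}{(2r+1)^2}\sum_{(u,v)\in W_r(x,y)} I_z(u,v)\Big)^2,$$

a *population* variance over the $(2r+1)^2$ window $W_r$, with reflective
boundary padding (deterministic and edge-safe). The selected slice is
$\arg\max_z V_z(x,y)$, ties resolved toward the lowest slice index so the
projection is reproducible. Three parameters shape the reconstruction, named
after their operational role:

* `smoothing` (default 5): half-width of a median filter applied to the
  selected slice-index map, suppressing salt-and-pepper slice switching.
* `contrast_length` (default 3): slices within this distance of the
  selected slice are blended into the output pixel.
* `reconstruction_factor` (default 0.05): geometric decay of the neighbour
  weights per slice step; 0 reduces to pure slice selection.

These are operational definitions chosen here; acquisition-software
implementations of similarly named controls are proprietary, so parity with
any vendor output is qualitative, not numeric. Stack alignment is
deliberately not performed. The defaults above are the sparse-regime
(cerebellum-like) preset; `edf_params_dense()` (`smoothing` 2, factor 0.01)
is the dense-regime variant.

### Enhancement

Two classical steps condition the image for spot detection:

1. **Rolling-ball background subtraction** (radius 10 px): the background
   is the grayscale opening of the image by a spherical-cap structuring
   element — erosion then dilation with heights
   $b(s)=\sqrt{r^2-\lVert s\rVert^2}$ — which follows smooth shading but
   cannot enter peaks narrower than the ball. The result is anti-extensive
   (never exceeds the input) and clipped at zero.
2. **Difference of Gaussians** ($\sigma_1 = 2$, $\sigma_2 = 10$ px):
   $G_{\sigma_1}\!\ast I - G_{\sigma_2}\!\ast I$, a band-pass that responds
   maximally to blobs between the two scales. Kernels are truncated at
   $4\sigma$ with reflective boundaries; negative responses are clipped by
   default because only bright condensates are sought. The two steps are
   applied sequentially (subtraction first).

### Segmentation and measurement

Detection on the enhanced image is deterministic:

* **Threshold.** Default is robust: median plus $k\cdot 1.4826\,
  \mathrm{MAD}$ with $k = 3$, computed inside the ROI. Because the enhanced
  image is clipped at zero, more than half its pixels can sit exactly at 0,
  which degenerates the MAD; in that case the noise scale is read off the
  84.13% quantile of the clipped distribution (which equals $1\sigma$ for
  zero-median noise clipped at zero), and for an essentially noiseless
  image the threshold falls back to 5% of the ROI maximum.
* **Seeds and watershed.** Seeds are regional maxima of the enhanced image
  within the foreground, with maxima closer than `min_distance_px`
  (default 3) suppressed; plateau maxima collapse to one seed per connected
  plateau. Objects grow by priority-flood watershed on the inverted
  enhanced landscape, restricted to the foreground, with FIFO tie-breaking
  so equal heights resolve deterministically.
* **Area measurement.** Each object is trimmed to the connected region at
  or above `peak_fraction` (default 0.35) of its own enhanced peak. The
  global threshold sits just above the noise floor, so the raw watershed
  support includes the full blurred skirt of each spot and would roughly
  double the area of a diffraction-blurred disk; a fraction-of-own-peak
  contour is the standard blur-robust alternative (half-max sits exactly at
  the true edge of a symmetric blurred step). The default 0.35 rather than
  0.5 compensates the slight interior depression the wide DoG lobe imposes
  on top of the PSF; on simulated disks spanning 1–4 µm² it recovers the
  true area with a mean bias of a few percent, small objects slightly
  inflated and large ones slightly trimmed. Physical area is
  `pixel_count × pixel_size_um²` at the default calibration of
  0.173 µm/pixel.
* **Borders.** Objects touching the image border are always dropped
  (truncated areas are not interpretable); objects touching the ROI
  boundary are dropped when `exclude_border` is set.

### False-positive rejection

In place of an expert-trained object classifier — whose features and
training set cannot be reproduced — the package uses explicit, auditable
rules. A candidate is accepted iff:

* its area lies within `[min_area_um2, max_area_um2]` (defaults 0.1 and
  50 µm²),
* its solidity (object pixels over convex-hull pixels) is at least
  `min_solidity` (default 0.7), and
* its contrast — object mean over local annulus mean, both on the
  *pre-enhancement* plane, where a background level exists for the ratio to
  be meaningful — reaches `min_contrast` (default 1.4), scaled up
  proportionally when local crowding exceeds `max_local_density` (default
  15 objects per 100 µm²). Crowding is counted among candidates that
  already pass the area and solidity rules, so noise specks cannot inflate
  it.

Rejected candidates are retained in the records with a `reject_reason`
(`"area"`, `"solidity"`, `"contrast"`), keeping the filter auditable. The
rule thresholds were set where the feature distributions of true objects
and spurious detections separate under the simulator's default conditions;
on dense fields with injected clutter at the noise floor, over 90% of
clutter is rejected while over 90% of true condensates are retained.

### Quantification and statistics

Accepted areas are binned on fixed µm² edges, default $\{1,2,3,4,5\}$ with
half-open bins $[l, h)$, a final open bin $[5, \infty)$, and a separately
reported sub-1 µm² tally. The edges are a declared choice: unit resolution
across the 1–5 µm² range where the biological contrast of interest lives.

The statistical unit is the subject (animal/field), never the condensate.
Per bin, per-subject counts of the two groups are compared with an unpaired
Student (pooled-variance) $t$-test — the pooled form is the default reading
of an unqualified "unpaired t-test", with Welch available via a flag — and
the per-bin p-values are adjusted across bins with the Holm–Šídák step-down
rule

$$\tilde p_{(j)} = \max_{i \le j}\ \big[1 - (1 - p_{(i)})^{\,m-i+1}\big],$$

capped at 1 and returned in the original order. Total counts are tested
separately without correction, mirroring the usual presentation of a total
panel alongside a binned panel. All tests are two-sided; bins where both
groups are constant are reported as $t = 0, p = 1$ when the constants agree
(e.g. empty top bins under the null) rather than erroring out.

### Spontaneous alternation

The one behavioural statistic included is the Y-maze spontaneous
alternation percentage: overlapping windows of three consecutive arm
entries, a window counting when it visits three distinct arms, normalised
by the number of windows, $\mathrm{SAR} = \#\text{alternations}/(n-2)
\times 100$. The overlapping-triplet convention is the standard one in the
rodent literature and is the only convention for which the $(n-2)$
denominator equals the number of windows.

## The simulator

`synthetic_spec()` describes one tissue field: nuclei placed without
overlap by rejection sampling (attempt-capped, shortfall recorded) at a
density given per 100×100 µm; per-nucleus condensate counts drawn
negative-binomially (mean/dispersion; `Inf` = Poisson, 0 = deterministic);
condensate areas drawn log-normally and rasterised as non-overlapping disks
inside their nucleus. The rendered image is the disk/nucleus structure
blurred by a Gaussian PSF, plus a constant background with a linear
gradient, plus Poisson shot noise and Gaussian read noise (clipping to the
16-bit range happens only at file-write time). Ground truth — label map,
per-object true area (`pixel count × pixel_size²` of the pre-blur disk),
centroids, nucleus mask — reflects the pre-blur geometry. Z-stacks share
one in-focus geometry; each slice adds defocus blur proportional to its
distance from a smooth sigmoidal focal surface, so opposite sides of the
field are sharp in different slices, which is what gives the EDF stage
something real to do.

Default conditions: 0.173 µm/pixel; sparse fields at 12 nuclei per
100×100 µm (cerebellum-like) and `dense_field_spec()` at 40 (the
hippocampus-like regime that stresses false-positive rejection); nucleus
radius 3 ± 0.4 µm; 6 condensates per nucleus (negative-binomial dispersion
4); areas log-normal with log-mean $\ln 2$ and log-sd 0.5, covering the
1–5 µm² range — the true size distribution is not observable, so this is a
calibration choice, not a measured fact. The knockout-like condition
(`knockout_spec()`) multiplies the count mean by 1.4 and lowers the
log-mean area by 30%, matching the qualitative contrast the pipeline is
meant to detect at n = 12 fields per group.

What the simulator does **not** emulate: tiled-scan stitching, chromatic
channels, autofluorescence, anisotropic or depth-varying PSFs, non-circular
condensates, and nucleus-to-nucleus intensity variation. Passing the
recovery tests therefore shows that the chain of operations is correct and
unbiased under its own model assumptions — it does not certify performance
on real tissue, where segmentation difficulty is dominated by exactly the
factors left out.

## Numerical choices and degenerate inputs

* Reflective padding everywhere; Gaussian truncation at $4\sigma$;
  population variance in windows.
* All tie-breaks are deterministic (lowest slice index, FIFO flood order,
  raster-scan labelling), and segmentation contains no randomness, so a
  rerun with a fixed configuration and seed is byte-identical.
* Empty cases return empty results, not errors: a foreground-free image
  yields zero records; a zero-rate spec yields an empty ground truth.
  Genuinely invalid inputs (empty ROI, non-increasing bin edges, p-values
  outside $[0,1]$, degenerate t-test groups, sequences shorter than 3
  entries) raise errors.
* Per-field seeds in a cohort are drawn from the cohort seed, and every
  seed stays below $2^{31}$.

## Problem sizes used in the shipped checks

The validation suite runs 24 noise-free 1024×1024 px fields for
ground-truth recovery (recall, precision ≥ 0.95; pooled mean-area error
≤ 10%), 100 replicate null and 100 effect cohorts at n = 12 per group for
statistical calibration (family-wise false-positive fraction ≤ 0.10;
power ≥ 0.80 in the 1–2 µm² bin), and small cohorts for byte-identity of
full reruns. The calibration studies sample per-subject counts and areas
from the generative model directly rather than rendering and re-detecting
100 × 24 images; that is the quantity the comparison consumes either way,
and the rendering path is audited separately by the recovery study.

## Known limitations

* The EDF parameters are operational re-definitions; vendor-numeric parity
  is out of reach and not claimed.
* The classical detector assumes approximately convex, blob-like spots; it
  will split strongly non-convex condensates and merge pairs closer than
  `min_distance_px` with no intensity dip between them.
* The `peak_fraction` area estimate is calibrated for the package's default
  DoG scales; substantially different $\sigma$ choices warrant re-checking
  the bias on simulated disks.
* Nested condensate-within-animal correlation is not modelled (the subject
  is the unit, matching the target study design); mixed-effects extensions
  are out of scope.
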