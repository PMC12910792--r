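# Example pipeline configuration. Paths in `manifest` must exist at run
# start; `roi` entries are optional binary TIFF masks.
pixel_size_um: 0.173
out_dir: results/pipeline
seed: 1
bins: [1, 2, 3, 4, 5]
welch: false
edf:
  window_radius_px: 4
  smoothing: 5
  contrast_length: 3
  reconstruction_factor: 0.05
enhance:
  rolling_ball_radius_px: 10
  dog_sigma_low_px: 2
  dog_sigma_high_px: 10
segmentation:
  threshold_mode: k_sigma_above_background
  threshold_value: 3
  min_distance_px: 3
classifier:
  min_solidity: 0.7
  min_contrast: 1.4
  max_local_density: 15
manifest:
  - path: results/cohort/WT_01.tif
    subject_id: WT_01
    group: WT
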