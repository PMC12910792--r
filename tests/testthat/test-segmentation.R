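test_that("blank images give no records and empty ROIs are rejected", {
  blank <- new_plane(matrix(0, 64, 64), 0.173)
  out <- segment_condensates(blank, blank)
  expect_equal(nrow(out$records), 0)
  expect_true(all(out$labels == 0))
  expect_error(segment_condensates(blank, blank,
                                   roi = matrix(FALSE, 64, 64)), "empty")
})

test_that("well-separated condensates are recovered one for one", {
  f <- generate_plane(forced_spec(5, seed = 8, size = 192L))
  res <- process_field(f$plane)
  acc <- res$records[res$records$accepted, ]
  expect_equal(nrow(acc), 5)
  mt <- match_to_truth(res$records, f$truth$objects, 0.173,
                       max_dist_um = 2 * 0.173)
  expect_equal(mt$n_matched, 5)     # every centroid within 2 px of truth
})

test_that("watershed splits touching blobs only when maxima are separated", {
  n <- 64
  bump <- function(cy, cx, h) {
    outer(1:n, 1:n, function(i, j) h * exp(-((i - cy)^2 + (j - cx)^2) / 18))
  }
  e <- new_plane(bump(32, 28, 100) + bump(32, 40, 99), 1)
  raw <- new_plane(unclass(e) + 10, 1)
  split <- segment_condensates(e, raw, params = segmentation_params(
    threshold_mode = "absolute", threshold_value = 5, min_distance_px = 3,
    peak_fraction = 0))
  expect_equal(nrow(split$records), 2)
  merged <- segment_condensates(e, raw, params = segmentation_params(
    threshold_mode = "absolute", threshold_value = 5, min_distance_px = 15,
    peak_fraction = 0))
  expect_equal(nrow(merged$records), 1)
})

test_that("accepted record ids appear in the label map with matching pixels", {
  f <- generate_plane(clean_spec(seed = 12))
  res <- process_field(f$plane)
  for (k in seq_len(nrow(res$records))) {
    expect_equal(sum(res$labels == res$records$id[k]),
                 res$records$pixel_count[k])
  }
  expect_equal(res$records$area_um2,
               res$records$pixel_count * 0.173^2)
})

test_that("segmentation is deterministic", {
  f <- generate_plane(synthetic_spec(field_size_px = c(160L, 160L), seed = 5))
  r1 <- process_field(f$plane)
  r2 <- process_field(f$plane)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$labels, r2$labels)
})

test_that("areas convert to square micrometres by the calibration square", {
  expect_equal(measure_area(100, 0.173), 2.9929)
  expect_equal(measure_area(33, 0.173), 0.987657)
  expect_equal(measure_area(1, 1), 1)
  expect_error(measure_area(0, 1))
})

test_that("classifier rules produce the documented reject reasons", {
  n <- 40
  m <- matrix(100, n, n)
  labels <- matrix(0L, n, n)
  put_block <- function(labels, m, id, r, c, w, value) {
    labels[r:(r + w - 1), c:(c + w - 1)] <- id
    m[r:(r + w - 1), c:(c + w - 1)] <- value
    list(labels = labels, m = m)
  }
  s <- put_block(labels, m, 1L, 5, 5, 3, 500)       # strong object
  s <- put_block(s$labels, s$m, 2L, 5, 25, 3, 108)  # weak contrast
  s <- put_block(s$labels, s$m, 3L, 25, 5, 3, 500)  # will fail solidity
  recs <- data.frame(id = 1:3, pixel_count = 9, area_um2 = 9,
                     centroid_y = c(5, 5, 25), centroid_x = c(5, 25, 5),
                     mean_intensity = c(500, 108, 500), peak_enhanced = 1,
                     solidity = c(1, 1, 0.4), roi_name = "field",
                     accepted = NA, reject_reason = "")
  out <- classify_condensates(recs, s$labels, new_plane(s$m, 1),
                              classifier_rules(),
                              segmentation_params(min_area_um2 = 0.1,
                                                  max_area_um2 = 50))
  expect_equal(out$accepted, c(TRUE, FALSE, FALSE))
  expect_equal(out$reject_reason, c("", "contrast", "solidity"))
  # area rule: same strong object but an admissible range that excludes it
  out2 <- classify_condensates(recs[1, ], s$labels, new_plane(s$m, 1),
                               classifier_rules(),
                               segmentation_params(min_area_um2 = 20,
                                                   max_area_um2 = 50))
  expect_false(out2$accepted)
  expect_equal(out2$reject_reason, "area")
})

test_that("dense fields with injected clutter keep truth and drop clutter", {
  spec <- dense_field_spec(field_size_px = c(512L, 512L), seed = 77)
  f <- generate_plane(spec)
  img <- unclass(f$plane)
  # inject dim clutter disks (amplitude at the read-noise floor) in free space
  set.seed(99)
  n_clutter <- 40
  pos <- cbind(sample(30:480, n_clutter), sample(30:480, n_clutter))
  for (k in seq_len(n_clutter)) {
    r <- 3
    rows <- (pos[k, 1] - r):(pos[k, 1] + r)
    cols <- (pos[k, 2] - r):(pos[k, 2] + r)
    d <- outer(rows - pos[k, 1], cols - pos[k, 2],
               function(a, b) a^2 + b^2) <= r^2
    img[rows, cols][d] <- img[rows, cols][d] + spec$noise_read_sd
  }
  res <- process_field(new_plane(img, 0.173))
  acc <- res$records[res$records$accepted, ]
  # clutter: accepted objects within 2 px of an injected position
  clutter_hit <- vapply(seq_len(n_clutter), function(k) {
    any(abs(acc$centroid_y - (pos[k, 1] - 1)) <= 2 &
          abs(acc$centroid_x - (pos[k, 2] - 1)) <= 2)
  }, logical(1))
  expect_lte(mean(clutter_hit), 0.10)
  mt <- match_to_truth(res$records, f$truth$objects, 0.173)
  expect_gte(mt$recall, 0.90)
})
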