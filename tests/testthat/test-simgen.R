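test_that("spec validation rejects non-positive dimensions and pixel size", {
  expect_error(synthetic_spec(field_size_px = c(0, 64)), "field_size_px")
  expect_error(synthetic_spec(pixel_size_um = 0), "pixel_size_um")
  expect_error(synthetic_spec(n_z_slices = 0), "n_z_slices")
})

test_that("zero condensate rate yields an empty ground truth", {
  f <- generate_plane(clean_spec(condensates_per_nucleus = 0))
  expect_equal(nrow(f$truth$objects), 0)
  expect_true(all(f$truth$label_map == 0))
})

test_that("forced counts give exactly that many labelled objects", {
  f <- generate_plane(forced_spec(3))
  expect_equal(nrow(f$truth$objects), 3)
  expect_setequal(unique(as.vector(f$truth$label_map[f$truth$label_map > 0])),
                  1:3)
})

test_that("ground truth is internally consistent", {
  f <- generate_plane(clean_spec(seed = 5))
  lm <- f$truth$label_map
  obj <- f$truth$objects
  # consecutive ids, map matches table
  expect_equal(sort(unique(as.vector(lm[lm > 0]))), seq_len(nrow(obj)))
  # per-object true area equals pixel count times pixel_size^2
  ps <- 0.173
  for (k in seq_len(nrow(obj))) {
    expect_equal(obj$true_area_um2[k], sum(lm == k) * ps^2)
  }
  # every labelled pixel lies inside a nucleus
  expect_true(all(f$truth$nucleus_mask[lm > 0]))
})

test_that("sampled true areas match the log-normal mean", {
  mu <- log(2); s <- 0.5
  areas <- unlist(lapply(1:6, function(i) sample_truth_areas(
    synthetic_spec(field_size_px = c(1024L, 1024L), nucleus_density = 30,
                   condensates_per_nucleus = 8,
                   condensate_area_meanlog = mu, condensate_area_sdlog = s),
    seed = i)))
  expect_gt(length(areas), 500)
  expected <- exp(mu + s^2 / 2)
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas) - expected), 3 * se)
})

test_that("identical spec and seed reproduce the field bit for bit", {
  spec <- synthetic_spec(field_size_px = c(128L, 128L), seed = 11)
  f1 <- generate_plane(spec)
  f2 <- generate_plane(spec)
  expect_identical(unclass(f1$plane), unclass(f2$plane))
  expect_identical(f1$truth$label_map, f2$truth$label_map)
  expect_identical(f1$truth$objects, f2$truth$objects)
})

test_that("with zero noise condensates outshine nuclei outshine background", {
  f <- generate_plane(clean_spec(seed = 2))
  img <- unclass(f$plane)
  lm <- f$truth$label_map
  nuc <- f$truth$nucleus_mask
  m_cond <- mean(img[lm > 0])
  m_nuc <- mean(img[nuc & lm == 0])
  m_bg <- mean(img[!nuc])
  expect_gt(m_cond, m_nuc)
  expect_gt(m_nuc, m_bg)
})

test_that("single-slice stack equals the plane for the same seed", {
  spec <- clean_spec(seed = 4, n_z_slices = 1L)
  st <- generate_stack(spec)
  pl <- generate_plane(spec)
  expect_equal(unclass(stack_slice(st$stack, 1)), unclass(pl$plane))
})

test_that("zero defocus gives identical slices at zero noise", {
  spec <- clean_spec(seed = 4, n_z_slices = 3L,
                     defocus_sigma_per_slice_um = 0)
  st <- generate_stack(spec)$stack
  expect_equal(unclass(st)[, , 1], unclass(st)[, , 2])
  expect_equal(unclass(st)[, , 2], unclass(st)[, , 3])
})

test_that("the focal surface makes opposite halves sharp in opposite slices", {
  spec <- clean_spec(seed = 9, size = 192L, n_z_slices = 2L,
                     defocus_sigma_per_slice_um = 1.2,
                     nucleus_density = 25)
  st <- generate_stack(spec)$stack
  n <- dim(st)[2]
  left <- 1:(n %/% 3); right <- (2 * n %/% 3):n
  v <- function(z) local_variance(unclass(st)[, , z], 4)
  v1 <- v(1); v2 <- v(2)
  # slice 1 focuses the left half, slice 2 the right half
  expect_gt(mean(v1[, left]), mean(v2[, left]))
  expect_gt(mean(v2[, right]), mean(v1[, right]))
})

test_that("cohorts have the requested size, labels, and a null is a null", {
  spec <- clean_spec(size = 160L, nucleus_density = 40)
  coh <- generate_cohort(spec, spec, n_per_group = 12, seed = 3)
  expect_length(coh$fields, 24)
  expect_equal(as.vector(table(coh$meta$group)), c(12, 12))
  expect_equal(anyDuplicated(coh$meta$field_seed), 0)
  # identical specs: pooled truth area distributions indistinguishable
  areas <- lapply(seq_len(24), function(i)
    coh$fields[[i]]$truth$objects$true_area_um2)
  a <- unlist(areas[coh$meta$group == "WT"])
  b <- unlist(areas[coh$meta$group == "cKO"])
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
})

test_that("knockout spec raises ground-truth counts in nearly all cohorts", {
  spec <- synthetic_spec()
  ko <- knockout_spec(spec)
  wins <- vapply(1:100, function(r) {
    tot_a <- vapply(1:12, function(i)
      length(sample_truth_areas(spec, seed = r * 1000 + i)), numeric(1))
    tot_b <- vapply(1:12, function(i)
      length(sample_truth_areas(ko, seed = r * 1000 + 500 + i)), numeric(1))
    mean(tot_b) > mean(tot_a)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("fields round-trip through TIFF and CSV on disk", {
  f <- generate_plane(clean_spec(seed = 6, size = 160L, nucleus_density = 40))
  prefix <- file.path(tempdir(), "field_rt")
  paths <- write_field(f, prefix)
  img <- read_image_tiff(paths["image"], 0.173)
  expect_equal(unclass(img), round(unclass(f$plane)), tolerance = 1e-12)
  expect_identical(read_label_tiff(paths["labels"]), f$truth$label_map)
  tab <- read.csv(paths["objects"])
  expect_equal(tab$true_area_um2, f$truth$objects$true_area_um2)
  unlink(paths)
})
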