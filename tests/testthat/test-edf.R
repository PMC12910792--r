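test_that("local variance is zero on constants and quadratic under scaling", {
  expect_true(all(local_variance(matrix(7, 16, 16), 2) == 0))
  m <- matrix(rnorm(20 * 20), 20, 20)
  expect_equal(local_variance(3 * m, 3), 9 * local_variance(m, 3),
               tolerance = 1e-12)
  expect_error(local_variance(m, 0), "window_radius_px")
})

test_that("window variance matches the direct population formula", {
  m <- matrix(0, 5, 5)
  m[2:4, 2:4] <- matrix(c(4, 0, 7, 2, 8, 1, 5, 3, 6), 3, 3)
  v <- local_variance(m, 1)
  expect_equal(v[3, 3], mean((0:8 - 4)^2))   # population variance of 0..8
  # random interior pixels against the naive window computation
  m2 <- matrix(rnorm(15 * 17), 15, 17)
  v2 <- local_variance(m2, 2)
  for (px in list(c(5, 6), c(1, 1), c(15, 17), c(8, 3))) {
    expect_equal(v2[px[1], px[2]],
                 naive_window_variance(m2, px[1], px[2], 2),
                 tolerance = 1e-10)
  }
})

test_that("edf parameter validation enforces the documented ranges", {
  expect_error(edf_params(window_radius_px = 0))
  expect_error(edf_params(reconstruction_factor = 1.5))
  expect_error(edf_params(align_stack = TRUE), "alignment")
})

test_that("single-slice and constant stacks project to themselves", {
  spec <- clean_spec(seed = 3, size = 96L)
  pl <- generate_plane(spec)$plane
  st1 <- new_zstack(array(unclass(pl), dim = c(dim(pl), 1)), 0.173)
  out1 <- edf_variance(st1, edf_params())
  expect_equal(unclass(out1$plane), unclass(pl))
  expect_true(all(out1$index_map == 0))
  st3 <- new_zstack(array(rep(unclass(pl), 3), dim = c(dim(pl), 3)), 0.173)
  out3 <- edf_variance(st3, edf_params())
  expect_equal(unclass(out3$plane), unclass(pl), tolerance = 1e-12)
})

test_that("slice selection matches the brute-force variance argmax", {
  spec <- clean_spec(seed = 9, size = 160L, n_z_slices = 2L,
                     defocus_sigma_per_slice_um = 1.5, nucleus_density = 30)
  st <- generate_stack(spec)$stack
  r <- 4
  out <- edf_variance(st, edf_params(window_radius_px = r, smoothing = 0,
                                     reconstruction_factor = 0))
  data <- unclass(st)
  v1 <- local_variance(data[, , 1], r); v2 <- local_variance(data[, , 2], r)
  oracle <- ifelse(v2 > v1, 1L, 0L)
  # away from the central focus boundary the smoothed pipeline agrees
  n <- dim(st)[2]
  margin <- abs(col(oracle) - n / 2) > n / 8
  expect_gte(mean(out$index_map[margin] == oracle[margin]), 0.95)
  # with smoothing 0 and factor 0 the output is the selected slice exactly
  flat <- cbind(seq_along(out$index_map),
                as.vector(out$index_map) + 1L)
  sel <- matrix(data[cbind((seq_along(out$index_map) - 1) %% nrow(oracle) + 1,
                           (seq_along(out$index_map) - 1) %/% nrow(oracle) + 1,
                           as.vector(out$index_map) + 1L)],
                nrow(oracle), ncol(oracle))
  got <- unclass(out$plane); attr(got, "pixel_size_um") <- NULL
  expect_equal(got, sel)
})

test_that("EDF output stays within the stack intensity range", {
  spec <- synthetic_spec(field_size_px = c(128L, 128L), seed = 21,
                         n_z_slices = 4L, defocus_sigma_per_slice_um = 0.8)
  st <- generate_stack(spec)$stack
  out <- edf_variance(st, edf_params())
  expect_gte(min(out$plane), min(st))
  expect_lte(max(out$plane), max(st))
})

test_that("re-projecting a stack of EDF copies returns the EDF plane", {
  spec <- synthetic_spec(field_size_px = c(96L, 96L), seed = 13,
                         n_z_slices = 3L, defocus_sigma_per_slice_um = 1)
  st <- generate_stack(spec)$stack
  edf1 <- edf_variance(st, edf_params())$plane
  st2 <- new_zstack(array(rep(unclass(edf1), 3), dim = c(dim(edf1), 3)), 0.173)
  edf2 <- edf_variance(st2, edf_params())$plane
  expect_equal(unclass(edf2), unclass(edf1), tolerance = 1e-12)
})

test_that("EDF is closer to the in-focus truth than the worst slice", {
  spec <- clean_spec(seed = 17, size = 192L, n_z_slices = 3L,
                     defocus_sigma_per_slice_um = 1.5, nucleus_density = 25)
  g <- generate_stack(spec)
  truth <- unclass(g$in_focus)
  mse <- function(m) mean((m - truth)^2)
  edf <- edf_variance(g$stack, edf_params())$plane
  worst <- max(vapply(1:3, function(z) mse(unclass(g$stack)[, , z]),
                      numeric(1)))
  expect_lt(mse(unclass(edf)), worst)
})

test_that("empty stacks are rejected", {
  expect_error(edf_variance(new_plane(matrix(0, 4, 4), 1), edf_params()))
})
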