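#' Specification of a synthetic fluorescence tissue field
#'
#' Bundles every parameter needed to simulate one field of nuclei carrying
#' bright nuclear condensates: geometry, intensities, optics and noise.
#' Defaults describe a sparse, cerebellum-like field imaged at the
#' calibration used throughout the package (0.173 um/pixel).
#'
#' @param field_size_px integer pair, image size in pixels (rows, cols).
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param nucleus_density nuclei per 100 x 100 um tissue area.
#' @param nucleus_radius_um mean nucleus radius in um.
#' @param nucleus_radius_jitter_um Gaussian sd of the nucleus radius.
#' @param condensates_per_nucleus mean of the per-nucleus condensate count.
#' @param condensate_dispersion negative-binomial size parameter of the count
#'   distribution; `Inf` gives a Poisson count, `0` a deterministic count of
#'   `round(condensates_per_nucleus)` per nucleus.
#' @param condensate_area_meanlog,condensate_area_sdlog log-normal parameters
#'   of the true condensate area in um^2.
#' @param condensate_min_gap_um minimum edge-to-edge gap between condensates
#'   within a nucleus (um).
#' @param condensate_peak_intensity intensity added inside a condensate disk,
#'   on top of the nuclear level.
#' @param nucleus_intensity diffuse intensity added inside nuclei.
#' @param background_level constant background offset.
#' @param background_gradient numeric pair: linear intensity slope per pixel
#'   along rows and columns.
#' @param psf_sigma_um Gaussian point-spread-function sigma in um.
#' @param noise_poisson_gain photons per intensity unit for shot noise;
#'   0 disables shot noise.
#' @param noise_read_sd Gaussian read-noise standard deviation; 0 disables.
#' @param n_z_slices number of Z slices (>= 1).
#' @param defocus_sigma_per_slice_um extra Gaussian blur sigma per slice of
#'   defocus distance (um).
#' @param seed integer RNG seed; identical spec + seed reproduces the field
#'   bit for bit.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(field_size_px = c(512L, 512L),
                           pixel_size_um = 0.173,
                           nucleus_density = 12,
                           nucleus_radius_um = 3,
                           nucleus_radius_jitter_um = 0.4,
                           condensates_per_nucleus = 6,
                           condensate_dispersion = 4,
                           condensate_area_meanlog = log(2),
                           condensate_area_sdlog = 0.5,
                           condensate_min_gap_um = 0.2,
                           condensate_peak_intensity = 3000,
                           nucleus_intensity = 1200,
                           background_level = 600,
                           background_gradient = c(0.2, 0.2),
                           psf_sigma_um = 0.2,
                           noise_poisson_gain = 0.05,
                           noise_read_sd = 60,
                           n_z_slices = 1L,
                           defocus_sigma_per_slice_um = 0,
                           seed = 1L) {
  spec <- list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    nucleus_density = nucleus_density,
    nucleus_radius_um = nucleus_radius_um,
    nucleus_radius_jitter_um = nucleus_radius_jitter_um,
    condensates_per_nucleus = condensates_per_nucleus,
    condensate_dispersion = condensate_dispersion,
    condensate_area_meanlog = condensate_area_meanlog,
    condensate_area_sdlog = condensate_area_sdlog,
    condensate_min_gap_um = condensate_min_gap_um,
    condensate_peak_intensity = condensate_peak_intensity,
    nucleus_intensity = nucleus_intensity,
    background_level = background_level,
    background_gradient = background_gradient,
    psf_sigma_um = psf_sigma_um,
    noise_poisson_gain = noise_poisson_gain,
    noise_read_sd = noise_read_sd,
    n_z_slices = as.integer(n_z_slices),
    defocus_sigma_per_slice_um = defocus_sigma_per_slice_um,
    seed = as.integer(seed)
  )
  validate_synthetic_spec(spec)
  class(spec) <- "synthetic_spec"
  spec
}

validate_synthetic_spec <- function(spec) {
  if (length(spec$field_size_px) != 2 || any(spec$field_size_px <= 0)) {
    stop("field_size_px must be two positive integers")
  }
  if (spec$pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (spec$nucleus_radius_um <= 0) stop("nucleus_radius_um must be positive")
  if (spec$condensates_per_nucleus < 0) stop("condensates_per_nucleus must be >= 0")
  if (spec$condensate_area_sdlog < 0) stop("condensate_area_sdlog must be >= 0")
  if (spec$n_z_slices < 1) stop("n_z_slices must be >= 1")
  if (spec$defocus_sigma_per_slice_um < 0) stop("defocus must be >= 0")
  if (spec$noise_read_sd < 0 || spec$noise_poisson_gain < 0) {
    stop("noise parameters must be >= 0")
  }
  invisible(spec)
}

#' Preset: dense, hippocampus-like field
#'
#' Same optics and intensities as the default sparse preset but with a high
#' nucleus density, the regime that stresses false-positive rejection.
#'
#' @param ... overrides passed on to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
dense_field_spec <- function(...) {
  args <- list(nucleus_density = 40, nucleus_radius_um = 2.6,
               condensate_min_gap_um = 0.1)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_spec, args)
}

#' Modify a spec to emulate the knockout phenotype
#'
#' Returns a copy of `spec` with the condensate count mean multiplied and the
#' log-mean area shifted down, the "more and smaller condensates" contrast
#' the pipeline is designed to detect.
#'
#' @param spec a `synthetic_spec`.
#' @param count_factor multiplier on the per-nucleus count mean (default 1.4).
#' @param area_logmean_shift relative reduction of the area log-mean
#'   (default 0.3 = 30 percent smaller log-mean).
#' @return a modified `synthetic_spec`.
#' @export
knockout_spec <- function(spec, count_factor = 1.4, area_logmean_shift = 0.3) {
  spec$condensates_per_nucleus <- spec$condensates_per_nucleus * count_factor
  spec$condensate_area_meanlog <- spec$condensate_area_meanlog * (1 - area_logmean_shift)
  spec
}

# --- geometry sampling ------------------------------------------------------

draw_count <- function(n, mean, dispersion) {
  if (mean == 0) return(integer(n))
  if (dispersion == 0) return(rep(as.integer(round(mean)), n))
  if (is.finite(dispersion)) {
    stats::rnbinom(n, size = dispersion, mu = mean)
  } else {
    stats::rpois(n, mean)
  }
}

# Sample nucleus centres/radii and condensate disks by rejection sampling.
# Consumes the RNG stream; callers seed it. Returns the geometry and a
# shortfall count (objects that could not be placed within the attempt cap).
sample_geometry <- function(spec, max_attempts = 200L) {
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  ps <- spec$pixel_size_um
  area_um2 <- nr * nc * ps^2
  n_nuclei <- round(spec$nucleus_density * area_um2 / 1e4)

  nuc <- data.frame(id = integer(), cy = numeric(), cx = numeric(), r_px = numeric())
  shortfall_nuclei <- 0L
  for (i in seq_len(n_nuclei)) {
    r_um <- max(0.5, stats::rnorm(1, spec$nucleus_radius_um,
                                  spec$nucleus_radius_jitter_um))
    r_px <- r_um / ps
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      cy <- stats::runif(1, r_px, nr - 1 - r_px)
      cx <- stats::runif(1, r_px, nc - 1 - r_px)
      if (nrow(nuc) == 0 ||
          all((nuc$cy - cy)^2 + (nuc$cx - cx)^2 >= (nuc$r_px + r_px)^2)) {
        nuc <- rbind(nuc, data.frame(id = nrow(nuc) + 1L, cy = cy, cx = cx,
                                     r_px = r_px))
        placed <- TRUE
        break
      }
    }
    if (!placed) shortfall_nuclei <- shortfall_nuclei + 1L
  }

  counts <- draw_count(nrow(nuc), spec$condensates_per_nucleus,
                       spec$condensate_dispersion)
  gap_px <- spec$condensate_min_gap_um / ps
  cond <- data.frame(id = integer(), nucleus_id = integer(),
                     cy = numeric(), cx = numeric(), r_px = numeric())
  shortfall_cond <- 0L
  for (i in seq_len(nrow(nuc))) {
    placed_here <- cond[cond$nucleus_id == 0, ]  # empty template
    for (j in seq_len(counts[i])) {
      a_um2 <- stats::rlnorm(1, spec$condensate_area_meanlog,
                             spec$condensate_area_sdlog)
      r_px <- sqrt(a_um2 / pi) / ps
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        if (nuc$r_px[i] <= r_px) break        # condensate larger than nucleus
        rad <- sqrt(stats::runif(1)) * (nuc$r_px[i] - r_px)
        th <- stats::runif(1, 0, 2 * pi)
        cy <- nuc$cy[i] + rad * sin(th)
        cx <- nuc$cx[i] + rad * cos(th)
        sibs <- cond[cond$nucleus_id == i, ]
        if (nrow(sibs) == 0 ||
            all((sibs$cy - cy)^2 + (sibs$cx - cx)^2 >=
                (sibs$r_px + r_px + gap_px)^2)) {
          cond <- rbind(cond, data.frame(id = nrow(cond) + 1L, nucleus_id = i,
                                         cy = cy, cx = cx, r_px = r_px))
          placed <- TRUE
          break
        }
      }
      if (!placed) shortfall_cond <- shortfall_cond + 1L
    }
  }
  list(nuclei = nuc, condensates = cond,
       shortfall = c(nuclei = shortfall_nuclei, condensates = shortfall_cond))
}

# Rasterise disks onto label / mask images. A disk covers the pixels whose
# centres fall within its radius; disks too small to cover any pixel centre
# claim the pixel nearest their centre so every object exists in the map.
rasterize_geometry <- function(geom, nr, nc, ps) {
  label_map <- matrix(0L, nr, nc)
  nucleus_mask <- matrix(FALSE, nr, nc)
  paint_disk <- function(cy, cx, r_px) {
    r0 <- max(0L, floor(cy - r_px)); r1 <- min(nr - 1L, ceiling(cy + r_px))
    c0 <- max(0L, floor(cx - r_px)); c1 <- min(nc - 1L, ceiling(cx + r_px))
    if (r1 < r0 || c1 < c0) return(NULL)
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
    list(rows = rows, cols = cols, inside = d2 <= r_px^2)
  }
  for (i in seq_len(nrow(geom$nuclei))) {
    n <- geom$nuclei[i, ]
    p <- paint_disk(n$cy, n$cx, n$r_px)
    if (!is.null(p)) {
      nucleus_mask[p$rows + 1, p$cols + 1][p$inside] <- TRUE
    }
  }
  objects <- geom$condensates
  objects$true_area_um2 <- rep(NA_real_, nrow(objects))
  for (i in seq_len(nrow(objects))) {
    o <- objects[i, ]
    p <- paint_disk(o$cy, o$cx, o$r_px)
    npix <- 0L
    if (!is.null(p) && any(p$inside)) {
      sub <- label_map[p$rows + 1, p$cols + 1]
      put <- p$inside & sub == 0L
      sub[put] <- i
      label_map[p$rows + 1, p$cols + 1] <- sub
      npix <- sum(put)
    }
    if (npix == 0L) {
      rr <- min(max(round(o$cy), 0), nr - 1); cc <- min(max(round(o$cx), 0), nc - 1)
      if (label_map[rr + 1, cc + 1] == 0L) {
        label_map[rr + 1, cc + 1] <- i
        npix <- 1L
      }
    }
    objects$true_area_um2[i] <- npix * ps^2
  }
  list(label_map = label_map, nucleus_mask = nucleus_mask, objects = objects)
}

# Smooth focal-depth surface: a sigmoidal ramp across columns from slice 0 to
# slice n_z - 1, so different parts of the field are sharp in different
# slices.
focus_surface <- function(nr, nc, n_z) {
  if (n_z == 1) return(matrix(0, nr, nc))
  x <- seq_len(nc) - 1
  ramp <- stats::plogis((x - (nc - 1) / 2) / (nc / 12))
  matrix(rep(ramp * (n_z - 1), each = nr), nr, nc)
}

apply_noise <- function(img, gain, read_sd) {
  if (gain > 0) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0) * gain) / gain,
                  nrow(img), ncol(img))
  }
  if (read_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, read_sd),
                        nrow(img), ncol(img))
  }
  img
}

# Blend between precomputed blur levels to emulate a per-pixel blur amount.
blend_blur_levels <- function(levels, amount) {
  n <- length(levels)
  if (n == 1) return(levels[[1]])
  amount <- pmin(pmax(amount, 0), n - 1)
  lo <- pmin(floor(amount), n - 2)
  frac <- amount - lo
  out <- matrix(0, nrow(amount), ncol(amount))
  for (j in 0:(n - 2)) {
    sel <- lo == j
    if (any(sel)) {
      out[sel] <- (1 - frac[sel]) * levels[[j + 1]][sel] +
        frac[sel] * levels[[j + 2]][sel]
    }
  }
  out
}

#' Generate a synthetic Z-stack with ground truth
#'
#' Samples the field geometry once (nuclei, condensate disks), renders an
#' in-focus image blurred by the PSF, then produces each slice by adding
#' defocus blur proportional to the distance between the slice index and a
#' smooth focal surface, plus background and per-slice noise. The ground
#' truth reflects the pre-blur geometry.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `stack` (a `zstack`), `truth` (list:
#'   `label_map`, `objects` data frame with true areas in um^2, `nuclei`,
#'   `nucleus_mask`, `shortfall`), and `in_focus` (the noise-free, PSF-blurred
#'   plane with background, before defocus/noise).
#' @export
generate_stack <- function(spec) {
  validate_synthetic_spec(spec)
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  ps <- spec$pixel_size_um
  set.seed(spec$seed)

  geom <- sample_geometry(spec)
  ras <- rasterize_geometry(geom, nr, nc, ps)

  structure_img <- matrix(0, nr, nc)
  structure_img[ras$nucleus_mask] <- spec$nucleus_intensity
  structure_img[ras$label_map > 0] <- structure_img[ras$label_map > 0] +
    spec$condensate_peak_intensity

  psf_px <- spec$psf_sigma_um / ps
  in_focus <- cpp_gaussian_blur(structure_img, psf_px)

  bg <- spec$background_level +
    outer((seq_len(nr) - 1) * spec$background_gradient[1],
          (seq_len(nc) - 1) * spec$background_gradient[2], `+`)

  n_z <- spec$n_z_slices
  defocus_px <- spec$defocus_sigma_per_slice_um / ps
  zf <- focus_surface(nr, nc, n_z)
  if (defocus_px > 0 && n_z > 1) {
    levels <- lapply(0:(n_z - 1), function(j) {
      if (j == 0) in_focus else cpp_gaussian_blur(in_focus, defocus_px * j)
    })
  } else {
    levels <- list(in_focus)
  }
  slices <- array(0, dim = c(nr, nc, n_z))
  for (z in seq_len(n_z)) {
    amount <- if (defocus_px > 0) abs((z - 1) - zf) else matrix(0, nr, nc)
    img <- blend_blur_levels(levels, amount) + bg
    slices[, , z] <- apply_noise(img, spec$noise_poisson_gain, spec$noise_read_sd)
  }

  truth <- list(label_map = ras$label_map,
                objects = ras$objects,
                nuclei = geom$nuclei,
                nucleus_mask = ras$nucleus_mask,
                shortfall = geom$shortfall)
  list(stack = new_zstack(slices, ps),
       truth = truth,
       in_focus = new_plane(in_focus + bg, ps))
}

#' Generate a single synthetic plane with ground truth
#'
#' Equivalent to [generate_stack()] with one slice; returns the slice as a
#' `plane`.
#'
#' @param spec a [synthetic_spec()]; `n_z_slices` is ignored (forced to 1).
#' @return list with `plane`, `truth` and `in_focus` (see [generate_stack()]).
#' @export
generate_plane <- function(spec) {
  spec$n_z_slices <- 1L
  res <- generate_stack(spec)
  list(plane = stack_slice(res$stack, 1), truth = res$truth,
       in_focus = res$in_focus)
}

#' Generate a two-group cohort of synthetic fields
#'
#' Produces `n_per_group` fields per group with per-field seeds derived from
#' the cohort seed, and a metadata table mapping each field to its group.
#'
#' @param spec_a,spec_b `synthetic_spec`s for the two groups.
#' @param n_per_group fields per group (>= 1).
#' @param seed cohort-level seed.
#' @param group_names character pair naming the groups.
#' @param stacks if TRUE generate Z-stacks, else single planes.
#' @return list with `fields` (list of [generate_plane()] /
#'   [generate_stack()] results) and `meta` (data frame: subject_id, group,
#'   field_seed).
#' @export
generate_cohort <- function(spec_a, spec_b, n_per_group, seed = 1L,
                            group_names = c("WT", "cKO"), stacks = FALSE) {
  stopifnot(n_per_group >= 1)
  set.seed(seed)
  n_total <- 2L * n_per_group
  field_seeds <- sample.int(.Machine$integer.max, n_total)
  meta <- data.frame(
    subject_id = sprintf("%s_%02d", rep(group_names, each = n_per_group),
                         rep(seq_len(n_per_group), 2)),
    group = rep(group_names, each = n_per_group),
    field_seed = field_seeds,
    stringsAsFactors = FALSE
  )
  fields <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    spec <- if (meta$group[i] == group_names[1]) spec_a else spec_b
    spec$seed <- meta$field_seed[i]
    fields[[i]] <- if (stacks) generate_stack(spec) else generate_plane(spec)
  }
  list(fields = fields, meta = meta)
}

#' Sample per-field ground-truth condensate areas without rendering images
#'
#' Draws the same count and size distributions the image generator uses but
#' skips geometry placement and rendering, giving a fast generative-model
#' path for statistical calibration studies.
#'
#' @param spec a `synthetic_spec`.
#' @param seed RNG seed for this draw.
#' @return numeric vector of condensate areas (um^2) for one field.
#' @export
sample_truth_areas <- function(spec, seed) {
  set.seed(seed)
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  n_nuclei <- round(spec$nucleus_density * nr * nc * spec$pixel_size_um^2 / 1e4)
  counts <- draw_count(n_nuclei, spec$condensates_per_nucleus,
                       spec$condensate_dispersion)
  n <- sum(counts)
  if (n == 0) return(numeric(0))
  stats::rlnorm(n, spec$condensate_area_meanlog, spec$condensate_area_sdlog)
}

#' Write a synthetic field to disk
#'
#' Writes the image as 16-bit TIFF, the ground-truth labels as a label TIFF,
#' and the object table as CSV.
#'
#' @param field result of [generate_plane()] or [generate_stack()].
#' @param prefix output path prefix (files `<prefix>.tif`,
#'   `<prefix>_labels.tif`, `<prefix>_objects.csv`).
#' @return character vector of paths written, invisibly.
#' @export
write_field <- function(field, prefix) {
  img <- if (!is.null(field$plane)) field$plane else field$stack
  paths <- c(image = paste0(prefix, ".tif"),
             labels = paste0(prefix, "_labels.tif"),
             objects = paste0(prefix, "_objects.csv"))
  write_image_tiff(img, paths["image"])
  write_label_tiff(field$truth$label_map, paths["labels"])
  utils::write.csv(field$truth$objects, paths["objects"], row.names = FALSE)
  invisible(paths)
}
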