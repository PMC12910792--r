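#' Segmentation parameters
#'
#' @param threshold_mode `"k_sigma_above_background"` (robust: median plus
#'   `threshold_value` times 1.4826 MAD of the enhanced image inside the ROI)
#'   or `"absolute"` (`threshold_value` is the raw cutoff).
#' @param threshold_value the k multiplier (default 3) or the absolute cutoff.
#' @param min_distance_px minimum separation of watershed seed maxima (>= 1).
#' @param min_area_um2,max_area_um2 admissible object area range used by the
#'   false-positive classifier.
#' @param exclude_border drop objects touching the ROI boundary (objects
#'   touching the image border are always dropped).
#' @param peak_fraction each object is trimmed to the pixels at or above this
#'   fraction of its own peak enhanced intensity, a blur-robust area
#'   estimate; 0 keeps the full watershed support.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_mode = c("k_sigma_above_background",
                                                   "absolute"),
                                threshold_value = 3,
                                min_distance_px = 3L,
                                min_area_um2 = 0.1,
                                max_area_um2 = 50,
                                exclude_border = FALSE,
                                peak_fraction = 0.35) {
  threshold_mode <- match.arg(threshold_mode)
  if (min_distance_px < 1) stop("min_distance_px must be >= 1")
  if (!(min_area_um2 < max_area_um2)) stop("min_area_um2 must be < max_area_um2")
  if (peak_fraction < 0 || peak_fraction >= 1) {
    stop("peak_fraction must lie in [0, 1)")
  }
  structure(list(threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_distance_px = as.integer(min_distance_px),
                 min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2,
                 exclude_border = isTRUE(exclude_border),
                 peak_fraction = peak_fraction),
            class = "segmentation_params")
}

#' Rules of the false-positive classifier
#'
#' An explicit, auditable stand-in for an expert-trained object classifier:
#' objects must be within the admissible area range, sufficiently compact
#' (solidity), and sufficiently contrasted against their local surround,
#' with the contrast requirement scaled up in crowded neighbourhoods.
#'
#' @param min_solidity minimum solidity (object pixels / convex-hull pixels).
#' @param min_contrast minimum ratio of object mean to local annulus mean on
#'   the reference (pre-enhancement) image.
#' @param max_local_density objects per 100 um^2 above which the contrast
#'   requirement scales proportionally with crowding.
#' @param annulus_width_px width of the background annulus around each
#'   object, in pixels.
#' @return a `classifier_rules` list.
#' @export
classifier_rules <- function(min_solidity = 0.7,
                             min_contrast = 1.4,
                             max_local_density = 15,
                             annulus_width_px = 3L) {
  stopifnot(min_solidity > 0, min_contrast > 0, max_local_density > 0)
  structure(list(min_solidity = min_solidity,
                 min_contrast = min_contrast,
                 max_local_density = max_local_density,
                 annulus_width_px = as.integer(annulus_width_px)),
            class = "classifier_rules")
}

#' Physical object area from a pixel count
#'
#' @param pixel_count number of pixels (>= 1).
#' @param pixel_size_um micrometres per pixel (> 0).
#' @return area in um^2 (`pixel_count * pixel_size_um^2`).
#' @export
measure_area <- function(pixel_count, pixel_size_um) {
  stopifnot(all(pixel_count >= 1), pixel_size_um > 0)
  pixel_count * pixel_size_um^2
}

# Solidity = object pixels / pixels inside (or on) the convex hull of the
# object's pixel centres. Always <= 1 because every object pixel lies in the
# hull.
object_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3) return(1)
  pts <- cbind(cols, rows)               # x = col, y = row
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(1)           # collinear
  hull <- pts[h, , drop = FALSE]
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  grid <- expand.grid(gc = c0:c1, gr = r0:r1)
  inside <- pracma::inpolygon(grid$gc, grid$gr, hull[, 1], hull[, 2],
                              boundary = TRUE)
  hull_pixels <- sum(inside)
  if (hull_pixels < n) hull_pixels <- n
  n / hull_pixels
}

# Robust background threshold: median + k * sigma. On zero-clipped images
# (negative DoG responses set to 0, so the median sits at 0 and the MAD
# degenerates) the noise scale is read off the upper quantile of the clipped
# distribution instead: for zero-median noise clipped at 0, the 84.13%
# quantile equals one sigma.
robust_threshold <- function(values, k) {
  med <- stats::median(values)
  sigma <- 1.4826 * stats::median(abs(values - med))
  if (sigma <= 0 || mean(values == 0) > 0.25) {
    med <- 0
    sigma <- stats::quantile(values, stats::pnorm(1), names = FALSE)
  }
  # essentially noiseless image: fall back to a small fraction of the
  # dynamic range so that the zero-clipped background stays below threshold
  if (sigma <= 0) return(0.05 * max(values))
  med + k * sigma
}

#' Segment condensates on an enhanced image
#'
#' Thresholds the enhanced image, seeds a watershed at the regional maxima
#' of the enhanced signal (maxima closer than `min_distance_px` are merged),
#' grows objects on the inverted enhanced landscape within the foreground,
#' and measures each object on the raw (pre-enhancement) plane. Objects
#' touching the image border are dropped; with `exclude_border` objects
#' touching the ROI boundary are dropped too. Detection is fully
#' deterministic.
#'
#' @param enhanced the enhanced `plane` (output of [enhance_plane()]).
#' @param raw the matching pre-enhancement `plane` (same shape and
#'   calibration); intensities are measured here.
#' @param roi logical matrix restricting detection, or NULL for the whole
#'   field.
#' @param params a [segmentation_params()] object.
#' @param roi_name label stored in the records.
#' @return list with `labels` (integer matrix; accepted and rejected
#'   candidate objects, ids matching the records) and `records` (data frame,
#'   one row per object: id, pixel_count, area_um2, centroid_y, centroid_x,
#'   mean_intensity, peak_enhanced, solidity, roi_name, accepted,
#'   reject_reason). `accepted` is NA until [classify_condensates()] runs.
#' @export
segment_condensates <- function(enhanced, raw, roi = NULL,
                                params = segmentation_params(),
                                roi_name = "field") {
  stopifnot(inherits(params, "segmentation_params"))
  e <- as_matrix(enhanced); m <- as_matrix(raw)
  if (!all(dim(e) == dim(m))) stop("enhanced and raw must share shape")
  ps <- pixel_size(enhanced)
  nr <- nrow(e); nc <- ncol(e)
  full_field <- is.null(roi)
  if (full_field) roi <- matrix(TRUE, nr, nc)
  if (!all(dim(roi) == dim(e))) stop("roi must match the image shape")
  if (!any(roi)) stop("roi is empty")

  thr <- switch(params$threshold_mode,
                absolute = params$threshold_value,
                k_sigma_above_background =
                  robust_threshold(e[roi], params$threshold_value))
  foreground <- e > thr & roi

  empty <- list(labels = matrix(0L, nr, nc),
                records = empty_records())
  if (!any(foreground)) return(empty)

  maxf <- cpp_max_filter_disk(e, params$min_distance_px)
  peaks <- foreground & (e >= maxf)
  seeds <- cpp_label_components(peaks)     # plateau maxima collapse to one seed
  if (max(seeds) == 0) return(empty)

  labels <- cpp_seeded_watershed(e, seeds, foreground)

  # Trim each watershed cell to its own half-peak (or peak_fraction) level,
  # keeping the connected component that contains the seed.
  if (params$peak_fraction > 0) {
    labels <- trim_to_peak_fraction(labels, e, seeds, params$peak_fraction)
  }

  ids <- sort(unique(labels[labels > 0]))
  recs <- lapply(ids, function(id) {
    idx <- which(labels == id)
    rows <- (idx - 1) %% nr          # 0-based
    cols <- (idx - 1) %/% nr
    touches_image <- any(rows == 0 | rows == nr - 1 | cols == 0 | cols == nc - 1)
    if (touches_image) return(NULL)
    if (params$exclude_border && !full_field) {
      # adjacent (4-neighbourhood) to a non-ROI pixel => touches ROI boundary
      on_edge <- any(!roi[cbind(pmax(rows, 1), cols + 1)]) ||
        any(!roi[cbind(pmin(rows + 2, nr), cols + 1)]) ||
        any(!roi[cbind(rows + 1, pmax(cols, 1))]) ||
        any(!roi[cbind(rows + 1, pmin(cols + 2, nc))])
      if (on_edge) return(NULL)
    }
    data.frame(id = id,
               pixel_count = length(idx),
               area_um2 = measure_area(length(idx), ps),
               centroid_y = mean(rows),
               centroid_x = mean(cols),
               mean_intensity = mean(m[idx]),
               peak_enhanced = max(e[idx]),
               solidity = object_solidity(rows, cols),
               roi_name = roi_name,
               accepted = NA,
               reject_reason = "",
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) return(empty)

  # relabel consecutively (1..n) in record order
  keep <- recs$id
  relab <- matrix(0L, nr, nc)
  for (i in seq_along(keep)) relab[labels == keep[i]] <- i
  recs$id <- seq_along(keep)
  rownames(recs) <- NULL
  list(labels = relab, records = recs)
}

empty_records <- function() {
  data.frame(id = integer(), pixel_count = integer(), area_um2 = numeric(),
             centroid_y = numeric(), centroid_x = numeric(),
             mean_intensity = numeric(), peak_enhanced = numeric(),
             solidity = numeric(), roi_name = character(),
             accepted = logical(), reject_reason = character(),
             stringsAsFactors = FALSE)
}

trim_to_peak_fraction <- function(labels, e, seeds, frac) {
  nr <- nrow(labels)
  out <- matrix(0L, nr, ncol(labels))
  for (id in seq_len(max(labels))) {
    idx <- which(labels == id)
    if (!length(idx)) next
    peak <- max(e[idx])
    keep <- idx[e[idx] >= frac * peak]
    if (!length(keep)) next
    # connected component containing the object's peak pixel
    sub <- matrix(FALSE, nr, ncol(labels))
    sub[keep] <- TRUE
    comp <- cpp_label_components(sub)
    peak_px <- keep[which.max(e[keep])]
    out[comp == comp[peak_px]] <- id
  }
  out
}

#' Apply the false-positive classifier to segmented objects
#'
#' Each candidate object is accepted iff its area lies in the admissible
#' range, its solidity meets `min_solidity`, and its contrast (object mean
#' over local annulus mean on the reference image) meets a requirement that
#' scales with local crowding: above `max_local_density` objects per
#' 100 um^2, the required contrast grows proportionally. Rejected records
#' are retained with a `reject_reason` (`"area"`, `"solidity"` or
#' `"contrast"`).
#'
#' @param records records data frame from [segment_condensates()].
#' @param labels matching label matrix.
#' @param reference `plane` used for contrast (normally the raw/EDF plane).
#' @param rules a [classifier_rules()] object.
#' @param params the [segmentation_params()] providing the area range.
#' @return the records with `accepted` and `reject_reason` filled in.
#' @export
classify_condensates <- function(records, labels, reference,
                                 rules = classifier_rules(),
                                 params = segmentation_params()) {
  stopifnot(inherits(rules, "classifier_rules"))
  if (nrow(records) == 0) return(records)
  m <- as_matrix(reference)
  ps <- pixel_size(reference)
  nr <- nrow(m); nc <- ncol(m)
  any_obj <- labels > 0

  # local crowding: plausible objects (those passing the area and solidity
  # rules) per 100 um^2 around each centroid, so that spurious noise
  # candidates do not inflate the crowding estimate
  plausible <- records$area_um2 >= params$min_area_um2 &
    records$area_um2 <= params$max_area_um2 &
    records$solidity >= rules$min_solidity
  r_px <- sqrt(100 / pi) / ps
  d2 <- outer(records$centroid_y, records$centroid_y[plausible], `-`)^2 +
    outer(records$centroid_x, records$centroid_x[plausible], `-`)^2
  local_density <- rowSums(d2 <= r_px^2)   # includes self when plausible

  contrast <- vapply(seq_len(nrow(records)), function(i) {
    idx <- which(labels == records$id[i])
    rows <- (idx - 1) %% nr; cols <- (idx - 1) %/% nr
    w <- rules$annulus_width_px
    r0 <- max(0, min(rows) - w); r1 <- min(nr - 1, max(rows) + w)
    c0 <- max(0, min(cols) - w); c1 <- min(nc - 1, max(cols) + w)
    box_r <- r0:r1; box_c <- c0:c1
    sub_obj <- matrix(FALSE, length(box_r), length(box_c))
    sub_obj[cbind(rows - r0 + 1, cols - c0 + 1)] <- TRUE
    dil <- sub_obj
    for (k in seq_len(w)) {
      dil <- dil |
        rbind(dil[-1, , drop = FALSE], FALSE) |
        rbind(FALSE, dil[-nrow(dil), , drop = FALSE]) |
        cbind(dil[, -1, drop = FALSE], FALSE) |
        cbind(FALSE, dil[, -ncol(dil), drop = FALSE])
    }
    ann <- dil & !any_obj[box_r + 1, box_c + 1]
    if (!any(ann)) return(Inf)
    mean(m[idx]) / max(mean(m[box_r + 1, box_c + 1][ann]), .Machine$double.eps)
  }, numeric(1))

  req_contrast <- rules$min_contrast *
    pmax(1, local_density / rules$max_local_density)

  reason <- character(nrow(records))
  reason[records$area_um2 < params$min_area_um2 |
           records$area_um2 > params$max_area_um2] <- "area"
  need <- reason == "" & records$solidity < rules$min_solidity
  reason[need] <- "solidity"
  need <- reason == "" & contrast < req_contrast
  reason[need] <- "contrast"

  records$accepted <- reason == ""
  records$reject_reason <- reason
  records$contrast <- contrast
  records$local_density <- local_density
  records
}

#' Match detected objects to ground truth by nearest centroid
#'
#' Greedy one-to-one matching: detected objects are paired with the closest
#' unmatched ground-truth object within `max_dist_um`, in increasing
#' distance order.
#'
#' @param records detected records (accepted rows are used if `accepted` is
#'   filled in, otherwise all).
#' @param truth_objects ground-truth object table from the simulator
#'   (columns `cy`, `cx`, `true_area_um2`).
#' @param pixel_size_um calibration used to convert the distance cap.
#' @param max_dist_um maximum centroid distance for a match (um).
#' @return list with `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, and `pairs` (data frame of matched indices and areas).
#' @export
match_to_truth <- function(records, truth_objects, pixel_size_um,
                           max_dist_um = 0.6) {
  if (!all(is.na(records$accepted))) records <- records[records$accepted, ]
  n_det <- nrow(records); n_tru <- nrow(truth_objects)
  if (n_det == 0 || n_tru == 0) {
    return(list(n_truth = n_tru, n_detected = n_det, n_matched = 0L,
                recall = ifelse(n_tru == 0, NA_real_, 0),
                precision = ifelse(n_det == 0, NA_real_, 0),
                pairs = data.frame()))
  }
  d <- sqrt(outer(records$centroid_y, truth_objects$cy, `-`)^2 +
              outer(records$centroid_x, truth_objects$cx, `-`)^2) * pixel_size_um
  cand <- which(d <= max_dist_um, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_det <- logical(n_det); used_tru <- logical(n_tru)
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    di <- cand[i, 1]; ti <- cand[i, 2]
    if (used_det[di] || used_tru[ti]) next
    used_det[di] <- TRUE; used_tru[ti] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(
      det = di, truth = ti,
      area_det_um2 = records$area_um2[di],
      area_true_um2 = truth_objects$true_area_um2[ti],
      dist_um = d[di, ti])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else data.frame()
  n_m <- sum(used_det)
  list(n_truth = n_tru, n_detected = n_det, n_matched = n_m,
       recall = n_m / n_tru, precision = n_m / n_det, pairs = pairs)
}
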