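#' Parameters for extended-depth-of-field projection
#'
#' Controls the local-variance focus measure and the reconstruction of the
#' all-in-focus plane. The defaults are the settings used for sparse
#' (cerebellum-like) fields; [edf_params_dense()] gives the dense-field
#' variant.
#'
#' @param window_radius_px half-width of the square local-variance window
#'   (>= 1); the window is (2r+1) x (2r+1).
#' @param smoothing half-width of the median filter applied to the selected
#'   slice-index map (kernel width 2 * smoothing + 1); 0 disables smoothing.
#' @param contrast_length blend depth: slices within +/- contrast_length of
#'   the selected slice contribute to the output pixel.
#' @param reconstruction_factor neighbour weight decay per slice step, in
#'   \[0, 1\]; 0 reduces to pure slice selection.
#' @param align_stack must be FALSE; slice registration is not performed.
#' @return an `edf_params` list.
#' @export
edf_params <- function(window_radius_px = 4L, smoothing = 5L,
                       contrast_length = 3L, reconstruction_factor = 0.05,
                       align_stack = FALSE) {
  if (window_radius_px < 1) stop("window_radius_px must be >= 1")
  if (smoothing < 0) stop("smoothing must be >= 0")
  if (contrast_length < 1) stop("contrast_length must be >= 1")
  if (reconstruction_factor < 0 || reconstruction_factor > 1) {
    stop("reconstruction_factor must lie in [0, 1]")
  }
  if (isTRUE(align_stack)) stop("stack alignment is not supported")
  structure(list(window_radius_px = as.integer(window_radius_px),
                 smoothing = as.integer(smoothing),
                 contrast_length = as.integer(contrast_length),
                 reconstruction_factor = reconstruction_factor,
                 align_stack = FALSE),
            class = "edf_params")
}

#' @rdname edf_params
#' @export
edf_params_dense <- function() {
  edf_params(smoothing = 2L, contrast_length = 3L, reconstruction_factor = 0.01)
}

#' Local intensity variance map
#'
#' Population variance of the intensities in the (2r+1) x (2r+1) window
#' centred on each pixel, with reflective boundary padding. This is the
#' focus measure of the variance-method EDF.
#'
#' @param plane a `plane` or numeric matrix.
#' @param window_radius_px window half-width (>= 1).
#' @return numeric matrix of per-pixel variances.
#' @export
local_variance <- function(plane, window_radius_px) {
  if (window_radius_px < 1) stop("window_radius_px must be >= 1")
  cpp_box_variance(as_matrix(plane), as.integer(window_radius_px))
}

#' Extended-depth-of-field projection by the variance method
#'
#' For each pixel the slice with maximal local intensity variance is
#' selected (ties go to the lowest slice index), the slice-index map is
#' median-smoothed, and the output pixel is a normalised blend of the
#' selected slice with its neighbours within `contrast_length` slices,
#' neighbour weights decaying geometrically by `reconstruction_factor` per
#' slice step.
#'
#' @param stack a `zstack` with at least one slice.
#' @param params an [edf_params()] object.
#' @return list with `plane` (the EDF projection, a `plane`) and `index_map`
#'   (integer matrix of 0-based selected slice indices).
#' @export
edf_variance <- function(stack, params = edf_params()) {
  stopifnot(inherits(params, "edf_params"))
  d <- dim(stack)
  if (is.null(d) || length(d) != 3 || d[3] < 1) stop("stack must have >= 1 slice")
  n_z <- d[3]
  data <- unclass(stack)

  if (n_z == 1) {
    return(list(plane = stack_slice(stack, 1),
                index_map = matrix(0L, d[1], d[2])))
  }

  best_var <- local_variance(data[, , 1], params$window_radius_px)
  index_map <- matrix(0L, d[1], d[2])
  for (z in 2:n_z) {
    v <- local_variance(data[, , z], params$window_radius_px)
    better <- v > best_var            # strict: ties keep the lower slice
    best_var[better] <- v[better]
    index_map[better] <- z - 1L
  }
  if (params$smoothing > 0) {
    index_map <- cpp_median_filter_int(index_map, params$smoothing)
  }

  out <- matrix(0, d[1], d[2])
  wsum <- matrix(0, d[1], d[2])
  L <- params$contrast_length
  rf <- params$reconstruction_factor
  for (dz in -L:L) {
    w <- if (dz == 0) 1 else rf^abs(dz)
    if (w == 0) next
    z <- index_map + dz
    valid <- z >= 0 & z <= n_z - 1
    if (!any(valid)) next
    idx <- which(valid)
    flat <- idx + as.numeric(z[idx]) * d[1] * d[2]
    out[idx] <- out[idx] + w * data[flat]
    wsum[idx] <- wsum[idx] + w
  }
  list(plane = new_plane(out / wsum, pixel_size(stack)), index_map = index_map)
}
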