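#' Calibrated image plane
#'
#' A `plane` is a numeric matrix of pixel intensities carrying its physical
#' calibration in micrometres per pixel. Rows index y, columns index x;
#' pixel coordinates are 0-based with centroids at pixel centres.
#'
#' @param data numeric matrix of intensities.
#' @param pixel_size_um physical pixel size in micrometres per pixel (> 0).
#' @return An object of class `plane`: the matrix with a `pixel_size_um`
#'   attribute.
#' @export
new_plane <- function(data, pixel_size_um) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(data, pixel_size_um = pixel_size_um, class = c("plane", "matrix"))
}

#' Calibrated Z-stack
#'
#' A `zstack` is a numeric 3-D array (y, x, z) of pixel intensities with a
#' micrometre-per-pixel calibration shared by all slices.
#'
#' @param data numeric array with three dimensions (rows, cols, slices).
#' @param pixel_size_um physical pixel size in micrometres per pixel (> 0).
#' @return An object of class `zstack`.
#' @export
new_zstack <- function(data, pixel_size_um) {
  stopifnot(is.array(data), length(dim(data)) == 3, is.numeric(data))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(data, pixel_size_um = pixel_size_um, class = c("zstack", "array"))
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<zstack> %d x %d px, %d slices, %.4g um/px\n",
              d[1], d[2], d[3], attr(x, "pixel_size_um")))
  invisible(x)
}

#' Pixel calibration of a plane or stack
#' @param x a `plane` or `zstack`.
#' @return pixel size in micrometres per pixel.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) stop("object carries no pixel_size_um calibration")
  ps
}

#' Extract one slice of a Z-stack as a plane
#' @param stack a `zstack`.
#' @param z slice index (1-based).
#' @return a `plane`.
#' @export
stack_slice <- function(stack, z) {
  d <- dim(stack)
  stopifnot(z >= 1, z <= d[3])
  new_plane(unclass(stack)[, , z, drop = TRUE], pixel_size(stack))
}

as_matrix <- function(x) {
  x <- unclass(x)
  attr(x, "pixel_size_um") <- NULL
  x
}

# 16-bit dynamic range used when serialising intensities to TIFF.
INT16_MAX <- 65535

#' Write a plane or Z-stack as a 16-bit grayscale TIFF
#'
#' Intensities are rounded and clipped to the 16-bit range; Z-stacks become
#' multi-page files. Clipping only happens here, at write time.
#'
#' @param x a `plane` or `zstack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  clip16 <- function(m) pmin(pmax(round(m), 0), INT16_MAX) / INT16_MAX
  if (inherits(x, "zstack")) {
    pages <- lapply(seq_len(dim(x)[3]), function(z) clip16(as_matrix(stack_slice(x, z))))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(clip16(as_matrix(x)), path, bits.per.sample = 16)
  }
  invisible(path)
}

#' Read a grayscale TIFF as a plane or Z-stack
#'
#' Single-page files come back as a `plane`, multi-page files as a `zstack`.
#' Integer TIFFs are read at their native integer scale (a 16-bit file
#' yields values in 0..65535).
#'
#' @param path TIFF file path.
#' @param pixel_size_um calibration to attach (micrometres per pixel).
#' @return a `plane` or `zstack`.
#' @export
read_image_tiff <- function(path, pixel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse any extra channels
    storage.mode(p) <- "double"
    p
  })
  if (length(pages) == 1) {
    new_plane(pages[[1]], pixel_size_um)
  } else {
    new_zstack(array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))),
               pixel_size_um)
  }
}

#' Write an integer label map as a 16-bit TIFF
#'
#' Labels must lie in 0..65535; they round-trip exactly through
#' [read_label_tiff()].
#'
#' @param labels integer matrix (0 = background).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > INT16_MAX) stop("label ids exceed the 16-bit TIFF range")
  tiff::writeTIFF(labels / INT16_MAX, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an integer label map written by [write_label_tiff()]
#' @param path TIFF file path.
#' @return integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Write a floating-point plane as a 32-bit float TIFF
#'
#' Values are stored divided by 65535 so they sit in the unit range the TIFF
#' writer expects; [read_float_tiff()] restores the original scale.
#'
#' @param x a `plane` with values in \[0, 65535\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(x, path) {
  tiff::writeTIFF(as_matrix(x) / INT16_MAX, path, bits.per.sample = 32)
  invisible(path)
}

#' Read a 32-bit float TIFF written by [write_float_tiff()]
#' @param path TIFF file path.
#' @param pixel_size_um calibration to attach.
#' @return a `plane`.
#' @export
read_float_tiff <- function(path, pixel_size_um) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  new_plane(m * INT16_MAX, pixel_size_um)
}
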