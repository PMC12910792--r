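#' Enhancement parameters
#'
#' Defaults follow the standard recipe for bright nuclear puncta on tissue:
#' rolling-ball background subtraction with a 10-pixel ball followed by a
#' difference-of-Gaussians band-pass with sigmas 2 and 10 pixels.
#'
#' @param rolling_ball_radius_px rolling-ball radius in pixels (>= 1).
#' @param dog_sigma_low_px,dog_sigma_high_px DoG sigmas in pixels,
#'   `low < high`.
#' @param clip_negative clip negative DoG output to 0 (default TRUE).
#' @return an `enhance_params` list.
#' @export
enhance_params <- function(rolling_ball_radius_px = 10,
                           dog_sigma_low_px = 2,
                           dog_sigma_high_px = 10,
                           clip_negative = TRUE) {
  if (rolling_ball_radius_px < 1) stop("rolling_ball_radius_px must be >= 1")
  if (!(dog_sigma_low_px > 0 && dog_sigma_low_px < dog_sigma_high_px)) {
    stop("require 0 < dog_sigma_low_px < dog_sigma_high_px")
  }
  structure(list(rolling_ball_radius_px = rolling_ball_radius_px,
                 dog_sigma_low_px = dog_sigma_low_px,
                 dog_sigma_high_px = dog_sigma_high_px,
                 clip_negative = isTRUE(clip_negative)),
            class = "enhance_params")
}

ball_structuring_element <- function(radius) {
  r <- ceiling(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- offs$dr^2 + offs$dc^2
  keep <- d2 <= radius^2
  list(dr = as.integer(offs$dr[keep]), dc = as.integer(offs$dc[keep]),
       height = sqrt(radius^2 - d2[keep]))
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image by a
#' spherical-cap structuring element of the given radius (the classical
#' rolling-ball construction, ball height scale equal to its pixel radius)
#' and subtracts it, clipping at zero. The output is pointwise less than or
#' equal to the input.
#'
#' @param plane a `plane` or numeric matrix.
#' @param radius_px ball radius in pixels (>= 1).
#' @return background-subtracted image of the same class as the input
#'   matrix data (a `plane` if the input was one).
#' @export
rolling_ball_subtract <- function(plane, radius_px = 10) {
  if (!is.numeric(radius_px) || radius_px < 1) {
    stop("radius_px must be >= 1")
  }
  m <- as_matrix(plane)
  se <- ball_structuring_element(radius_px)
  eroded <- cpp_gray_erode(m, se$dr, se$dc, se$height)
  background <- cpp_gray_dilate(eroded, se$dr, se$dc, se$height)
  out <- pmax(m - background, 0)
  if (inherits(plane, "plane")) new_plane(out, pixel_size(plane)) else out
}

#' Difference-of-Gaussians band-pass filter
#'
#' Subtracts a wide Gaussian blur from a narrow one, enhancing blob-like
#' structure between the two scales. Gaussian kernels are truncated at four
#' sigma and boundaries are reflective.
#'
#' @param plane a `plane` or numeric matrix.
#' @param sigma_low,sigma_high Gaussian sigmas in pixels, `0 < low < high`.
#' @param clip_negative clip negative responses to 0.
#' @return filtered image (a `plane` if the input was one).
#' @export
difference_of_gaussians <- function(plane, sigma_low = 2, sigma_high = 10,
                                    clip_negative = TRUE) {
  if (!(sigma_low > 0 && sigma_low < sigma_high)) {
    stop("require 0 < sigma_low < sigma_high")
  }
  m <- as_matrix(plane)
  out <- cpp_gaussian_blur(m, sigma_low) - cpp_gaussian_blur(m, sigma_high)
  if (clip_negative) out <- pmax(out, 0)
  if (inherits(plane, "plane")) new_plane(out, pixel_size(plane)) else out
}

#' Full signal enhancement: rolling ball then difference of Gaussians
#'
#' @param plane a `plane`.
#' @param params an [enhance_params()] object.
#' @return the enhanced `plane`.
#' @export
enhance_plane <- function(plane, params = enhance_params()) {
  stopifnot(inherits(params, "enhance_params"))
  sub <- rolling_ball_subtract(plane, params$rolling_ball_radius_px)
  difference_of_gaussians(sub, params$dog_sigma_low_px,
                          params$dog_sigma_high_px, params$clip_negative)
}
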