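# Particle amount analysis (PAA).
#
# Undissolved solute is segmented at pixel level in two passes: fine
# particles by Gaussian-weighted adaptive thresholding (dark pixels well
# below their local mean), clumps by a Gabor filter bank with a fixed binary
# threshold. The feature is the summed pixel count of both masks inside a
# rim-eroded ROI (the circle edge itself is a strong local-contrast
# structure and is excluded). Dark-on-light polarity is assumed: undissolved
# solute is darker than the lit background.

#' Adaptive-threshold parameters for fine-particle segmentation
#'
#' @param block_size odd Gaussian window side in pixels.
#' @param c_offset offset subtracted from the local mean; a pixel is marked
#'   when its intensity is strictly below `local_mean - c_offset`.
#' @export
adaptive_threshold_params <- function(block_size = 151, c_offset = 10) {
  stopifnot(block_size %% 2 == 1, block_size >= 3)
  list(block_size = block_size, c_offset = c_offset)
}

#' Gabor-bank parameters for clump segmentation
#'
#' @param orientations filter orientations in degrees.
#' @param wavelength,sigma,aspect_ratio Gabor carrier wavelength, envelope
#'   sigma (px) and aspect ratio. The wavelength sets the clump scale the
#'   bank responds to; isolated fine dots stay below threshold and are left
#'   to the adaptive-threshold stage, avoiding double counting.
#' @param binary_threshold fixed threshold on the \[0, 255\] rescaled
#'   maximum filter response. The rescale is absolute: 255 corresponds to
#'   the response of the kernel's positive lobe on a full-contrast feature,
#'   so a structureless ROI can never be rescaled up into detections.
#' @param closing_radius disc radius of the morphological closing that
#'   fills the interior between a clump's edge responses; defaults to half
#'   the wavelength.
#' @param dark_offset clump pixels must also be darker than the ROI mean
#'   minus this offset (undissolved solute is dark on the lit background).
#' @export
gabor_params <- function(orientations = c(0, 45, 90, 135), wavelength = 24,
                         sigma = 8, aspect_ratio = 0.5,
                         binary_threshold = 51, closing_radius = NULL,
                         dark_offset = 10) {
  stopifnot(length(orientations) >= 1)
  if (is.null(closing_radius)) closing_radius <- round(wavelength / 2)
  list(orientations = orientations, wavelength = wavelength, sigma = sigma,
       aspect_ratio = aspect_ratio, binary_threshold = binary_threshold,
       closing_radius = closing_radius, dark_offset = dark_offset)
}

# fill masked-out pixels with the in-ROI mean so the circle boundary does
# not create an artificial step for window-based filters
fill_outside <- function(image, roi_mask) {
  out <- image
  if (any(roi_mask)) out[!roi_mask] <- mean(image[roi_mask])
  out
}

#' Segment fine particles by adaptive thresholding
#'
#' A pixel is marked iff it lies inside the ROI and its intensity is
#' strictly below the Gaussian-weighted local mean (window `block_size`)
#' minus `c_offset`. Outside-ROI pixels are replaced by the ROI mean before
#' filtering so the rim step does not bias local means.
#'
#' @param image gray matrix.
#' @param roi_mask logical ROI mask.
#' @param p [adaptive_threshold_params()].
#' @return logical mask.
#' @export
segment_fine <- function(image, roi_mask, p = adaptive_threshold_params()) {
  filled <- fill_outside(image, roi_mask)
  lm <- local_gaussian_mean(filled, p$block_size)
  (image < lm - p$c_offset) & roi_mask
}

#' Segment particle clumps with a Gabor filter bank
#'
#' Maximum absolute response over the bank orientations, rescaled to
#' \[0, 255\] against the kernel's full-contrast positive-lobe response,
#' fixed binary threshold, then a disc closing (radius about half the
#' wavelength) that fills the interior between a clump's edge responses,
#' restricted to dark in-ROI pixels.
#'
#' @inheritParams segment_fine
#' @param p [gabor_params()].
#' @return logical mask.
#' @export
segment_clumps <- function(image, roi_mask, p = gabor_params()) {
  filled <- fill_outside(image, roi_mask)
  resp <- matrix(0, nrow(image), ncol(image))
  ref <- NULL
  for (th in p$orientations) {
    k <- gabor_kernel(p$wavelength, p$sigma, th, p$aspect_ratio)
    if (is.null(ref)) ref <- 255 * sum(pmax(k, 0))
    resp <- pmax(resp, abs(convolve2(filled, k)))
  }
  scaled <- pmin(resp * 255 / ref, 255)
  raw <- (scaled >= p$binary_threshold) & roi_mask
  size <- 2 * p$closing_radius + 1
  closed <- EBImage::closing(raw * 1, EBImage::makeBrush(size, "disc")) > 0
  dark <- image < mean(image[roi_mask]) - p$dark_offset
  closed & dark & roi_mask
}

#' Count undissolved-particle pixels
#'
#' The ROI mask is eroded by `rim_margin` pixels and the counts of both
#' masks inside the eroded region are summed (pixels detected by both
#' stages count twice, matching the additive feature definition).
#'
#' @param fine_mask,clump_mask logical masks from the two segmenters.
#' @param roi_mask logical ROI mask (same geometry).
#' @param rim_margin erosion radius in pixels.
#' @return integer pixel count.
#' @export
count_particles <- function(fine_mask, clump_mask, roi_mask, rim_margin = 5) {
  stopifnot(identical(dim(fine_mask), dim(clump_mask)),
            identical(dim(fine_mask), dim(roi_mask)))
  core <- erode_disk(roi_mask, rim_margin)
  sum(fine_mask & core) + sum(clump_mask & core)
}

#' Full particle-amount feature
#'
#' Runs both segmentation stages and returns the summed pixel count.
#'
#' @param masked a `masked_roi` (gray image).
#' @param at [adaptive_threshold_params()].
#' @param gp [gabor_params()].
#' @param rim_margin rim-erosion margin in pixels.
#' @return list with `count`, `fine_mask`, `clump_mask`.
#' @export
paa_features <- function(masked, at = adaptive_threshold_params(),
                         gp = gabor_params(), rim_margin = 5) {
  fine <- segment_fine(masked$image, masked$mask, at)
  clump <- segment_clumps(masked$image, masked$mask, gp)
  list(count = count_particles(fine, clump, masked$mask, rim_margin),
       fine_mask = fine, clump_mask = clump)
}
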