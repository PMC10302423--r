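# Moire-pattern suppression.
#
# Capturing a tablet display through a camera produces interference stripes
# (Moire) that masquerade as undissolved particles. The removal stage
# upscales the masked ROI, applies a two-step contrast stretch that
# saturates the bright liquid field (so low-amplitude stripes on it clip
# away) while darkening genuine particles, denoises with non-local means,
# and downscales back so downstream coordinates are unchanged.

#' Contrast-stretch parameters
#'
#' @param alpha stretch gain; the stretch maps `dst' -> (1 + alpha) * dst' -
#'   128 * alpha`, pivoting around mid-gray.
#' @param beta pre-scale applied before the stretch.
#' @export
contrast_params <- function(alpha = 1.0, beta = 1.2) {
  stopifnot(alpha >= 0, beta > 0)
  list(alpha = alpha, beta = beta)
}

#' Denoising parameters
#'
#' @param upscale_factor integer resampling factor (>= 1) applied before
#'   denoising so fine particles span more pixels than the stripe period.
#' @param nlm_strength non-local means filtering strength `h` (intensity).
#' @param patch_size odd patch side in pixels.
#' @param search_window odd search-window side in pixels (> patch_size).
#' @param noise_sigma assumed sensor-noise standard deviation at the point
#'   the filter runs (after contrast enhancement); patch distances are
#'   noise-compensated by subtracting `2 * noise_sigma^2`, the expected
#'   squared distance between two noisy copies of the same signal.
#' @export
denoise_params <- function(upscale_factor = 2, nlm_strength = 10,
                           patch_size = 7, search_window = 21,
                           noise_sigma = 5) {
  stopifnot(upscale_factor >= 1, patch_size %% 2 == 1,
            search_window > patch_size)
  list(upscale_factor = upscale_factor, nlm_strength = nlm_strength,
       patch_size = patch_size, search_window = search_window,
       noise_sigma = noise_sigma)
}

#' Two-step contrast enhancement
#'
#' Per pixel: `dst' = clip(beta * src, 0, 255)` then
#' `dst = clip((1 + alpha) * dst' - 128 * alpha, 0, 255)`, rounding to the
#' nearest integer at each clip. With the defaults (`alpha = 1`,
#' `beta = 1.2`) any source intensity of 160 or more saturates to white,
#' which is what strips Moire off the bright liquid field.
#'
#' Monotone non-decreasing in the source intensity.
#'
#' @param image gray matrix on \[0, 255\].
#' @param p [contrast_params()].
#' @return gray matrix.
#' @export
enhance_contrast <- function(image, p = contrast_params()) {
  dst1 <- clip8(p$beta * image)
  clip8((1 + p$alpha) * dst1 - 128 * p$alpha)
}

#' Suppress Moire stripes in a masked ROI
#'
#' Pipeline: bilinear upscale by `p$upscale_factor`, [enhance_contrast()],
#' non-local means denoising, block-mean downscale to the original geometry,
#' and re-application of the ROI mask (outside stays exactly 0). Output
#' dimensions and ROI are identical to the input.
#'
#' @param masked a `masked_roi` (gray image).
#' @param p [denoise_params()].
#' @param cp [contrast_params()].
#' @return a `masked_roi` with the filtered image.
#' @export
remove_moire <- function(masked, p = denoise_params(), cp = contrast_params()) {
  stopifnot(inherits(masked, "masked_roi"))
  img <- masked$image
  stopifnot(is.matrix(img))
  f <- p$upscale_factor
  up <- if (f > 1) resize_bilinear(img, nrow(img) * f, ncol(img) * f) else img
  up <- enhance_contrast(up, cp)
  den <- nlm_denoise_cpp(up, p$nlm_strength, p$patch_size, p$search_window,
                         if (is.null(p$noise_sigma)) 0 else p$noise_sigma)
  down <- if (f > 1) downscale_block_mean(den, f) else den
  out <- clip8(down)
  out[!masked$mask] <- 0
  structure(list(image = out, roi = masked$roi, mask = masked$mask),
            class = "masked_roi")
}
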