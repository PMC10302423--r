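# Low-level image primitives shared across the pipeline.
#
# All images are numeric matrices indexed [row, col] with intensities on the
# 8-bit scale [0, 255]; RGB images are H x W x 3 arrays on the same scale.
# Pixel coordinates are 1-based: `cx` is a column index, `cy` a row index.

#' Clip and round to the 8-bit intensity range
#'
#' @param x numeric vector, matrix or array.
#' @return `x` rounded to the nearest integer and clipped to \[0, 255\].
#' @keywords internal
clip8 <- function(x) {
  pmin(pmax(round(x), 0), 255)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded rendering does
#' not perturb unrelated randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Normalized 2-D Gaussian kernel
#'
#' @param size odd kernel side length in pixels.
#' @param sigma standard deviation in pixels; when `NULL` it is derived from
#'   the kernel size as `0.3 * ((size - 1) * 0.5 - 1) + 0.8`, the common
#'   convention tying the Gaussian width to an adaptive-threshold block size.
#' @return `size` x `size` matrix summing to 1.
#' @keywords internal
gaussian_kernel <- function(size, sigma = NULL) {
  stopifnot(size %% 2 == 1, size >= 3)
  if (is.null(sigma)) sigma <- 0.3 * ((size - 1) * 0.5 - 1) + 0.8
  ax <- seq_len(size) - (size + 1) / 2
  g1 <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Real Gabor kernel
#'
#' Standard even (cosine-phase) Gabor filter, mean-subtracted so that a
#' uniform field yields zero response.
#'
#' @param wavelength carrier wavelength in pixels.
#' @param sigma Gaussian envelope standard deviation in pixels.
#' @param theta orientation in degrees (0 = horizontal carrier axis).
#' @param gamma spatial aspect ratio of the envelope.
#' @keywords internal
gabor_kernel <- function(wavelength, sigma, theta, gamma = 0.5) {
  half <- ceiling(3 * sigma)
  ax <- -half:half
  th <- theta * pi / 180
  xg <- outer(rep(1, length(ax)), ax)     # column offsets
  yg <- outer(ax, rep(1, length(ax)))     # row offsets
  xp <- xg * cos(th) + yg * sin(th)
  yp <- -xg * sin(th) + yg * cos(th)
  k <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / wavelength)
  k - mean(k)
}

#' 2-D convolution with replicated borders
#'
#' Thin wrapper over [EBImage::filter2()] keeping the matrix orientation of
#' this package.
#' @keywords internal
convolve2 <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}

#' Bilinear interpolation at fractional pixel positions
#'
#' @param img numeric matrix.
#' @param x,y fractional column and row coordinates (1-based). Positions
#'   outside the image are clamped to the border.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]
  i11 <- img[cbind(y0 + 1, x0 + 1)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

#' Resize a matrix with bilinear interpolation
#' @keywords internal
resize_bilinear <- function(img, h, w) {
  EBImage::resize(img, w = h, h = w, filter = "bilinear")
}

#' Integer-factor block-mean downscale (area interpolation)
#' @keywords internal
downscale_block_mean <- function(img, factor) {
  stopifnot(nrow(img) %% factor == 0, ncol(img) %% factor == 0)
  h <- nrow(img) / factor
  w <- ncol(img) / factor
  rsum <- rowsum(img, rep(seq_len(h), each = factor))
  csum <- t(rowsum(t(rsum), rep(seq_len(w), each = factor)))
  csum / factor^2
}

#' Sobel gradients
#'
#' @param normalize divide kernels by 4 so a unit step yields magnitude ~1
#'   times the step height; `FALSE` gives the raw Sobel scale assumed by
#'   the conventional Canny 50/150 thresholds.
#' @return list with `gx`, `gy` (column-, row-direction derivatives) and
#'   magnitude `mag`.
#' @keywords internal
sobel_gradients <- function(img, normalize = TRUE) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  if (normalize) kx <- kx / 4
  ky <- t(kx)
  gx <- convolve2(img, kx)
  gy <- convolve2(img, ky)
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge detector
#'
#' Gaussian smoothing, Sobel gradients, 4-direction non-maximum suppression
#' and hysteresis thresholding (weak edges kept only in connected components
#' that contain a strong edge).
#'
#' @param img numeric matrix on \[0, 255\].
#' @param low,high hysteresis thresholds on the gradient magnitude.
#' @param sigma smoothing standard deviation in pixels.
#' @return logical matrix of edge pixels.
#' @keywords internal
canny_edges <- function(img, low = 50, high = 150, sigma = 1.4) {
  sm <- convolve2(img, gaussian_kernel(2 * ceiling(2 * sigma) + 1, sigma))
  g <- sobel_gradients(sm, normalize = FALSE)
  mag <- g$mag
  h <- nrow(mag); w <- ncol(mag)
  ang <- atan2(g$gy, g$gx)                      # [-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)        # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  shift <- function(m, dr, dc) {
    out <- matrix(0, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  nms <- matrix(FALSE, h, w)
  for (s in 0:3) {
    d <- offs[[s + 1]]
    sel <- sector == s
    ok <- mag >= shift(mag, d[1], d[2]) & mag >= shift(mag, -d[1], -d[2])
    nms <- nms | (sel & ok)
  }
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  weak & (matrix(lab %in% keep, h, w))
}

#' Binary morphology helpers (3x3 box, one iteration each)
#' @keywords internal
dilate3 <- function(mask) {
  EBImage::dilate(mask * 1, EBImage::makeBrush(3, shape = "box")) > 0
}

#' @rdname dilate3
#' @keywords internal
close3 <- function(mask) {
  EBImage::closing(mask * 1, EBImage::makeBrush(3, shape = "box")) > 0
}

#' Erode a binary mask by a disk of given radius
#' @keywords internal
erode_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  size <- 2 * radius + 1
  EBImage::erode(mask * 1, EBImage::makeBrush(size, shape = "disc")) > 0
}

#' Sliding box sum via integral image
#'
#' Sum of `m` over a `(2*radius+1)` square window centered at each pixel,
#' windows clipped at the borders.
#' @keywords internal
box_sum <- function(m, radius) {
  h <- nrow(m); w <- ncol(m)
  ii <- matrix(0, h + 1, w + 1)
  ii[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(h) - radius - 1, 0) + 1
  r2 <- pmin(seq_len(h) + radius, h) + 1
  c1 <- pmax(seq_len(w) - radius - 1, 0) + 1
  c2 <- pmin(seq_len(w) + radius, w) + 1
  ii[r2, c2] - ii[r1, c2] - ii[r2, c1] + ii[r1, c1]
}

#' Gaussian-weighted local mean (adaptive-threshold support)
#'
#' The weight kernel has side `block_size` and the sigma convention derived
#' from it (see [gaussian_kernel()]).
#' @keywords internal
local_gaussian_mean <- function(img, block_size) {
  convolve2(img, gaussian_kernel(block_size))
}
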