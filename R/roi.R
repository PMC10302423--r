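# ROI preprocessing: find the circular solution region and mask the rest.
#
# The solution seen through the flask bottom is circular, so a circle Hough
# transform (gradient voting) locates it. Detection starts from a
# conservative accumulator threshold and relaxes it geometrically until at
# least one candidate appears; among candidates the one closest to the image
# center wins, which rejects reflections and background structure near the
# frame edges.

#' Convert an RGB image to 8-bit gray
#'
#' BT.601 luma (0.299 R + 0.587 G + 0.114 B), rounded to the nearest integer
#' and clipped to \[0, 255\]. Gray matrices pass through unchanged.
#'
#' @param image H x W x 3 array or H x W matrix on the 8-bit scale.
#' @return H x W numeric matrix.
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) return(clip8(image))
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  clip8(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Circular region of interest
#'
#' @param cx,cy center in pixel coordinates (column, row; 1-based).
#' @param r radius in pixels.
#' @export
circular_roi <- function(cx, cy, r) {
  structure(list(cx = cx, cy = cy, r = r), class = "circular_roi")
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("<circular_roi> center (%.1f, %.1f), radius %.1f px\n",
              x$cx, x$cy, x$r))
  invisible(x)
}

#' Default circle-detector parameters
#'
#' @param radius_frac search band for the radius as fractions of
#'   `min(H, W)`; the flask fills a large central fraction of the frame.
#' @param radius_step radius quantization of the vote loop, px.
#' @param edge_threshold Sobel gradient-magnitude threshold selecting voting
#'   edge pixels.
#' @param start_threshold initial accumulator threshold (votes, on the
#'   box-smoothed accumulator).
#' @param decay,max_steps geometric threshold schedule: the threshold is
#'   multiplied by `decay` up to `max_steps` times until a candidate appears.
#' @param median_radius radius of the median pre-blur (2 = 5x5 kernel);
#'   stabilizes the accumulator. Feature extraction always uses the
#'   unblurred image.
#' @export
circle_detector_params <- function(radius_frac = c(0.15, 0.49),
                                   radius_step = 2,
                                   edge_threshold = 60,
                                   start_threshold = 6000,
                                   decay = 0.8,
                                   max_steps = 10,
                                   median_radius = 2) {
  list(radius_frac = radius_frac, radius_step = radius_step,
       edge_threshold = edge_threshold, start_threshold = start_threshold,
       decay = decay, max_steps = max_steps, median_radius = median_radius)
}

#' Detect the circular solution region
#'
#' Gradient-voting circle Hough transform on a median-blurred copy of the
#' image: each strong edge pixel votes along its gradient direction (both
#' senses) for every candidate radius; center candidates are accumulator
#' peaks above a threshold that decays geometrically until at least one
#' candidate appears. Candidates are tried in order of closeness to the
#' image center; each is refined by an iterated algebraic circle fit over
#' the radially aligned edge pixels in its modal distance band, and the
#' first candidate whose refined circle has sufficient angular edge support
#' is returned.
#'
#' @param image gray matrix.
#' @param params [circle_detector_params()].
#' @return [circular_roi()].
#' @section Errors: signals a condition of class `solscreen_no_circle` when
#'   no candidate exists even at the weakest threshold (unusable frame).
#' @export
detect_solution_circle <- function(image, params = circle_detector_params()) {
  h <- nrow(image); w <- ncol(image)
  blurred <- EBImage::medianFilter(image / 255, params$median_radius) * 255
  g <- sobel_gradients(blurred)
  edge <- which(g$mag > params$edge_threshold)
  if (length(edge) == 0) {
    stop(no_circle_error("no edge pixels above threshold"))
  }
  if (length(edge) > 20000) {
    # deterministic thinning keeps the vote matrix bounded
    edge <- edge[seq(1, length(edge), length.out = 20000)]
  }
  ey <- (edge - 1) %% h + 1
  ex <- (edge - 1) %/% h + 1
  gx <- g$gx[edge]; gy <- g$gy[edge]
  mag <- g$mag[edge]
  ux <- gx / mag; uy <- gy / mag
  rmin <- params$radius_frac[1] * min(h, w)
  rmax <- params$radius_frac[2] * min(h, w)
  radii <- seq(rmin, rmax, by = params$radius_step)

  acc <- hough_circle_votes_cpp(as.integer(ex), as.integer(ey), ux, uy,
                                radii, h, w)
  # gradient-direction noise spreads center votes over a few pixels; a 9x9
  # box sum concentrates them before peak detection
  accm <- box_sum(acc, 4)

  thr <- params$start_threshold
  centers <- NULL
  for (step in seq_len(params$max_steps)) {
    peaks <- which(accm >= thr)
    if (length(peaks) > 0) {
      py <- (peaks - 1) %% h + 1
      px <- (peaks - 1) %/% h + 1
      votes <- accm[peaks]
      # greedy peak NMS within 10 px
      ord <- order(votes, decreasing = TRUE)
      keep <- integer(0)
      for (i in ord) {
        if (length(keep) == 0 ||
            all((px[i] - px[keep])^2 + (py[i] - py[keep])^2 > 100)) {
          keep <- c(keep, i)
        }
      }
      centers <- data.frame(cx = px[keep], cy = py[keep], votes = votes[keep])
      break
    }
    thr <- thr * params$decay
  }
  if (is.null(centers)) {
    stop(no_circle_error("no accumulator peak at the weakest threshold"))
  }

  # refine each candidate: modal distance band of supporting edge pixels,
  # then an algebraic least-squares circle fit (Kasa) on the radially
  # aligned pixels in that band (the rim's gradient points at the center;
  # grid lines or other background structure in the same band does not),
  # iterated so a few-pixel bias in the coarse peak converges out
  br <- seq(rmin, rmax + params$radius_step, by = params$radius_step)
  refine <- function(cx0, cy0) {
    cx <- cx0; cy <- cy0
    r_est <- NA_real_
    for (it in 1:3) {
      d <- sqrt((ex - cx)^2 + (ey - cy)^2)
      in_band <- d >= rmin & d <= rmax
      if (!any(in_band)) return(NULL)
      hist_counts <- tabulate(findInterval(d[in_band], br), nbins = length(br))
      bin <- which.max(hist_counts)
      lo <- br[max(1, bin - 2)]
      hi <- br[min(length(br), bin + 2)] + params$radius_step
      radial_dot <- ((ex - cx) * ux + (ey - cy) * uy) / pmax(d, 1e-9)
      sel <- in_band & d >= lo & d < hi & abs(radial_dot) > 0.9
      if (sum(sel) < 30) sel <- in_band & d >= lo & d < hi
      px_s <- ex[sel]; py_s <- ey[sel]
      # Kasa fit: x^2 + y^2 = 2 a x + 2 b y + c
      A <- cbind(2 * px_s, 2 * py_s, 1)
      bvec <- px_s^2 + py_s^2
      sol <- tryCatch(solve(crossprod(A), crossprod(A, bvec)),
                      error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      r_new <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
      if (r_new < rmin || r_new > rmax ||
          (sol[1] - cx0)^2 + (sol[2] - cy0)^2 > 20^2) {
        if (is.na(r_est)) r_est <- mean(d[sel])
        break
      }
      cx <- sol[1]; cy <- sol[2]; r_est <- r_new
    }
    # angular coverage of aligned inliers validates that this is a circle,
    # not a coincidental vote pile-up
    d <- sqrt((ex - cx)^2 + (ey - cy)^2)
    radial_dot <- ((ex - cx) * ux + (ey - cy) * uy) / pmax(d, 1e-9)
    inl <- abs(d - r_est) <= 2.5 & abs(radial_dot) > 0.9
    cov <- if (any(inl)) {
      length(unique(floor(atan2(ey[inl] - cy, ex[inl] - cx) * 180 / pi))) / 360
    } else 0
    list(cx = cx, cy = cy, r = r_est, coverage = cov)
  }

  # closest-to-center first; a candidate whose refined circle lacks angular
  # support is a vote pile-up, not a circle, and the next candidate is tried
  d2c <- (centers$cx - (w + 1) / 2)^2 + (centers$cy - (h + 1) / 2)^2
  ord <- order(d2c)[seq_len(min(8, nrow(centers)))]
  best <- NULL
  fallback <- NULL
  for (i in ord) {
    cand <- refine(centers$cx[i], centers$cy[i])
    if (is.null(cand)) next
    if (cand$coverage >= 0.5) { best <- cand; break }
    if (is.null(fallback) || cand$coverage > fallback$coverage) fallback <- cand
  }
  if (is.null(best)) best <- fallback
  if (is.null(best)) stop(no_circle_error("no refinable candidate"))

  circular_roi(best$cx, best$cy, best$r)
}

no_circle_error <- function(msg) {
  structure(class = c("solscreen_no_circle", "error", "condition"),
            list(message = paste0("NoCircleFound: ", msg), call = sys.call(-1)))
}

#' Mask everything outside a circular ROI
#'
#' Pixels at distance <= r from the center (closed disk) are kept; all other
#' pixels are set exactly to 0. Idempotent.
#'
#' @param image gray matrix or RGB array.
#' @param roi [circular_roi()]; must either fit inside the image (2 px
#'   clipping tolerance) or fully contain it (in which case nothing is
#'   masked); a disk that partially overhangs the frame is an error.
#' @return object of class `masked_roi`: list with `image` (same type as
#'   input), `roi`, and logical `mask`.
#' @export
apply_mask <- function(image, roi) {
  dims <- dim(image)
  h <- dims[1]; w <- dims[2]
  tol <- 2
  corners <- sqrt(c(1 - roi$cx, w - roi$cx)^2 +
                    rep(c(1 - roi$cy, h - roi$cy), each = 2)^2)
  contains_image <- all(corners <= roi$r)
  fits_inside <- roi$cx - roi$r >= 1 - tol && roi$cx + roi$r <= w + tol &&
    roi$cy - roi$r >= 1 - tol && roi$cy + roi$r <= h + tol
  if (!contains_image && !fits_inside) {
    stop("apply_mask: ROI exceeds image bounds")
  }
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  mask <- (xg - roi$cx)^2 + (yg - roi$cy)^2 <= roi$r^2
  if (length(dims) == 3) {
    out <- image
    for (ch in seq_len(dims[3])) {
      plane <- out[, , ch]
      plane[!mask] <- 0
      out[, , ch] <- plane
    }
  } else {
    out <- image
    out[!mask] <- 0
  }
  structure(list(image = out, roi = roi, mask = mask), class = "masked_roi")
}

#' @export
print.masked_roi <- function(x, ...) {
  cat(sprintf("<masked_roi> %d x %d image, ", nrow(x$mask), ncol(x$mask)))
  print(x$roi)
  invisible(x)
}
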