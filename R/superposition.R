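# Superposition analysis (SA).
#
# On the checked-background capture, the grid seen through the solution is
# detected (adaptive threshold, Canny edges, Hough line segments, light
# morphology), line coordinates are picked from projection-profile peaks
# with non-maximum suppression, the expected central nine-part grid is
# predicted from the four coordinates per axis closest to the ROI center,
# and the fraction of that predicted grid actually covered by the detection
# is the superposition ratio: a transparent solution leaves the pattern
# visible (ratio near 1), an opaque one hides it (ratio near 0).

#' Check-pattern detector parameters
#'
#' @param at_block,at_c adaptive-threshold window and offset for binarizing
#'   the grid lines.
#' @param canny_low,canny_high Canny hysteresis thresholds.
#' @param hough_threshold minimum accumulator votes for a line.
#' @param min_length,max_gap minimum segment length and maximum bridged gap
#'   along a line, pixels.
#' @param max_lines cap on extracted peak lines.
#' @export
check_detector_params <- function(at_block = 31, at_c = 10,
                                  canny_low = 50, canny_high = 150,
                                  hough_threshold = 50, min_length = 20,
                                  max_gap = 5, max_lines = 40) {
  list(at_block = at_block, at_c = at_c, canny_low = canny_low,
       canny_high = canny_high, hough_threshold = hough_threshold,
       min_length = min_length, max_gap = max_gap, max_lines = max_lines)
}

# standard rho-theta Hough accumulator line detection followed by segment
# extraction along each peak line (split at gaps, enforce minimum length)
hough_line_segments <- function(edge_mask, p) {
  pts <- which(edge_mask)
  h <- nrow(edge_mask); w <- ncol(edge_mask)
  if (length(pts) == 0) return(matrix(FALSE, h, w))
  py <- (pts - 1) %% h + 1
  px <- (pts - 1) %/% h + 1
  thetas <- seq(0, 179) * pi / 180
  rho_max <- ceiling(sqrt(h^2 + w^2))
  n_rho <- 2 * rho_max + 1
  acc <- matrix(0L, n_rho, length(thetas))
  for (ti in seq_along(thetas)) {
    rho <- round(px * cos(thetas[ti]) + py * sin(thetas[ti]))
    acc[, ti] <- tabulate(rho + rho_max + 1, nbins = n_rho)
  }
  seg_mask <- matrix(FALSE, h, w)
  used <- rep(FALSE, length(pts))
  for (iter in seq_len(p$max_lines)) {
    peak <- which.max(acc)
    if (acc[peak] < p$hough_threshold) break
    ri <- (peak - 1) %% n_rho + 1
    ti <- (peak - 1) %/% n_rho + 1
    rho <- ri - rho_max - 1
    th <- thetas[ti]
    # suppress the peak neighborhood in the accumulator; the radius kept
    # narrow so the twin edge of a stroke a few pixels away survives
    rs <- max(1, ri - 2):min(n_rho, ri + 2)
    ts <- ((ti - 3):(ti + 3) - 1) %% length(thetas) + 1
    acc[rs, ts] <- 0L
    # points within 1.5 px of the line
    d <- abs(px * cos(th) + py * sin(th) - rho)
    on_line <- which(d <= 1.5 & !used)
    if (length(on_line) < p$min_length) next
    # project on the line direction, sort, split at gaps
    tproj <- -px[on_line] * sin(th) + py[on_line] * cos(th)
    ord <- order(tproj)
    tp <- tproj[ord]
    brk <- c(0, which(diff(tp) > p$max_gap), length(tp))
    for (b in seq_len(length(brk) - 1)) {
      idx <- (brk[b] + 1):brk[b + 1]
      if (tp[idx[length(idx)]] - tp[idx[1]] + 1 >= p$min_length) {
        sel <- on_line[ord[idx]]
        seg_mask[cbind(py[sel], px[sel])] <- TRUE
        used[sel] <- TRUE
      }
    }
  }
  seg_mask
}

#' Detect the check pattern visible through the solution
#'
#' Adaptive threshold (dark grid lines), Canny edge detection, Hough line
#' segment extraction, rasterization, 3x3 dilation and closing, intersected
#' with the ROI. An empty mask is a valid output for an opaque solution.
#'
#' @param image gray matrix (checked-background capture, masked).
#' @param roi_mask logical ROI mask.
#' @param p [check_detector_params()].
#' @return logical mask of detected pattern pixels (zero outside the ROI).
#' @export
detect_check_pattern <- function(image, roi_mask, p = check_detector_params()) {
  filled <- fill_outside(image, roi_mask)
  lm <- local_gaussian_mean(filled, p$at_block)
  binarized <- (image < lm - p$at_c) & roi_mask
  edges <- canny_edges(binarized * 255, p$canny_low, p$canny_high) & roi_mask
  segs <- hough_line_segments(edges, p)
  close3(dilate3(segs)) & roi_mask
}

#' Select grid-line coordinates from projection profiles
#'
#' Row sums give candidate y-coordinates, column sums candidate
#' x-coordinates. Per axis the global maximum is taken, its +/- `nms_radius`
#' neighborhood zeroed, and the process repeated up to six times (stopping
#' early when the remaining maximum is zero). Peaks are selected by
#' descending projection magnitude; returned coordinates are sorted
#' ascending.
#'
#' @param pattern logical check-pattern mask.
#' @param nms_radius suppression radius in pixels.
#' @param min_peaks minimum peaks required per axis.
#' @return object of class `line_set` with `xs`, `ys`.
#' @section Errors: condition `solscreen_insufficient_pattern` when either
#'   axis yields fewer than `min_peaks` peaks; the ratio stage maps this to
#'   a superposition ratio of 0.
#' @export
select_line_coordinates <- function(pattern, nms_radius = 25, min_peaks = 4) {
  pick <- function(profile) {
    coords <- integer(0)
    prof <- profile
    for (i in 1:6) {
      m <- which.max(prof)
      if (prof[m] <= 0) break
      # sub-peak centroid: dilation plateaus the profile, so the argmax can
      # sit off the stroke center by a few pixels
      win <- max(1, m - 10):min(length(prof), m + 10)
      coords <- c(coords, round(sum(win * prof[win]) / sum(prof[win])))
      lo <- max(1, m - nms_radius); hi <- min(length(prof), m + nms_radius)
      prof[lo:hi] <- 0
    }
    sort(coords)
  }
  ys <- pick(rowSums(pattern))
  xs <- pick(colSums(pattern))
  if (length(xs) < min_peaks || length(ys) < min_peaks) {
    stop(insufficient_pattern_error(length(xs), length(ys)))
  }
  structure(list(xs = xs, ys = ys), class = "line_set")
}

insufficient_pattern_error <- function(nx, ny) {
  structure(class = c("solscreen_insufficient_pattern", "error", "condition"),
            list(message = sprintf(
              "InsufficientPattern: %d x-peaks, %d y-peaks (need 4 per axis)",
              nx, ny), call = sys.call(-1)))
}

#' Predict the central nine-part grid
#'
#' Per axis, the four coordinates closest to the ROI center are kept and
#' drawn as full lines of width `line_width` across the ROI; the result
#' (clipped to the ROI mask) partitions the central region into nine parts.
#'
#' @param lines a `line_set` with at least 4 coordinates per axis.
#' @param roi [circular_roi()].
#' @param roi_mask logical ROI mask.
#' @param line_width drawn line width in pixels.
#' @return logical mask of the predicted grid.
#' @export
predict_grid <- function(lines, roi, roi_mask, line_width = 4) {
  stopifnot(length(lines$xs) >= 4, length(lines$ys) >= 4)
  closest4 <- function(v, center) sort(v[order(abs(v - center))][1:4])
  xs <- closest4(lines$xs, roi$cx)
  ys <- closest4(lines$ys, roi$cy)
  h <- nrow(roi_mask); w <- ncol(roi_mask)
  grid <- matrix(FALSE, h, w)
  half_lo <- floor((line_width - 1) / 2)
  half_hi <- floor(line_width / 2)
  for (x in xs) grid[, max(1, x - half_lo):min(w, x + half_hi)] <- TRUE
  for (y in ys) grid[max(1, y - half_lo):min(h, y + half_hi), ] <- TRUE
  grid & roi_mask
}

#' Superposition ratio
#'
#' Fraction of the predicted grid covered by the detected pattern:
#' `|predicted & detected| / |predicted|`; 0 when the predicted grid is
#' empty.
#'
#' @param predicted,detected logical masks of the same geometry.
#' @return numeric in \[0, 1\].
#' @export
superposition_ratio <- function(predicted, detected) {
  np <- sum(predicted)
  if (np == 0) return(0)
  sum(predicted & detected) / np
}

#' Full superposition feature
#'
#' Runs detection, line selection, grid prediction and the ratio; an
#' insufficient pattern yields a ratio of 0 by contract. The predicted grid
#' is drawn at a fixed line width (thinner than the dilated detection) so
#' the ratio depends only on how much of the expected pattern was actually
#' detected, not on the detection's stroke thickness.
#'
#' @param masked a `masked_roi` of the checked-background capture.
#' @param p [check_detector_params()].
#' @param nms_radius projection-peak suppression radius, pixels.
#' @param line_width predicted-grid line width, pixels.
#' @return list with `ratio`, `detected`, and (when available) `predicted`
#'   and `lines`.
#' @export
sa_features <- function(masked, p = check_detector_params(), nms_radius = 25,
                        line_width = 4) {
  detected <- detect_check_pattern(masked$image, masked$mask, p)
  lines <- tryCatch(select_line_coordinates(detected, nms_radius),
                    solscreen_insufficient_pattern = function(e) NULL)
  if (is.null(lines)) {
    return(list(ratio = 0, detected = detected, predicted = NULL, lines = NULL))
  }
  predicted <- predict_grid(lines, masked$roi, masked$mask, line_width)
  list(ratio = superposition_ratio(predicted, detected),
       detected = detected, predicted = predicted, lines = lines)
}
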