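# Grid homogeneity analysis (GHA).
#
# The square circumscribing the ROI circle is tiled with axis-aligned cells
# of side n; a cell is retained only if all four of its corners fall
# strictly inside the circle. Per-cell intensity mean and population
# standard deviation are summarized into four features:
#   MMG  mean of cell means          (overall brightness)
#   MSG  mean of cell stds           (within-cell texture, e.g. particles)
#   SMG  std  of cell means          (large-scale inhomogeneity)
#   SSG  std  of cell stds           (texture inhomogeneity)
# Population (divide-by-count) standard deviations are used throughout.

#' Build the retained-cell grid for a circular ROI
#'
#' The circumscribing square spans `2r` pixels per side starting at the
#' top-left corner `(cy - r, cx - r)`; it is tiled in steps of `n` from that
#' origin, partial cells at the right/bottom edge are discarded, and a cell
#' is kept iff the pixel centers of all four of its corner pixels are at
#' distance strictly less than `r` from the circle center.
#'
#' @param roi [circular_roi()].
#' @param n cell side in pixels (paper-scale captures use 80; scale with
#'   the flask diameter).
#' @return object of class `grid_spec`: `n`, `m` (number of retained
#'   cells), and `cells`, a data frame of 1-based top-left `row`/`col`
#'   pixel indices.
#' @section Errors: `EmptyGrid` error when no cell is retained (ROI too
#'   small for `n`).
#' @export
build_grid <- function(roi, n) {
  r <- roi$r
  if (2 * r < n) stop("EmptyGrid: circle diameter smaller than cell size")
  x0 <- round(roi$cx - r)   # leftmost column of the square
  y0 <- round(roi$cy - r)
  k <- floor(2 * r / n)     # full cells per axis
  cells <- expand.grid(i = seq_len(k) - 1, j = seq_len(k) - 1)
  keep <- logical(nrow(cells))
  for (q in seq_len(nrow(cells))) {
    cs <- x0 + cells$j[q] * n          # first column of cell
    rs <- y0 + cells$i[q] * n          # first row of cell
    corner_x <- c(cs, cs + n - 1, cs, cs + n - 1)
    corner_y <- c(rs, rs, rs + n - 1, rs + n - 1)
    d <- sqrt((corner_x - roi$cx)^2 + (corner_y - roi$cy)^2)
    keep[q] <- all(d < r)
  }
  if (!any(keep)) stop("EmptyGrid: no grid cell lies fully inside the circle")
  kept <- cells[keep, , drop = FALSE]
  structure(list(n = n, m = nrow(kept),
                 cells = data.frame(row = y0 + kept$i * n,
                                    col = x0 + kept$j * n)),
            class = "grid_spec")
}

#' Compute the four grid-homogeneity features
#'
#' @param image gray matrix.
#' @param grid [build_grid()] result.
#' @return named numeric vector `c(MMG, MSG, SMG, SSG)`.
#' @export
compute_gha <- function(image, grid) {
  stopifnot(inherits(grid, "grid_spec"), grid$m >= 1)
  n <- grid$n
  mus <- numeric(grid$m)
  sds <- numeric(grid$m)
  for (q in seq_len(grid$m)) {
    rs <- grid$cells$row[q]; cs <- grid$cells$col[q]
    cell <- image[rs:(rs + n - 1), cs:(cs + n - 1)]
    mus[q] <- mean(cell)
    sds[q] <- sqrt(mean((cell - mus[q])^2))
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  c(MMG = mean(mus), MSG = mean(sds), SMG = pop_sd(mus), SSG = pop_sd(sds))
}
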