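# Radial profile analysis (RPA).
#
# Twelve diameter intensity profiles are sampled through the ROI center at
# 30 degree steps; their pointwise mean is fitted by an even quadratic
# y = a x^2 + c on the normalized abscissa x in [-1, 1]. A clear solution
# gives a flat parabola with small fit error; a cloudy solution darkens the
# center (large curvature a, small minimum c); particles scatter samples
# away from the parabola (large MSE).

#' Extract 12 diameter intensity profiles
#'
#' Sampling a rotated image's horizontal diameter is equivalent to sampling
#' the original image along the diameter at the opposite angle, so profiles
#' are taken directly along rays at `k * 30` degrees (k = 0..11) through the
#' ROI center with bilinear interpolation, `L = 2r` equally spaced samples
#' per diameter. Profiles at `theta` and `theta + 180` are reversed
#' duplicates and are retained as distinct sequences.
#'
#' @param masked a `masked_roi` (gray image).
#' @param rim_trim samples within `rim_trim` pixels of the circle rim are
#'   flagged and excluded from the fit (bilinear samples there mix in
#'   masked-out or flask-wall pixels).
#' @return object of class `profile_set`: `profiles` (L x 12 matrix, one
#'   column per rotation), `x` (normalized abscissa in (-1, 1)), `keep`
#'   (logical fit-inclusion flags), `r`.
#' @section Errors: radius below 16 px (profile too short to fit).
#' @export
extract_profiles <- function(masked, rim_trim = 3) {
  stopifnot(inherits(masked, "masked_roi"))
  roi <- masked$roi
  if (roi$r < 16) stop("extract_profiles: ROI radius below 16 px")
  r <- roi$r
  L <- round(2 * r)
  tpos <- seq(-r + 0.5, r - 0.5, length.out = L)
  profiles <- matrix(0, L, 12)
  for (k in 0:11) {
    th <- k * 30 * pi / 180
    xs <- roi$cx + tpos * cos(th)
    ys <- roi$cy + tpos * sin(th)
    profiles[, k + 1] <- bilinear_sample(masked$image, xs, ys)
  }
  structure(list(profiles = profiles, x = tpos / r,
                 keep = abs(tpos) <= r - rim_trim, r = r),
            class = "profile_set")
}

#' Least-squares even-quadratic fit
#'
#' Fits `y = a x^2 + c` (no linear term) on `x` in \[-1, 1\] by closed-form
#' normal equations; `mse` is the mean squared residual.
#'
#' @param y mean profile values.
#' @param x normalized abscissa (same length as `y`, >= 3 samples).
#' @return list with `a` (curvature), `c` (minimum value), `mse`.
#' @export
fit_quadratic <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  x2 <- x^2
  n <- length(y)
  s2 <- sum(x2); s4 <- sum(x2^2)
  sy <- sum(y); sxy <- sum(x2 * y)
  denom <- n * s4 - s2^2
  a <- (n * sxy - s2 * sy) / denom
  c0 <- (sy - a * s2) / n
  fit <- a * x2 + c0
  list(a = a, c = c0, mse = mean((fit - y)^2))
}

#' Radial-profile features: curvature, minimum value, MSE
#'
#' Fits the pointwise mean of the 12 profiles.
#'
#' @param set a `profile_set`.
#' @return named numeric vector `c(minimum_value, curvature, mse)` (the
#'   fitted `c`, `a`, and mean squared error).
#' @export
rpa_features <- function(set) {
  stopifnot(inherits(set, "profile_set"))
  meanp <- rowMeans(set$profiles)
  keep <- if (!is.null(set$keep)) set$keep else rep(TRUE, length(meanp))
  f <- fit_quadratic(meanp[keep], set$x[keep])
  c(minimum_value = f$c, curvature = f$a, mse = f$mse)
}
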