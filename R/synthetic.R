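# Parametric flask-scene renderer with pixel-level ground truth.
#
# Every downstream stage (ROI detection, Moire suppression, the four feature
# analyses, classification) is testable against these scenes: the renderer
# reports the true circle, particle mask, and check-pattern occlusion of each
# image it draws. Rasterization is hard (no anti-aliasing) so mask oracles
# are exact.

#' Render a checked tablet background
#'
#' A light field crossed by dark grid lines at a regular spacing, emulating
#' the checked background image shown on the tablet under the flask. Line
#' center coordinates are returned for use as oracles.
#'
#' @param image_size integer `c(H, W)` in pixels.
#' @param cell_size_px grid pitch in pixels (distance between line centers).
#' @param line_width_px line width in pixels; must satisfy
#'   `0 < line_width_px < cell_size_px`.
#' @param field_intensity,line_intensity 8-bit intensities of the background
#'   field and the grid lines.
#' @return list with `image` (H x W matrix), `xs`, `ys` (column/row centers
#'   of the interior vertical/horizontal lines).
#' @export
#' @examples
#' bg <- render_checked_background(c(240, 240), cell_size_px = 48, line_width_px = 4)
#' length(bg$xs)
render_checked_background <- function(image_size, cell_size_px = 48,
                                      line_width_px = 4,
                                      field_intensity = 255,
                                      line_intensity = 40) {
  if (!(cell_size_px > line_width_px && line_width_px > 0)) {
    stop("render_checked_background: need cell_size_px > line_width_px > 0")
  }
  h <- image_size[1]; w <- image_size[2]
  img <- matrix(field_intensity, h, w)
  xs <- seq(cell_size_px, w - 1, by = cell_size_px)
  ys <- seq(cell_size_px, h - 1, by = cell_size_px)
  half_lo <- floor((line_width_px - 1) / 2)
  half_hi <- floor(line_width_px / 2)
  for (x in xs) {
    cols <- max(1, x - half_lo):min(w, x + half_hi)
    img[, cols] <- line_intensity
  }
  for (y in ys) {
    rows <- max(1, y - half_lo):min(h, y + half_hi)
    img[rows, ] <- line_intensity
  }
  list(image = img, xs = xs, ys = ys,
       cell_size_px = cell_size_px, line_width_px = line_width_px,
       field_intensity = field_intensity, line_intensity = line_intensity)
}

#' Specify a synthetic flask scene
#'
#' @param background `"white"` or `"checked"`.
#' @param image_size `c(H, W)` pixels.
#' @param circle `c(cx, cy, r)`: solution-disk center (column, row) and
#'   radius in pixels; `r` must be below `min(H, W) / 2`.
#' @param turbidity cloudiness in \[0, 1\]; 0 = transparent, 1 = opaque.
#' @param radial_gradient `c(a0, c0)`: brightness profile of the turbid
#'   liquid, `I(rho) = c0 + a0 * rho^2` with `rho` the radius normalized to
#'   \[0, 1\]. The default `c(0, 235)` is a flat milky tone.
#' @param particles data frame with columns `x`, `y`, `radius`, `intensity`
#'   (pixel units / 8-bit); every particle must lie fully inside the circle.
#' @param tint RGB channel multipliers in \[0, 1\] applied to the solution.
#' @param moire optional `c(period_px, amplitude, orientation_deg)` additive
#'   sinusoidal stripe overlay emulating display-capture interference.
#' @param noise_sigma Gaussian pixel-noise standard deviation (intensity).
#' @param scatter_sigma forward-scattering blur: the background seen through
#'   the solution is Gaussian-blurred with standard deviation
#'   `scatter_sigma * turbidity` pixels before blending, so a turbid liquid
#'   washes out background detail (the check pattern) as well as darkening
#'   it. Zero at `turbidity = 0`, leaving the identity case exact.
#' @param rim `c(width_px, intensity)` of the flask-wall annulus drawn just
#'   outside the solution disk (the glass rim that makes even a perfectly
#'   clear solution visible); `c(0, 0)` disables it.
#' @param seed integer RNG seed; renders are bit-identical given the spec.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(background = c("white", "checked"),
                       image_size = c(320, 320),
                       circle = c(160, 160, 140),
                       turbidity = 0,
                       radial_gradient = c(0, 235),
                       particles = NULL,
                       tint = c(1, 1, 1),
                       moire = NULL,
                       noise_sigma = 0,
                       scatter_sigma = 4,
                       rim = c(3, 70),
                       seed = 1L) {
  background <- match.arg(background)
  stopifnot(turbidity >= 0, turbidity <= 1)
  if (circle[3] >= min(image_size) / 2) {
    stop("scene_spec: circle radius must be < min(H, W) / 2")
  }
  if (is.null(particles)) {
    particles <- data.frame(x = numeric(0), y = numeric(0),
                            radius = numeric(0), intensity = numeric(0))
  }
  if (nrow(particles) > 0) {
    d <- sqrt((particles$x - circle[1])^2 + (particles$y - circle[2])^2)
    if (any(d + particles$radius > circle[3])) {
      stop("scene_spec: all particles must lie fully inside the circle")
    }
  }
  structure(list(background = background, image_size = image_size,
                 circle = circle, turbidity = turbidity,
                 radial_gradient = radial_gradient, particles = particles,
                 tint = tint, moire = moire, noise_sigma = noise_sigma,
                 scatter_sigma = scatter_sigma, rim = rim,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a flask scene with ground truth
#'
#' Inside-circle pixels are the background alpha-blended by `turbidity`
#' toward the radial liquid-brightness model; particles are drawn last as
#' hard dark disks; an optional Moire sinusoid and Gaussian noise are added
#' afterwards. A `turbidity = 0` scene without particles or Moire leaves the
#' inside of the circle exactly equal to the background.
#'
#' @param spec a [scene_spec()].
#' @param checked_bg optional pre-rendered checked background (from
#'   [render_checked_background()]) so a white/checked pair shares one grid.
#' @return list with `image` (H x W x 3 array, 8-bit scale) and `truth`:
#'   `label` (`"DS"`, `"US1"` or `"US2"`), `particle_mask`,
#'   `particle_pixel_count`, `occluded_fraction` (checked scenes; `NA`
#'   otherwise), `circle`, `turbidity`.
#' @export
render_scene <- function(spec, checked_bg = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cx <- spec$circle[1]; cy <- spec$circle[2]; r <- spec$circle[3]

  if (spec$background == "checked") {
    if (is.null(checked_bg)) checked_bg <- render_checked_background(c(h, w))
    bg <- checked_bg$image
  } else {
    bg <- matrix(255, h, w)
  }

  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  dist2 <- (xg - cx)^2 + (yg - cy)^2
  inside <- dist2 <= r^2
  rho2 <- pmin(dist2 / r^2, 1)

  a0 <- spec$radial_gradient[1]; c0 <- spec$radial_gradient[2]
  target <- pmin(pmax(c0 + a0 * rho2, 0), 255)

  t <- spec$turbidity
  # background seen through the liquid: scattering blurs it before the
  # turbidity blend washes it toward the liquid tone
  sigma <- if (is.null(spec$scatter_sigma)) 0 else spec$scatter_sigma * t
  bg_seen <- if (sigma >= 0.3) {
    convolve2(bg, gaussian_kernel(2 * ceiling(2 * sigma) + 1, sigma))
  } else bg
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    plane <- bg
    blended <- bg_seen * (1 - t) + target * t
    plane[inside] <- blended[inside] * spec$tint[ch]
    img[, , ch] <- plane
  }

  # flask rim: annulus strictly outside the closed solution disk
  if (spec$rim[1] > 0) {
    ann <- dist2 > r^2 & dist2 <= (r + spec$rim[1])^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ann] <- spec$rim[2]
      img[, , ch] <- plane
    }
  }

  # particles drawn last as hard dark disks
  pmask <- matrix(FALSE, h, w)
  if (nrow(spec$particles) > 0) {
    for (i in seq_len(nrow(spec$particles))) {
      p <- spec$particles[i, ]
      pd <- (xg - p$x)^2 + (yg - p$y)^2 <= p$radius^2
      pmask <- pmask | pd
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[pd] <- p$intensity
        img[, , ch] <- plane
      }
    }
  }

  if (!is.null(spec$moire)) {
    # Moire is display-capture interference: the display grid seen through
    # a turbid liquid loses coherence, so the stripe amplitude inside the
    # solution is attenuated by (1 - turbidity)
    per <- spec$moire[1]; amp <- spec$moire[2]
    th <- spec$moire[3] * pi / 180
    stripe <- amp * sin(2 * pi * (xg * cos(th) + yg * sin(th)) / per)
    stripe[inside] <- stripe[inside] * (1 - t)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + stripe
  }

  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed, matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
  }
  img <- clip8(img)

  occ <- NA_real_
  if (spec$background == "checked") {
    if (is.null(checked_bg)) checked_bg <- render_checked_background(c(h, w))
    line_px <- checked_bg$image == checked_bg$line_intensity & inside
    if (any(line_px)) {
      occ <- mean(t + (1 - t) * pmask[line_px])
    } else {
      occ <- 0
    }
  }

  label <- if (sum(pmask) > 0) "US2" else if (t >= 0.5) "US1" else "DS"

  list(image = img,
       truth = list(label = label,
                    particle_mask = pmask,
                    particle_pixel_count = sum(pmask),
                    occluded_fraction = occ,
                    circle = spec$circle,
                    turbidity = t))
}

#' Default per-class scene parameter ranges
#'
#' DS: near-transparent, no particles. US1: heavily turbid with a darker
#' center (barely-dissolved solute scatters light). US2: mildly turbid with
#' 20-2000 pixels of undissolved particles, including occasional clumps.
#'
#' @export
default_class_ranges <- function() {
  list(
    DS  = list(turbidity = c(0, 0.1), particle_area = c(0, 0),
               a0 = c(0, 0), c0 = c(235, 235)),
    US1 = list(turbidity = c(0.6, 0.95), particle_area = c(0, 0),
               a0 = c(40, 90), c0 = c(50, 110)),
    US2 = list(turbidity = c(0.05, 0.5), particle_area = c(20, 2000),
               a0 = c(0, 30), c0 = c(180, 235))
  )
}

# draw a random particle field totalling roughly `area` pixels
random_particles <- function(area, circle, clump_prob = 0.1) {
  cx <- circle[1]; cy <- circle[2]; r <- circle[3]
  rows <- list()
  total <- 0
  while (total < area) {
    pr <- if (stats::runif(1) < clump_prob && area - total > 150) {
      sample(6:10, 1)
    } else {
      sample(c(1, 1, 2, 2, 3), 1)
    }
    max_d <- r - pr - 8
    if (max_d <= 0) break
    rd <- sqrt(stats::runif(1)) * max_d
    an <- stats::runif(1, 0, 2 * pi)
    rows[[length(rows) + 1]] <- data.frame(
      x = round(cx + rd * cos(an)), y = round(cy + rd * sin(an)),
      radius = pr, intensity = stats::runif(1, 60, 130))
    total <- total + pi * pr^2
  }
  if (length(rows) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      radius = numeric(0), intensity = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Sample a labelled synthetic dataset
#'
#' Renders `n_per_class` paired scenes (white and checked background, same
#' solution state) for each of the three dissolution classes.
#'
#' @param n_per_class samples per class (>= 1).
#' @param class_ranges per-class parameter ranges as in
#'   [default_class_ranges()]; ranges that make classes indistinguishable
#'   raise a warning, not an error.
#' @param seed integer seed driving every random choice.
#' @param image_size,cell_size_px scene geometry.
#' @param r_frac solution-radius range as a fraction of `min(H, W)` (the
#'   flask fills most of the frame).
#' @param moire_prob fraction of samples receiving a Moire overlay.
#' @param tint_prob fraction of samples receiving a mild color tint.
#' @param noise_sigma pixel-noise level.
#' @return list of samples, each with `sample_id`, `white` and `checked`
#'   (H x W x 3 arrays), `truth` (checked-scene ground truth plus shared
#'   particle mask), `label`.
#' @export
sample_dataset <- function(n_per_class, class_ranges = default_class_ranges(),
                           seed = 1L, image_size = c(320, 320),
                           cell_size_px = 48, r_frac = c(0.406, 0.469),
                           moire_prob = 0.3, tint_prob = 0.3,
                           noise_sigma = 2) {
  stopifnot(n_per_class >= 1)
  if (class_ranges$DS$turbidity[2] >= class_ranges$US1$turbidity[1] &&
      class_ranges$DS$particle_area[2] == 0 &&
      class_ranges$US1$particle_area[2] == 0) {
    warning("sample_dataset: DS and US1 parameter ranges overlap; classes may be indistinguishable")
  }
  h <- image_size[1]; w <- image_size[2]
  bg <- render_checked_background(image_size, cell_size_px = cell_size_px)
  samples <- with_seed(seed, {
    out <- list()
    idx <- 0
    for (cls in c("DS", "US1", "US2")) {
      rg <- class_ranges[[cls]]
      for (i in seq_len(n_per_class)) {
        idx <- idx + 1
        r <- round(stats::runif(1, r_frac[1] * min(image_size),
                                r_frac[2] * min(image_size)))
        cx <- round(w / 2 + stats::runif(1, -6, 6))
        cy <- round(h / 2 + stats::runif(1, -6, 6))
        turb <- stats::runif(1, rg$turbidity[1], rg$turbidity[2])
        # US1 must stay above the labelling threshold; DS below it
        a0 <- stats::runif(1, rg$a0[1], rg$a0[2])
        c0 <- stats::runif(1, rg$c0[1], rg$c0[2])
        circle <- c(cx, cy, r)
        parts <- if (rg$particle_area[2] > 0) {
          area <- exp(stats::runif(1, log(max(rg$particle_area[1], 20)),
                                   log(rg$particle_area[2])))
          random_particles(area, circle)
        } else NULL
        tint <- if (stats::runif(1) < tint_prob) {
          tt <- c(1, 1, 1); tt[sample(1:3, 1)] <- stats::runif(1, 0.85, 1); tt
        } else c(1, 1, 1)
        moire <- if (stats::runif(1) < moire_prob) {
          c(stats::runif(1, 6, 14), stats::runif(1, 10, 25), stats::runif(1, 0, 180))
        } else NULL
        sseed <- sample.int(2^30, 1)
        common <- list(image_size = image_size, circle = circle,
                       turbidity = turb, radial_gradient = c(a0, c0),
                       particles = parts, tint = tint, moire = moire,
                       noise_sigma = noise_sigma)
        sw <- do.call(scene_spec, c(list(background = "white", seed = sseed), common))
        sc <- do.call(scene_spec, c(list(background = "checked", seed = sseed + 1L), common))
        rw <- render_scene(sw)
        rc <- render_scene(sc, checked_bg = bg)
        truth <- rc$truth
        truth$label <- cls
        out[[idx]] <- list(sample_id = sprintf("%s_%03d", cls, i),
                           white = rw$image, checked = rc$image,
                           truth = truth, label = cls)
      }
    }
    out
  })
  samples
}

#' Write a rendered dataset to disk
#'
#' Writes each sample's white and checked captures as PNG and a CSV manifest
#' with columns `sample_id`, `white_path`, `checked_path`, `label`,
#' `particle_pixel_count`, `turbidity`, `seed`.
#'
#' @param samples output of [sample_dataset()].
#' @param dir output directory (created if missing).
#' @param seed the seed used to generate `samples` (recorded in the manifest).
#' @return the manifest data frame, invisibly written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_dataset <- function(samples, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    wp <- file.path(dir, paste0(s$sample_id, "_white.png"))
    cp <- file.path(dir, paste0(s$sample_id, "_checked.png"))
    png::writePNG(aperm(s$white / 255, c(1, 2, 3)), wp)
    png::writePNG(aperm(s$checked / 255, c(1, 2, 3)), cp)
    data.frame(sample_id = s$sample_id, white_path = wp, checked_path = cp,
               label = s$label,
               particle_pixel_count = s$truth$particle_pixel_count,
               turbidity = s$truth$turbidity, seed = seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest
#'
#' @param path CSV manifest path; image paths are validated.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "white_path", "checked_path", "label")
  if (!all(req %in% names(m))) {
    stop("read_manifest: manifest must have columns ", paste(req, collapse = ", "))
  }
  if (!all(m$label %in% c("DS", "US1", "US2"))) {
    stop("read_manifest: labels must be DS, US1 or US2")
  }
  missing <- !file.exists(m$white_path) | !file.exists(m$checked_path)
  if (any(missing)) {
    stop("read_manifest: missing image files for samples: ",
         paste(m$sample_id[missing], collapse = ", "))
  }
  m
}
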