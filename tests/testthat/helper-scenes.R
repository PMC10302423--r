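# Shared fixtures: all scenes are generated in code at test time.

# small masked ROI with a constant interior
tiny_masked <- function(value = 100, size = 160, r = 60) {
  img <- matrix(value, size, size)
  apply_mask(img, circular_roi(size / 2, size / 2, r))
}

# white-background scene at the default rendering scale, with its true ROI
scene_with_roi <- function(..., circle = c(160, 160, 140)) {
  spec <- scene_spec(background = "white", circle = circle, ...)
  sc <- render_scene(spec)
  list(spec = spec, scene = sc,
       masked = apply_mask(to_gray(sc$image), do.call(circular_roi, as.list(circle))))
}

# random dissolution-class scene parameters, mirroring the generator ranges
random_scene_spec <- function(cls, seed, background = "white",
                              image_size = c(320, 320)) {
  r <- round(stats::runif(1, 0.406, 0.469) * min(image_size))
  cx <- round(image_size[2] / 2 + stats::runif(1, -6, 6))
  cy <- round(image_size[1] / 2 + stats::runif(1, -6, 6))
  t <- switch(cls, DS = stats::runif(1, 0, 0.1),
              US1 = stats::runif(1, 0.6, 0.95),
              US2 = stats::runif(1, 0.05, 0.5))
  rg <- switch(cls, DS = c(0, 235),
               US1 = c(stats::runif(1, 40, 90), stats::runif(1, 50, 110)),
               US2 = c(stats::runif(1, 0, 30), stats::runif(1, 180, 235)))
  scene_spec(background = background, image_size = image_size,
             circle = c(cx, cy, r), turbidity = t, radial_gradient = rg,
             noise_sigma = 2, seed = seed)
}

# separable 3-class Gaussian blobs in 9 dimensions (margin >= 2 sd).
# Simplex-style centers: each class is linearly separable from the union of
# the other two (collinear centers would break one-vs-rest).
separable_blobs <- function(n_per_class = 100, seed = 1, sd = 1, gap = 6) {
  centers <- gap * diag(3)
  centers <- cbind(centers, matrix(0, 3, 6))
  x <- with_seed2(seed, {
    do.call(rbind, lapply(1:3, function(k) {
      matrix(stats::rnorm(n_per_class * 9, sd = sd), n_per_class, 9) +
        matrix(centers[k, ], n_per_class, 9, byrow = TRUE)
    }))
  })
  colnames(x) <- FEATURE_NAMES
  list(x = x, labels = factor(rep(CLASS_LABELS, each = n_per_class),
                              levels = CLASS_LABELS))
}

with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# brute-force per-pixel GHA oracle: explicit loops, two-pass statistics
gha_oracle <- function(image, grid) {
  n <- grid$n
  mus <- c(); sds <- c()
  for (q in seq_len(grid$m)) {
    vals <- c()
    for (i in 0:(n - 1)) {
      for (j in 0:(n - 1)) {
        vals <- c(vals, image[grid$cells$row[q] + i, grid$cells$col[q] + j])
      }
    }
    mu <- sum(vals) / length(vals)
    mus <- c(mus, mu)
    sds <- c(sds, sqrt(sum((vals - mu)^2) / length(vals)))
  }
  mbar <- sum(mus) / length(mus)
  sbar <- sum(sds) / length(sds)
  c(MMG = mbar, MSG = sbar,
    SMG = sqrt(sum((mus - mbar)^2) / length(mus)),
    SSG = sqrt(sum((sds - sbar)^2) / length(sds)))
}
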