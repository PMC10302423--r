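test_that("profiles of a constant disk are constant and short ROIs error", {
  m <- tiny_masked(100)
  ps <- extract_profiles(m)
  expect_identical(dim(ps$profiles), c(120L, 12L))
  kept <- ps$profiles[ps$keep, ]
  expect_true(all(abs(kept - 100) < 1e-9))
  small <- apply_mask(matrix(100, 64, 64), circular_roi(32, 32, 12))
  expect_error(extract_profiles(small), "16 px")
})

test_that("the even-quadratic fit has closed-form behavior", {
  x <- seq(-1, 1, length.out = 101)
  f <- fit_quadratic(rep(7, 101), x)
  expect_equal(f$a, 0)
  expect_equal(f$c, 7)
  expect_equal(f$mse, 0)
  # pure odd input is orthogonal to the even basis
  f2 <- fit_quadratic(x, x)
  expect_equal(f2$a, 0, tolerance = 1e-12)
  expect_equal(f2$c, 0, tolerance = 1e-12)
  # exact quadratic is recovered exactly
  f3 <- fit_quadratic(80 * x^2 + 60, x)
  expect_equal(f3$a, 80)
  expect_equal(f3$c, 60)
  expect_equal(f3$mse, 0, tolerance = 1e-18)
})

test_that("noiseless radial scenes recover the generator model within 5%", {
  for (p in list(c(40, 120), c(80, 60))) {
    spec <- scene_spec(background = "white", turbidity = 1,
                       radial_gradient = p, noise_sigma = 0,
                       circle = c(160, 160, 140))
    m <- apply_mask(to_gray(render_scene(spec)$image),
                    circular_roi(160, 160, 140))
    f <- rpa_features(extract_profiles(m))
    expect_lt(abs(f[["curvature"]] - p[1]) / p[1], 0.05)
    expect_lt(abs(f[["minimum_value"]] - p[2]) / p[2], 0.05)
    expect_lte(f[["mse"]], 4)
  }
})

test_that("a 90-degree scene rotation permutes the profile set exactly", {
  spec <- scene_spec(background = "white", turbidity = 0.8,
                     radial_gradient = c(60, 90), noise_sigma = 2,
                     circle = c(160, 160, 120), seed = 14,
                     particles = data.frame(x = 190, y = 150, radius = 6,
                                            intensity = 70))
  g <- to_gray(render_scene(spec)$image)
  m <- apply_mask(g, circular_roi(160, 160, 120))
  p0 <- extract_profiles(m)
  # rotate the image by 90 degrees (exact index permutation, 320 even:
  # pixel centers map onto pixel centers about the image center)
  g90 <- t(g)[, nrow(g):1]
  m90 <- apply_mask(g90, circular_roi(320 + 1 - 160, 160, 120))
  p90 <- extract_profiles(m90)
  # each diameter of the rotated scene equals a (possibly reversed)
  # diameter of the original
  match_one <- function(prof, set) {
    any(vapply(seq_len(ncol(set)), function(k) {
      max(abs(prof - set[, k])) < 1e-6 ||
        max(abs(rev(prof) - set[, k])) < 1e-6
    }, logical(1)))
  }
  for (k in 1:12) expect_true(match_one(p90$profiles[, k], p0$profiles))
})

test_that("features are invariant under 180-degree rotation", {
  spec <- scene_spec(background = "white", turbidity = 0.7,
                     radial_gradient = c(50, 100), noise_sigma = 2,
                     circle = c(160, 160, 120), seed = 5)
  g <- to_gray(render_scene(spec)$image)
  m <- apply_mask(g, circular_roi(160, 160, 120))
  f0 <- rpa_features(extract_profiles(m))
  g180 <- g[nrow(g):1, ncol(g):1]
  m180 <- apply_mask(g180, circular_roi(320 + 1 - 160, 320 + 1 - 160, 120))
  f180 <- rpa_features(extract_profiles(m180))
  expect_equal(f0, f180, tolerance = 1e-6)
})

test_that("an off-center dot only disturbs the diameters that cross it", {
  dot <- data.frame(x = 160 + 80, y = 160, radius = 3, intensity = 40)
  spec <- scene_spec(background = "white", turbidity = 1,
                     radial_gradient = c(0, 200), noise_sigma = 0,
                     particles = dot, circle = c(160, 160, 120))
  m <- apply_mask(to_gray(render_scene(spec)$image),
                  circular_roi(160, 160, 120))
  ps <- extract_profiles(m)
  dev <- apply(ps$profiles, 2, function(v) max(abs(v - 200)))
  # the dot sits on the 0-degree diameter; 90-degree misses it entirely
  expect_gt(dev[1], 100)
  expect_gt(dev[7], 100)   # reversed duplicate
  expect_lt(dev[4], 1)     # 90 degrees
  expect_lt(dev[10], 1)
})

test_that("feature ordering separates the dissolution phenotypes", {
  mk <- function(t, rg, parts = NULL) {
    spec <- scene_spec(background = "white", turbidity = t,
                       radial_gradient = rg, noise_sigma = 1,
                       particles = parts, circle = c(160, 160, 140), seed = 3)
    m <- apply_mask(to_gray(render_scene(spec)$image),
                    circular_roi(160, 160, 140))
    rpa_features(extract_profiles(m))
  }
  ds <- mk(0.05, c(0, 235))
  us1 <- mk(0.9, c(70, 80))
  expect_gt(us1[["curvature"]], ds[["curvature"]])
  expect_lt(us1[["minimum_value"]], ds[["minimum_value"]])
  set.seed(21)
  parts <- solscreen:::random_particles(800, c(160, 160, 140), clump_prob = 0)
  us2 <- mk(0.2, c(0, 235), parts)
  expect_gt(us2[["mse"]], ds[["mse"]])
})
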