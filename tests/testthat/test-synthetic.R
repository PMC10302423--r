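test_that("checked background construction matches its line bookkeeping", {
  bg <- render_checked_background(c(480, 480), cell_size_px = 60, line_width_px = 4)
  expect_length(bg$xs, 7)
  expect_length(bg$ys, 7)
  expect_equal(diff(bg$xs), rep(60, 6))
  # two intensity modes only: line color and field color
  expect_setequal(unique(as.vector(bg$image)), c(40, 255))
  expect_error(render_checked_background(c(480, 480), 60, 0), "line_width")
  expect_error(render_checked_background(c(480, 480), 4, 8), "line_width")
})

test_that("transparent particle-free scene leaves the background untouched inside the circle", {
  spec <- scene_spec(background = "white", turbidity = 0, noise_sigma = 0,
                     circle = c(160, 160, 120))
  sc <- render_scene(spec)
  xg <- matrix(1:320, 320, 320, byrow = TRUE)
  yg <- matrix(1:320, 320, 320)
  inside <- (xg - 160)^2 + (yg - 160)^2 <= 120^2
  for (ch in 1:3) expect_true(all(sc$image[, , ch][inside] == 255))
})

test_that("particle masks agree with a brute-force rasterization oracle", {
  parts <- data.frame(x = c(120, 180, 160), y = c(160, 140, 200),
                      radius = c(4, 4, 4), intensity = 80)
  spec <- scene_spec(background = "white", turbidity = 0.2, particles = parts,
                     noise_sigma = 0, circle = c(160, 160, 120))
  sc <- render_scene(spec)
  # independent rasterization: per-pixel distance test over the full frame
  oracle <- 0
  for (row in 1:320) {
    for (col in 1:320) {
      hit <- any((col - parts$x)^2 + (row - parts$y)^2 <= parts$radius^2)
      oracle <- oracle + hit
    }
  }
  expect_identical(sc$truth$particle_pixel_count, as.integer(oracle))
  expect_identical(sc$truth$particle_pixel_count, sum(sc$truth$particle_mask))
  expect_identical(sc$truth$label, "US2")
})

test_that("rendering is deterministic and rejects out-of-circle particles", {
  spec <- scene_spec(background = "checked", turbidity = 0.4, noise_sigma = 3,
                     moire = c(9, 20, 30), seed = 99)
  a <- render_scene(spec)
  b <- render_scene(spec)
  expect_identical(a$image, b$image)
  expect_error(
    scene_spec(particles = data.frame(x = 300, y = 160, radius = 5,
                                      intensity = 80),
               circle = c(160, 160, 140)),
    "fully inside")
})

test_that("sampled datasets have exact class counts and construction invariants", {
  samples <- sample_dataset(3, seed = 7)
  expect_length(samples, 9)
  labels <- vapply(samples, `[[`, character(1), "label")
  expect_equal(unname(table(labels)[CLASS_LABELS]), rep(3L, 3),
               ignore_attr = TRUE)
  counts <- vapply(samples, function(s) s$truth$particle_pixel_count, numeric(1))
  expect_true(all(counts[labels == "US2"] > 0))
  expect_true(all(counts[labels == "DS"] == 0))
  expect_true(all(counts[labels == "US1"] == 0))
  # same seed, same dataset
  again <- sample_dataset(3, seed = 7)
  expect_identical(samples[[5]]$white, again[[5]]$white)
  expect_identical(samples[[9]]$checked, again[[9]]$checked)
})

test_that("check-pattern occlusion is non-decreasing in turbidity", {
  occ <- vapply(seq(0, 1, length.out = 6), function(t) {
    spec <- scene_spec(background = "checked", turbidity = t, noise_sigma = 0,
                       seed = 3)
    render_scene(spec)$truth$occluded_fraction
  }, numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("dataset round-trips through PNG files and a CSV manifest", {
  dir <- withr::local_tempdir()
  samples <- sample_dataset(1, seed = 5)
  manifest <- write_dataset(samples, dir, seed = 5)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(back), 3)
  img <- png::readPNG(back$white_path[1]) * 255
  expect_equal(img[, , 1], samples[[1]]$white[, , 1], tolerance = 1e-8,
               ignore_attr = TRUE)
  # manifests validate labels and paths
  bad <- back
  bad$white_path[1] <- file.path(dir, "missing.png")
  badfile <- file.path(dir, "bad.csv")
  utils::write.csv(bad, badfile, row.names = FALSE)
  expect_error(read_manifest(badfile), "missing image files")
})
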