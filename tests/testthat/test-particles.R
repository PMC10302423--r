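test_that("parameter constructors enforce their invariants", {
  expect_error(adaptive_threshold_params(block_size = 150))
  expect_error(gabor_params(orientations = numeric(0)))
  expect_silent(adaptive_threshold_params(block_size = 151, c_offset = 10))
})

test_that("uniform ROIs yield empty masks in both segmentation stages", {
  m <- tiny_masked(200)
  expect_false(any(segment_fine(m$image, m$mask)))
  expect_false(any(segment_clumps(m$image, m$mask)))
})

test_that("a small dark disk is segmented close to its true area", {
  img <- matrix(200, 160, 160)
  roi <- circular_roi(80, 80, 60)
  xg <- matrix(1:160, 160, 160, byrow = TRUE); yg <- matrix(1:160, 160, 160)
  disk <- (xg - 70)^2 + (yg - 90)^2 <= 5^2
  img[disk] <- 60
  m <- apply_mask(img, roi)
  mask <- segment_fine(m$image, m$mask)
  a <- sum(disk)
  expect_gte(sum(mask), 0.8 * a)
  expect_lte(sum(mask), 1.2 * a)
})

test_that("segmentation equals a global threshold when the local mean is flat", {
  img <- matrix(200, 160, 160)
  img[80, 80] <- 50   # one dark pixel barely moves a 151-px local mean
  roi <- circular_roi(80, 80, 70)
  m <- apply_mask(img, roi)
  got <- segment_fine(m$image, m$mask)
  ref <- (m$image < mean(m$image[m$mask]) - 10) & m$mask
  expect_identical(got, ref)
})

test_that("the clump stage takes large blobs and ignores dot fields", {
  # one irregular dark blob over 40 px across
  blob <- data.frame(x = c(160, 172, 150), y = c(160, 166, 168),
                     radius = c(14, 10, 9), intensity = 90)
  spec <- scene_spec(background = "white", turbidity = 0.15, noise_sigma = 2,
                     particles = blob, circle = c(160, 160, 140), seed = 2)
  sc <- render_scene(spec)
  m <- apply_mask(to_gray(sc$image), circular_roi(160, 160, 140))
  cm <- segment_clumps(m$image, m$mask)
  overlap <- sum(cm & sc$truth$particle_mask) / sum(sc$truth$particle_mask)
  expect_gte(overlap, 0.6)
  # dot fields are left entirely to the fine stage
  set.seed(13)
  dots <- solscreen:::random_particles(500, c(160, 160, 140), clump_prob = 0)
  spec2 <- scene_spec(background = "white", turbidity = 0.15, noise_sigma = 2,
                      particles = dots, circle = c(160, 160, 140), seed = 3)
  m2 <- apply_mask(to_gray(render_scene(spec2)$image),
                   circular_roi(160, 160, 140))
  expect_identical(sum(segment_clumps(m2$image, m2$mask)), 0L)
})

test_that("the clump stage still fires where block-scale adaptivity blinds the fine stage", {
  blob <- data.frame(x = 160, y = 160, radius = 100, intensity = 90)
  spec <- scene_spec(background = "white", turbidity = 0, noise_sigma = 0,
                     particles = blob, circle = c(160, 160, 140))
  m <- apply_mask(to_gray(render_scene(spec)$image),
                  circular_roi(160, 160, 140))
  fine <- segment_fine(m$image, m$mask)
  clump <- segment_clumps(m$image, m$mask)
  # a blob much wider than the threshold block sets its own local mean, so
  # its interior falls below the c-offset trigger
  xg <- matrix(1:320, 320, 320, byrow = TRUE); yg <- matrix(1:320, 320, 320)
  center <- (xg - 160)^2 + (yg - 160)^2 <= 40^2
  expect_lt(mean(fine[center]), 0.05)
  expect_gt(sum(clump), 1000)
})

test_that("counting is additive over disjoint masks and zero on empties", {
  roi_mask <- matrix(TRUE, 100, 100)
  empty <- matrix(FALSE, 100, 100)
  expect_identical(count_particles(empty, empty, roi_mask), 0L)
  fine <- empty; fine[20:29, 20:31] <- TRUE          # 120 px
  clump <- empty; clump[60:74, 60:79] <- TRUE        # 300 px
  expect_identical(count_particles(fine, clump, roi_mask, rim_margin = 0), 420L)
})

test_that("adding a particle never decreases the count", {
  set.seed(17)
  for (rep in 1:6) {
    base <- solscreen:::random_particles(runif(1, 100, 600),
                                         c(160, 160, 140), clump_prob = 0)
    extra_xy <- c(160, 160) + round(runif(2, -60, 60))
    extra <- rbind(base, data.frame(x = extra_xy[1], y = extra_xy[2],
                                    radius = 3, intensity = 80))
    count_of <- function(parts) {
      spec <- scene_spec(background = "white", turbidity = 0.1,
                         noise_sigma = 2, particles = parts,
                         circle = c(160, 160, 140), seed = rep)
      m <- apply_mask(to_gray(render_scene(spec)$image),
                      circular_roi(160, 160, 140))
      paa_features(m)$count
    }
    expect_gte(count_of(extra), count_of(base))
  }
})

test_that("counts calibrate against rendered particle area", {
  set.seed(23)
  for (area in c(150, 700, 1800)) {
    parts <- solscreen:::random_particles(area, c(160, 160, 140),
                                          clump_prob = 0)
    spec <- scene_spec(background = "white", turbidity = 0.1, noise_sigma = 2,
                       particles = parts, circle = c(160, 160, 140),
                       seed = area)
    sc <- render_scene(spec)
    m <- apply_mask(to_gray(sc$image), circular_roi(160, 160, 140))
    truth <- sc$truth$particle_pixel_count
    expect_lt(abs(paa_features(m)$count - truth), 0.15 * truth)
  }
})
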