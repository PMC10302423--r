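make_grid_mask <- function(size = 320, xs, ys, width = 4) {
  # same stroke convention as the drawing code: floor((w-1)/2) left,
  # floor(w/2) right of the center coordinate
  lo <- (width - 1) %/% 2; hi <- width %/% 2
  m <- matrix(FALSE, size, size)
  for (x in xs) m[, (x - lo):(x + hi)] <- TRUE
  for (y in ys) m[(y - lo):(y + hi), ] <- TRUE
  m
}

test_that("projection peaks recover constructed line coordinates", {
  xs <- c(40, 95, 150, 205, 260, 310)
  ys <- c(35, 90, 145, 200, 255, 305)
  pattern <- make_grid_mask(320, xs, ys)
  ls <- select_line_coordinates(pattern)
  expect_true(all(abs(sort(ls$xs) - xs) <= 2))
  expect_true(all(abs(sort(ls$ys) - ys) <= 2))
})

test_that("non-maximum suppression keeps the stronger of two close lines", {
  m <- matrix(FALSE, 320, 320)
  m[, 100:103] <- TRUE                 # strong line, 4 px wide
  m[1:150, 110:111] <- TRUE            # weaker line 10 px away
  # give the y-axis enough structure to avoid the insufficiency error
  for (y in c(40, 100, 160, 220)) m[y:(y + 2), ] <- TRUE
  ls <- select_line_coordinates(m)
  expect_true(all(abs(ls$xs - 102) > 20 | abs(ls$xs - 102) <= 3))
  expect_false(any(ls$xs %in% 108:113))
})

test_that("an empty pattern raises the insufficiency condition", {
  expect_error(select_line_coordinates(matrix(FALSE, 100, 100)),
               class = "solscreen_insufficient_pattern")
  # selected coordinates always respect the suppression radius
  dense <- make_grid_mask(320, seq(30, 310, by = 28), seq(30, 310, by = 28))
  ls <- select_line_coordinates(dense)
  expect_true(all(diff(sort(ls$xs)) > 25))
  expect_true(all(diff(sort(ls$ys)) > 25))
})

test_that("grid prediction keeps the four center-closest lines and nine parts", {
  roi <- circular_roi(160, 160, 140)
  roi_mask <- apply_mask(matrix(255, 320, 320), roi)$mask
  lines <- structure(list(xs = c(40, 95, 150, 205, 260, 310),
                          ys = c(35, 90, 145, 200, 255, 305)),
                     class = "line_set")
  grid <- predict_grid(lines, roi, roi_mask, line_width = 4)
  # oracle: rasterize the union of the 4 + 4 center-closest lines directly
  # (x = 40, 310 and y = 35, 305 are excluded by the closest-to-center rule)
  oracle <- make_grid_mask(320, c(95, 150, 205, 260), c(90, 145, 200, 255)) &
    roi_mask
  expect_identical(grid, oracle)
  # the complement inside the central window falls into exactly 9 regions
  inner <- matrix(FALSE, 320, 320)
  inner[93:252, 98:257] <- TRUE
  lab <- EBImage::bwlabel((!grid) & inner)
  expect_equal(max(lab), 9)
})

test_that("the superposition ratio is an intersection fraction", {
  p <- matrix(FALSE, 50, 50); p[10:19, ] <- TRUE
  expect_equal(superposition_ratio(p, p | matrix(TRUE, 50, 50)), 1)
  expect_equal(superposition_ratio(p, matrix(FALSE, 50, 50)), 0)
  half <- p; half[, 26:50] <- FALSE
  expect_equal(superposition_ratio(p, half), 0.5)
  expect_equal(superposition_ratio(matrix(FALSE, 50, 50), p), 0)
})

test_that("pattern detection sees transparent scenes and loses opaque ones", {
  bg <- render_checked_background(c(320, 320))
  clear <- scene_spec(background = "checked", turbidity = 0, noise_sigma = 2,
                      seed = 6)
  opaque <- scene_spec(background = "checked", turbidity = 1, noise_sigma = 2,
                       seed = 6)
  truth_lines <- make_grid_mask(320, bg$xs, bg$ys)
  run <- function(spec) {
    g <- to_gray(render_scene(spec, checked_bg = bg)$image)
    roi <- detect_solution_circle(g)
    m <- apply_mask(g, roi)
    list(det = detect_check_pattern(m$image, m$mask), mask = m$mask)
  }
  rc <- run(clear)
  in_roi_truth <- truth_lines & rc$mask
  expect_gte(sum(rc$det & in_roi_truth) / sum(in_roi_truth), 0.7)
  ro <- run(opaque)
  expect_lt(sum(ro$det), 0.05 * sum(rc$det))
  # white-background captures have no pattern to find
  white <- scene_spec(background = "white", turbidity = 0, noise_sigma = 2,
                      seed = 6)
  gw <- to_gray(render_scene(white)$image)
  mw <- apply_mask(gw, detect_solution_circle(gw))
  expect_lt(sum(detect_check_pattern(mw$image, mw$mask)), 0.02 * sum(mw$mask))
})

test_that("the assembled feature degrades with turbidity and is 0 when blocked", {
  ratio_at <- function(t) {
    spec <- scene_spec(background = "checked", turbidity = t, noise_sigma = 0,
                       seed = 8)
    g <- to_gray(render_scene(spec)$image)
    roi <- detect_solution_circle(g)
    sa_features(remove_moire(apply_mask(g, roi)))$ratio
  }
  expect_gte(ratio_at(0), 0.8)
  expect_identical(ratio_at(1), 0)
})
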