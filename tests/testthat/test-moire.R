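test_that("contrast enhancement follows the two-step clip formula", {
  p <- contrast_params(alpha = 1.0, beta = 1.2)
  ec <- function(v) enhance_contrast(matrix(v, 1, 1), p)[1, 1]
  expect_identical(ec(100), 112)   # 120 then 2*120-128
  expect_identical(ec(0), 0)
  expect_identical(ec(255), 255)
  expect_identical(ec(160), 255)   # saturation point of the defaults
  # monotone non-decreasing over the whole 8-bit range
  out <- enhance_contrast(matrix(0:255, 1), p)
  expect_true(all(diff(as.numeric(out)) >= 0))
})

test_that("non-local means agrees with a direct reference implementation", {
  set.seed(31)
  img <- matrix(round(runif(18 * 14, 0, 255)), 18, 14)
  h <- 9; patch <- 3; search <- 7
  got <- solscreen:::nlm_denoise_cpp(img, h, patch, search)
  # naive reference: replicate padding, explicit patch-distance loops
  pr <- patch %/% 2; sr <- search %/% 2; pad <- pr + sr
  idx_r <- pmin(pmax((1 - pad):(18 + pad), 1), 18)
  idx_c <- pmin(pmax((1 - pad):(14 + pad), 1), 14)
  P <- img[idx_r, idx_c]
  ref <- matrix(0, 18, 14)
  for (i in 1:18) {
    for (j in 1:14) {
      pi <- i + pad; pj <- j + pad
      acc <- 0; wsum <- 0
      for (dy in -sr:sr) {
        for (dx in -sr:sr) {
          d2 <- mean((P[(pi - pr):(pi + pr), (pj - pr):(pj + pr)] -
                        P[(pi + dy - pr):(pi + dy + pr),
                          (pj + dx - pr):(pj + dx + pr)])^2)
          wgt <- exp(-d2 / h^2)
          acc <- acc + wgt * P[pi + dy, pj + dx]
          wsum <- wsum + wgt
        }
      }
      ref[i, j] <- acc / wsum
    }
  }
  # the kernel quantizes weights through a lookup table
  expect_equal(got, ref, tolerance = 2e-3)
})

test_that("a uniform ROI passes through the Moire stage unchanged", {
  m <- tiny_masked(200)
  out <- remove_moire(m)
  # interior away from the rim transition introduced by resampling
  core <- solscreen:::erode_disk(out$mask, 4)
  inside <- out$image[core]
  expect_lte(max(abs(inside - enhance_contrast(matrix(200, 1, 1))[1, 1])), 1)
  expect_true(all(out$image[!out$mask] == 0))
  expect_identical(dim(out$image), dim(m$image))
  expect_identical(out$roi, m$roi)
})

test_that("stripes are suppressed while fine particles survive", {
  # striped scene: energy at the stripe frequency must drop by >= 50%
  stripe_energy <- function(img, roi, period, theta_deg) {
    h <- nrow(img); w <- ncol(img)
    xg <- matrix(seq_len(w), h, w, byrow = TRUE)
    yg <- matrix(seq_len(h), h, w)
    d <- sqrt((xg - roi$cx)^2 + (yg - roi$cy)^2)
    win <- pmax(0, pmin(1, (roi$r - 10 - d) / 10))
    m <- (img - mean(img[win > 0])) * win
    F <- stats::fft(m)
    fy <- ifelse(0:(h - 1) <= h / 2, 0:(h - 1), 0:(h - 1) - h) / h
    fx <- ifelse(0:(w - 1) <= w / 2, 0:(w - 1), 0:(w - 1) - w) / w
    th <- theta_deg * pi / 180
    tx <- cos(th) / period; ty <- sin(th) / period
    d2a <- outer(fy, fx, function(a, b) (a - ty)^2 + (b - tx)^2)
    d2b <- outer(fy, fx, function(a, b) (a + ty)^2 + (b + tx)^2)
    sqrt(sum(Mod(F)[pmin(d2a, d2b) < 0.02^2]^2))
  }
  spec <- scene_spec(background = "white", turbidity = 0.25, noise_sigma = 2,
                     moire = c(9, 30, 70), radial_gradient = c(10, 215), seed = 4)
  g <- to_gray(render_scene(spec)$image)
  roi <- detect_solution_circle(g)
  m <- apply_mask(g, roi)
  mm <- remove_moire(m)
  e0 <- stripe_energy(m$image, roi, 9, 70)
  e1 <- stripe_energy(mm$image, roi, 9, 70)
  expect_lt(e1, 0.5 * e0)

  # particle scene: counts with and without the stage agree within 20%
  set.seed(12)
  parts <- solscreen:::random_particles(500, c(160, 160, 140), clump_prob = 0)
  spec2 <- scene_spec(background = "white", turbidity = 0.15, noise_sigma = 2,
                      particles = parts, seed = 5)
  g2 <- to_gray(render_scene(spec2)$image)
  m2 <- apply_mask(g2, detect_solution_circle(g2))
  c_no <- paa_features(m2)$count
  c_yes <- paa_features(remove_moire(m2))$count
  expect_lt(abs(c_yes - c_no), 0.2 * c_no)
})
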