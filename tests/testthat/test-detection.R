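test_that("band threshold selects exactly the in-band masked pixels", {
  img <- matrix(c(250, 130, 40, 90, 60, 220, 0, 255, 75), 3, 3)
  all_mask <- matrix(TRUE, 3, 3)
  bw <- band_threshold(img, all_mask, 30, 100)
  expect_identical(bw, img >= 30 & img <= 100)
  expect_equal(sum(bw), 4)  # 40, 90, 60, 75
  expect_false(any(band_threshold(matrix(255, 3, 3), all_mask, 30, 100)))
  expect_error(band_threshold(img, all_mask, 100, 30), "low <= high")

  # idempotent and monotone in the band
  set.seed(1)
  r <- matrix(sample(0:255, 400, TRUE), 20, 20)
  m <- matrix(TRUE, 20, 20)
  b1 <- band_threshold(r, m, 50, 120)
  expect_identical(band_threshold(r, b1, 50, 120), b1)
  wider <- band_threshold(r, m, 40, 140)
  expect_true(all(wider[b1]))
})

test_that("denoise removes only components below the area threshold", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2] <- TRUE                   # 2-px speckle
  m[8:15, 8:12] <- TRUE               # 40-px blob
  out <- denoise(m, 5)
  expect_false(any(out[1:5, 1:5]))
  expect_true(all(out[8:15, 8:12]))
  expect_identical(denoise(m, 1), m)
  expect_error(denoise(m, 0), "min_area")

  # salt noise on a simulated PIV mask: the four spots survive intact
  cfg <- test_config()
  sim <- simulate_subject(0.5, cfg, seed = 31)
  iris <- segment_iris(sim$blue, cfg$iris_radius_range, cfg$edge_threshold)
  bw <- band_threshold(sim$blue, iris$mask, 30, 100)
  set.seed(8)
  salt <- matrix(runif(length(bw)) < 0.001, nrow(bw), ncol(bw))
  noisy <- bw | (salt & iris$mask)
  clean <- denoise(noisy, cfg$min_area)
  expect_equal(max(EBImage::bwlabel(clean * 1)), 4)
  expect_true(all(bw[clean]))
})

test_that("hough transform finds rendered rings and matches the brute-force count", {
  expect_identical(nrow(hough_circles(matrix(0, 50, 50), c(5, 15),
                                      max_circles = 3)), 0L)
  draw_disc <- function(m, x0, y0, r, level = 255) {
    xs <- matrix(rep(0:(ncol(m) - 1), each = nrow(m)), nrow(m))
    ys <- matrix(rep(0:(nrow(m) - 1), times = ncol(m)), nrow(m))
    m[(xs - x0)^2 + (ys - y0)^2 <= r^2] <- level
    m
  }
  big <- draw_disc(matrix(0, 200, 200), 100, 100, 40)
  hc <- hough_circles(big, c(30, 50), edge_threshold = 200)
  expect_equal(nrow(hc), 1L)
  expect_lt(sqrt((hc$x - 100)^2 + (hc$y - 100)^2), 1 + 1e-9)
  expect_lte(abs(hc$r - 40), 1)

  # two disjoint discs on a small image, checked against the exhaustive
  # vote-counting oracle over the full parameter grid
  m <- draw_disc(matrix(0, 64, 64), 25, 25, 15)
  m <- draw_disc(m, 50, 50, 10, level = 200)
  two <- hough_circles(m, c(5, 20), edge_threshold = 200, max_circles = 2,
                       min_score = 10)
  expect_equal(nrow(two), 2L)
  expect_lt(sqrt((two$x[1] - 25)^2 + (two$y[1] - 25)^2), 1 + 1e-9)
  expect_lte(abs(two$r[1] - 15), 1)
  expect_lt(sqrt((two$x[2] - 50)^2 + (two$y[2] - 50)^2), 1 + 1e-9)
  expect_lte(abs(two$r[2] - 10), 1)
  oracle <- hough_oracle(m, c(5, 20), 200)
  expect_equal(two$x[1], oracle$x)
  expect_equal(two$y[1], oracle$y)
  expect_equal(two$r[1], oracle$r)
  expect_equal(two$score[1], oracle$score)

  expect_error(hough_circles(m, c(10, 9)), "radius range")
  expect_error(hough_circles(m, c(10, 80)), "image extent")
})

test_that("iris segmentation recovers the simulated iris and its mask", {
  cfg <- test_config()
  sim <- simulate_subject(0.5, cfg, seed = 41)
  iris <- segment_iris(sim$blue, cfg$iris_radius_range, cfg$edge_threshold)
  sc <- eye_scene()
  expect_lte(abs(iris$circle$r - sc$iris_radius), 2)
  expect_lt(sqrt((iris$circle$x - sc$pupil_center[1])^2 +
                 (iris$circle$y - sc$pupil_center[2])^2), 2)
  expect_lt(abs(sum(iris$mask) - pi * iris$circle$r^2) /
            (pi * iris$circle$r^2), 0.02)
  expect_error(segment_iris(matrix(0, 40, 40), cfg$iris_radius_range),
               "image extent")
  expect_error(segment_iris(matrix(0, 200, 200), c(60, 84)), "iris not found")
})

test_that("PIV spots are located to subpixel accuracy and labelled by quadrant", {
  cfg <- test_config()
  sim <- simulate_subject(0.5, cfg, seed = 51)
  det <- detect_piv_spots(sim$blue, cfg, band = "blue")
  truth <- true_piv_pattern(sim$truth, "blue", cfg$pixel_scale)
  expect_identical(det$label, c("a", "b", "c", "d"))
  expect_lt(max_centroid_err_px(det, truth, cfg$pixel_scale), 0.3)
  expect_identical(attr(det, "band"), "blue")

  # intensity weighting is at least as accurate on the noiseless scene
  detw <- detect_piv_spots(sim$blue, cfg, band = "blue",
                           weighting = "intensity")
  expect_lt(max_centroid_err_px(detw, truth, cfg$pixel_scale), 0.3)
})

test_that("missing spots produce a counted failure", {
  cfg <- test_config()
  sim <- simulate_subject(0.5, cfg, seed = 51)
  truth <- true_piv_pattern(sim$truth, "blue", cfg$pixel_scale)
  img3 <- sim$blue
  tp <- purkinjelca:::pattern_px(truth)
  x0 <- round(tp[1, "x"]); y0 <- round(tp[1, "y"])
  img3$pixels[y0 + 1 + (-10:10), x0 + 1 + (-10:10)] <- 20
  expect_error(detect_piv_spots(img3, cfg), "spot count 3")
})

test_that("quadrant labelling follows the fixed convention", {
  expect_identical(label_quadrants(c(1, -1, -1, 1), c(-1, -1, 1, 1), c(0, 0)),
                   c("a", "b", "c", "d"))
  th <- 10 * pi / 180
  rot <- function(x, y) list(x = x * cos(th) - y * sin(th),
                             y = x * sin(th) + y * cos(th))
  r <- rot(c(1, -1, -1, 1), c(-1, -1, 1, 1))
  expect_identical(label_quadrants(r$x, r$y, c(0, 0)),
                   c("a", "b", "c", "d"))
  expect_error(label_quadrants(c(1, -1, -1), c(-1, -1, 1), c(0, 0)),
               "four points")
  expect_error(label_quadrants(c(1, 1, -1, 1), c(-1, -1.2, 1, 1), c(0, 0)),
               "collision")
})

test_that("detection is invariant to a pupil-region intensity offset", {
  cfg <- test_config()
  sim <- simulate_subject(0.5, cfg, seed = 61)
  det <- detect_piv_spots(sim$blue, cfg, band = "blue")
  sc <- eye_scene()
  img2 <- sim$blue
  ny <- nrow(img2$pixels)
  xs <- matrix(rep(0:(ncol(img2$pixels) - 1), each = ny), ny)
  ys <- matrix(rep(0:(ny - 1), times = ncol(img2$pixels)), ny)
  inside <- (xs - sc$pupil_center[1])^2 + (ys - sc$pupil_center[2])^2 <=
    (sc$pupil_radius - 1)^2
  img2$pixels[inside] <- pmin(img2$pixels[inside] + 20, 255)
  cfg2 <- test_config(piv_band = cfg$piv_band + 20)
  det2 <- detect_piv_spots(img2, cfg2, band = "blue")
  expect_equal(det2$x_mm, det$x_mm, tolerance = 1e-9)
  expect_equal(det2$y_mm, det$y_mm, tolerance = 1e-9)
})
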