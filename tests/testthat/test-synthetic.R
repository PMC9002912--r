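test_that("forward spot model displaces spots by the wavefront gradient", {
  ref <- reference_pattern(1.5, center_mm = c(4.8, 4.8))
  zero <- zernike_coefficients(pupil_radius = 2.5)
  expect_equal(forward_spot_positions(zero, ref, 0.25)$x_mm, ref$x_mm)
  expect_equal(forward_spot_positions(zero, ref, 0.25)$y_mm, ref$y_mm)

  # pure x-tilt: every spot shifts by (k*t, 0)
  tilt <- zernike_coefficients(c(C1 = 0.6), pupil_radius = 2.5)
  pt <- forward_spot_positions(tilt, ref, 0.25)
  expect_equal(pt$x_mm - ref$x_mm, rep(0.25 * 0.6, 4))
  expect_equal(pt$y_mm - ref$y_mm, rep(0, 4))

  # pure defocus: equal-magnitude radial displacement k*4*c*rho_norm,
  # verified against central finite differences of W
  c4 <- 0.5
  cc <- zernike_coefficients(c(C4 = c4), pupil_radius = 2.5)
  pd <- forward_spot_positions(cc, ref, 0.25)
  disp <- sqrt((pd$x_mm - ref$x_mm)^2 + (pd$y_mm - ref$y_mm)^2)
  rho_n <- 1.5 / 2.5
  expect_equal(disp, rep(0.25 * 4 * c4 * rho_n, 4))
  u <- (ref$x_mm - 4.8) / 2.5; v <- (ref$y_mm - 4.8) / 2.5
  for (k in 1:4) {
    fd <- fd_gradient(function(a, b) reconstruct_wavefront(cc, a, b),
                      u[k], v[k])
    expect_equal(c(pd$x_mm[k] - ref$x_mm[k], pd$y_mm[k] - ref$y_mm[k]),
                 0.25 * fd, tolerance = 1e-6)
  }
  outward <- (pd$x_mm - ref$x_mm) * u + (pd$y_mm - ref$y_mm) * v
  expect_true(all(outward > 0))

  expect_error(forward_spot_positions(
    zernike_coefficients(c(C1 = 1)), ref, 0.25), "pupil_radius")
})

test_that("the forward model is linear in the coefficients", {
  ref <- reference_pattern(1.5, center_mm = c(4.8, 4.8))
  set.seed(5)
  a <- zernike_coefficients(c(0, rnorm(5, sd = 0.2)), pupil_radius = 2.5)
  b <- zernike_coefficients(c(0, rnorm(5, sd = 0.2)), pupil_radius = 2.5)
  ab <- zernike_coefficients(unclass(a) + unclass(b), pupil_radius = 2.5)
  pa <- forward_spot_positions(a, ref, 0.25)
  pb <- forward_spot_positions(b, ref, 0.25)
  pab <- forward_spot_positions(ab, ref, 0.25)
  expect_equal(pab$x_mm - ref$x_mm,
               (pa$x_mm - ref$x_mm) + (pb$x_mm - ref$x_mm),
               tolerance = 1e-12)
  expect_equal(pab$y_mm - ref$y_mm,
               (pa$y_mm - ref$y_mm) + (pb$y_mm - ref$y_mm),
               tolerance = 1e-12)
})

test_that("a common tilt leaves the blue-red displacement difference fixed", {
  ref <- reference_pattern(1.5, center_mm = c(4.8, 4.8))
  cb <- zernike_coefficients(c(C4 = 0.75), pupil_radius = 2.5)
  cr <- zernike_coefficients(c(C4 = 0.30), pupil_radius = 2.5)
  tilt <- c(C1 = 0.4, C2 = -0.2)
  cb_t <- zernike_coefficients(unclass(cb) +
    unclass(zernike_coefficients(tilt)), pupil_radius = 2.5)
  cr_t <- zernike_coefficients(unclass(cr) +
    unclass(zernike_coefficients(tilt)), pupil_radius = 2.5)
  d0 <- forward_spot_positions(cb, ref, 0.25)$x_mm -
        forward_spot_positions(cr, ref, 0.25)$x_mm
  d1 <- forward_spot_positions(cb_t, ref, 0.25)$x_mm -
        forward_spot_positions(cr_t, ref, 0.25)$x_mm
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("rendering is deterministic and respects the scene levels", {
  sc <- eye_scene()
  ctr <- sc$pupil_center * sc$pixel_scale
  piv <- reference_pattern(1.5, center_mm = ctr, pixel_scale = sc$pixel_scale)
  i1 <- render_eye_image(sc, piv_pattern = piv, noise_sd = 2, seed = 21)
  i2 <- render_eye_image(sc, piv_pattern = piv, noise_sd = 2, seed = 21)
  expect_identical(i1$pixels, i2$pixels)
  i3 <- render_eye_image(sc, piv_pattern = piv, noise_sd = 2, seed = 22)
  expect_false(identical(i1$pixels, i3$pixels))

  # no spots, no noise: the pupil area stays at pupil_level
  empty <- render_eye_image(sc)
  ny <- nrow(empty$pixels)
  xs <- matrix(rep(0:(ncol(empty$pixels) - 1), each = ny), ny)
  ys <- matrix(rep(0:(ny - 1), times = ncol(empty$pixels)), ny)
  inside <- (xs - sc$pupil_center[1])^2 + (ys - sc$pupil_center[2])^2 <=
    sc$pupil_radius^2
  expect_true(all(empty$pixels[inside] == sc$pupil_level))
})

test_that("rendered spot peaks hit the configured grey levels", {
  sc <- eye_scene()
  ctr <- sc$pupil_center * sc$pixel_scale
  # integer-centred spots so the peak lands exactly on a pixel
  piv <- spot_pattern((sc$pupil_center[1] + c(25, -25, -25, 25)) * sc$pixel_scale,
                      (sc$pupil_center[2] + c(-25, -25, 25, 25)) * sc$pixel_scale,
                      center_mm = ctr, pixel_scale = sc$pixel_scale)
  pi_pat <- purkinjelca:::reflect_pattern(piv, scale = 1.9)
  img <- render_eye_image(sc, pi_pattern = pi_pat, piv_pattern = piv)
  expect_equal(max(img$pixels), sc$pi_peak)
  px <- img$pixels
  spot1 <- px[(sc$pupil_center[2] - 25) + 1 + (-3:3),
              (sc$pupil_center[1] + 25) + 1 + (-3:3)]
  expect_equal(max(spot1), sc$piv_peak)
})

test_that("rendered subpixel spot centres survive intensity-weighted centroiding", {
  sc <- eye_scene()
  ctr <- sc$pupil_center * sc$pixel_scale
  tx <- sc$pupil_center[1] + c(12.3, -11.7, -12.4, 11.6)
  ty <- sc$pupil_center[2] + c(-12.6, -12.2, 12.7, 12.1)
  piv <- spot_pattern(tx * sc$pixel_scale, ty * sc$pixel_scale,
                      center_mm = ctr, pixel_scale = sc$pixel_scale)
  img <- render_eye_image(sc, piv_pattern = piv)
  px <- img$pixels; ny <- nrow(px)
  for (k in 1:4) {
    idx <- which(px >= 30 & px <= 100)
    x <- (idx - 1) %/% ny; y <- (idx - 1) %% ny
    near <- abs(x - tx[k]) < 9 & abs(y - ty[k]) < 9
    w <- px[idx[near]] - sc$pupil_level
    cx <- sum(w * x[near]) / sum(w); cy <- sum(w * y[near]) / sum(w)
    expect_lt(sqrt((cx - tx[k])^2 + (cy - ty[k])^2), 0.05)
  }
})

test_that("out-of-bounds spots are rejected by the renderer", {
  sc <- eye_scene()
  far <- spot_pattern(c(50, -50, -50, 50) + 500, c(-50, -50, 50, 50) + 500,
                      center_mm = c(500, 500), pixel_scale = sc$pixel_scale)
  expect_error(render_eye_image(sc, piv_pattern = far), "outside image bounds")
  on_bg <- reference_pattern(sc$iris_radius * sc$pixel_scale * 1.2,
                             center_mm = sc$pupil_center * sc$pixel_scale,
                             pixel_scale = sc$pixel_scale)
  expect_error(render_eye_image(sc, piv_pattern = on_bg), "iris disc")
})

test_that("image pairs collapse when both bands share one wavefront", {
  cfg <- test_config()
  sc <- eye_scene()
  ctr <- sc$pupil_center * sc$pixel_scale
  ref <- reference_pattern(cfg$ref_rho_mm, center_mm = ctr,
                           pixel_scale = sc$pixel_scale)
  cc <- zernike_coefficients(c(C4 = 0.4), pupil_radius = cfg$pupil_radius_mm)
  truth <- ground_truth(cc, cc, cfg$calibration_k, ref)
  expect_equal(truth$true_lca, 0)
  pair <- make_image_pair(truth, sc, noise_sd = 0, seed = 1)
  expect_identical(pair$blue$pixels, pair$red$pixels)
  # determinism of the full pair
  pair2 <- make_image_pair(truth, sc, noise_sd = 0, seed = 1)
  expect_identical(pair$blue$pixels, pair2$blue$pixels)
})
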