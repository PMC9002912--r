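#' Synthetic anterior-segment scene description
#'
#' Geometry and intensity levels for a rendered eye image: a dark pupil disc
#' inside a brighter iris disc on a mid-grey background, with a bright
#' four-spot first Purkinje (PI) pattern and a dim inverted fourth Purkinje
#' (PIV) pattern. Intensity bands follow the detection contract: PI peaks in
#' 200--255, PIV peaks at or below 100.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param pupil_center pupil/iris centre in 0-based pixel coordinates.
#' @param pupil_radius,iris_radius disc radii in pixels
#'   (`0 < pupil_radius < iris_radius < min(image_size)/2`).
#' @param pupil_level,iris_level,background_level grey levels 0--255 with
#'   `pupil_level < iris_level`.
#' @param pi_peak PI spot peak grey level, in 200--255.
#' @param piv_peak PIV spot peak grey level, at most 100.
#' @param spot_sigma Gaussian spot width in pixels.
#' @param pi_shape radial profile exponent for PI spots
#'   (`exp(-(r/sigma)^pi_shape)`); the default 4 gives the compact,
#'   near-saturated profile of a specular corneal reflection, whose skirt
#'   does not leak into the PIV intensity band. PIV spots always use the
#'   ordinary Gaussian profile.
#' @param pixel_scale mm per pixel.
#' @return object of class `eye_scene` (a validated list).
#' @export
eye_scene <- function(image_size = c(192, 192), pupil_center = c(96, 96),
                      pupil_radius = 50, iris_radius = 72,
                      pupil_level = 20, iris_level = 150,
                      background_level = 60,
                      pi_peak = 240, piv_peak = 90,
                      spot_sigma = 3.5, pi_shape = 4,
                      pixel_scale = 0.05) {
  sc <- list(image_size = as.numeric(image_size),
             pupil_center = as.numeric(pupil_center),
             pupil_radius = pupil_radius, iris_radius = iris_radius,
             pupil_level = pupil_level, iris_level = iris_level,
             background_level = background_level,
             pi_peak = pi_peak, piv_peak = piv_peak,
             spot_sigma = spot_sigma, pi_shape = pi_shape,
             pixel_scale = pixel_scale)
  if (!(sc$pupil_radius > 0 && sc$pupil_radius < sc$iris_radius &&
        sc$iris_radius < min(sc$image_size) / 2))
    stop("need 0 < pupil_radius < iris_radius < min(image_size)/2",
         call. = FALSE)
  if (!(sc$pi_peak >= 200 && sc$pi_peak <= 255))
    stop("pi_peak must lie in [200, 255]", call. = FALSE)
  if (sc$piv_peak > 100 || sc$piv_peak < 0)
    stop("piv_peak must lie in [0, 100]", call. = FALSE)
  if (sc$pupil_level >= sc$iris_level)
    stop("pupil_level must be below iris_level", call. = FALSE)
  if (sc$spot_sigma <= 0 || sc$pixel_scale <= 0)
    stop("spot_sigma and pixel_scale must be positive", call. = FALSE)
  structure(sc, class = "eye_scene")
}

#' 8-bit grayscale eye image
#'
#' @param pixels integer matrix of grey levels 0--255, rows = image rows (y),
#'   columns = x.
#' @param pixel_scale mm per pixel.
#' @return object of class `eye_image`.
#' @export
eye_image <- function(pixels, pixel_scale) {
  stopifnot(is.matrix(pixels), pixel_scale > 0)
  if (any(pixels < 0 | pixels > 255))
    stop("pixel values outside [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, pixel_scale = pixel_scale),
            class = "eye_image")
}

#' @export
print.eye_image <- function(x, ...) {
  cat("eye_image:", ncol(x$pixels), "x", nrow(x$pixels), "px,",
      x$pixel_scale, "mm/px, grey range",
      min(x$pixels), "-", max(x$pixels), "\n")
  invisible(x)
}

#' Displace a reference spot pattern by a known wavefront
#'
#' Hartmann-test forward model: each reference spot moves by the local
#' wavefront gradient, \eqn{\Delta p = k \,\nabla W(u, v)}, where \eqn{(u,v)}
#' is the reference position in pupil-normalized coordinates, \eqn{W} is in
#' micrometres, and the calibration constant `calibration_k` converts a unit
#' of slope into millimetres of centroid displacement on the sensor.
#'
#' @param coeffs [zernike_coefficients] with a finite `pupil_radius`
#'   (mm) used to normalize coordinates.
#' @param reference a four-point [spot_pattern] (the zero-aberration grid).
#' @param calibration_k mm of displacement per unit slope (positive).
#' @param pixel_scale mm per pixel, stored on the output pattern.
#' @return the displaced [spot_pattern].
#' @export
forward_spot_positions <- function(coeffs, reference, calibration_k,
                                   pixel_scale = attr(reference, "pixel_scale")) {
  if (!inherits(coeffs, "zernike_coefficients"))
    coeffs <- zernike_coefficients(coeffs)
  if (any(!is.finite(unclass(coeffs))))
    stop("non-finite coefficients", call. = FALSE)
  if (!is.finite(calibration_k) || calibration_k <= 0)
    stop("calibration_k must be positive", call. = FALSE)
  R <- attr(coeffs, "pupil_radius")
  if (!is.finite(R) || R <= 0)
    stop("coefficients need a positive pupil_radius (mm)", call. = FALSE)
  ctr <- attr(reference, "center_mm")
  u <- (reference$x_mm - ctr[1]) / R
  v <- (reference$y_mm - ctr[2]) / R
  if (any(u^2 + v^2 > 1 + 1e-9))
    stop("reference points outside the unit pupil disc", call. = FALSE)
  g <- wavefront_slopes(coeffs, u, v)
  spot_pattern(reference$x_mm + calibration_k * g$dx,
               reference$y_mm + calibration_k * g$dy,
               labels = reference$label, band = attr(reference, "band"),
               center_mm = ctr, pixel_scale = pixel_scale)
}

#' Ground truth for a simulated two-band acquisition
#'
#' Bundles the per-band injected coefficient vectors, the calibration
#' constant, the ideal reference pattern, and the LCA in diopters implied by
#' the injected defocus difference
#' (\eqn{D = 4\sqrt{3}\,(C_{b4} - C_{r4})/R^2}).
#'
#' @param coeffs_blue,coeffs_red [zernike_coefficients] per band; both must
#'   carry the same positive pupil radius.
#' @param calibration_k mm per unit slope.
#' @param reference a four-point [spot_pattern].
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(coeffs_blue, coeffs_red, calibration_k, reference) {
  Rb <- attr(coeffs_blue, "pupil_radius"); Rr <- attr(coeffs_red, "pupil_radius")
  if (!isTRUE(all.equal(Rb, Rr)) || !is.finite(Rb) || Rb <= 0)
    stop("both bands must share one positive pupil radius", call. = FALSE)
  if (!is.finite(calibration_k) || calibration_k <= 0)
    stop("calibration_k must be positive", call. = FALSE)
  structure(list(coeffs_blue = coeffs_blue, coeffs_red = coeffs_red,
                 calibration_k = calibration_k,
                 reference_pattern = reference,
                 pupil_radius = Rb,
                 true_lca = lca_from_defocus(coeffs_blue[["C4"]],
                                             coeffs_red[["C4"]], Rb)),
            class = "ground_truth")
}

#' Render a synthetic eye image
#'
#' Paints the background, iris disc, pupil disc, then the PI and PIV spot
#' patterns, adds optional Gaussian noise, clips to \[0, 255\] and rounds to
#' 8-bit levels. Spots are painted as `I = I + (peak - I) * g(r)` so the
#' profile peaks exactly at `peak` over any local background; `g` is a
#' Gaussian for PIV and a compact super-Gaussian (exponent `pi_shape`) for
#' PI. Rendering is deterministic given the seed.
#'
#' @param scene an [eye_scene].
#' @param pi_pattern,piv_pattern [spot_pattern]s in mm, or `NULL` to omit.
#' @param noise_sd additive Gaussian noise SD in grey levels.
#' @param seed integer seed fixing the noise realization (required when
#'   `noise_sd > 0`).
#' @return an [eye_image].
#' @export
render_eye_image <- function(scene, pi_pattern = NULL, piv_pattern = NULL,
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(scene, "eye_scene"))
  nx <- scene$image_size[1]; ny <- scene$image_size[2]
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)  # x per pixel (0-based)
  ys <- matrix(rep(0:(ny - 1), times = nx), ny, nx) # y per pixel
  r2 <- (xs - scene$pupil_center[1])^2 + (ys - scene$pupil_center[2])^2
  img <- matrix(scene$background_level, ny, nx)
  img[r2 <= scene$iris_radius^2] <- scene$iris_level
  img[r2 <= scene$pupil_radius^2] <- scene$pupil_level

  paint <- function(img, pattern, peak, shape) {
    pts <- pattern_px(pattern, scene$pixel_scale)
    if (any(pts[, "x"] < 0 | pts[, "x"] > nx - 1 |
            pts[, "y"] < 0 | pts[, "y"] > ny - 1))
      stop("spot outside image bounds", call. = FALSE)
    d <- sqrt((pts[, "x"] - scene$pupil_center[1])^2 +
              (pts[, "y"] - scene$pupil_center[2])^2)
    if (any(d > scene$iris_radius))
      stop("spot outside the iris disc", call. = FALSE)
    for (k in seq_len(nrow(pts))) {
      rr <- sqrt((xs - pts[k, "x"])^2 + (ys - pts[k, "y"])^2)
      g <- exp(-(rr / scene$spot_sigma)^shape / ifelse(shape == 2, 2, 1))
      img <- img + (peak - img) * g
    }
    img
  }
  if (!is.null(pi_pattern))
    img <- paint(img, pi_pattern, scene$pi_peak, scene$pi_shape)
  if (!is.null(piv_pattern))
    img <- paint(img, piv_pattern, scene$piv_peak, 2)

  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    img <- img + local_seed(seed, stats::rnorm(length(img), sd = noise_sd))
  }
  eye_image(round(pmin(pmax(img, 0), 255)), scene$pixel_scale)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a two-band acquisition
#'
#' Renders the blue-band and red-band images of one synthetic eye: the PIV
#' pattern of each band is the reference pattern displaced by that band's
#' injected wavefront ([forward_spot_positions]); the bright PI pattern is
#' the reference reflected through the pupil centre (PIV is inverted with
#' respect to PI) and radially scaled by `pi_offset_scale`.
#'
#' @param truth a [ground_truth].
#' @param scene an [eye_scene].
#' @param noise_sd grey-level noise SD (0 for noiseless).
#' @param seed integer; blue uses `seed`, red uses `seed + 1`.
#' @param pi_offset_scale radial scale of the PI pattern relative to the
#'   reflected reference. The square array is point-symmetric, so the
#'   reflection alone would land the PI spots back on the PIV quadrants;
#'   the default 1.9 places them on the iris annulus, where the bright-spot
#'   skirt (rising from the iris grey level) cannot enter the PIV intensity
#'   band or bias the PIV centroids.
#' @return list with elements `blue`, `red` ([eye_image]s) and `truth`
#'   (the input [ground_truth], echoed for scoring).
#' @export
make_image_pair <- function(truth, scene, noise_sd = 0, seed = 1L,
                            pi_offset_scale = 1.9) {
  stopifnot(inherits(truth, "ground_truth"), inherits(scene, "eye_scene"))
  ref <- truth$reference_pattern
  ctr <- attr(ref, "center_mm")
  d <- sqrt((ref$x_mm - ctr[1])^2 + (ref$y_mm - ctr[2])^2)
  if (any(d / scene$pixel_scale > scene$pupil_radius))
    stop("reference pattern outside the pupil", call. = FALSE)
  pi_pat <- reflect_pattern(ref, scale = pi_offset_scale)
  piv_b <- forward_spot_positions(truth$coeffs_blue, ref, truth$calibration_k,
                                  scene$pixel_scale)
  piv_r <- forward_spot_positions(truth$coeffs_red, ref, truth$calibration_k,
                                  scene$pixel_scale)
  list(blue = render_eye_image(scene, pi_pat, piv_b, noise_sd, seed),
       red = render_eye_image(scene, pi_pat, piv_r, noise_sd,
                              if (is.null(seed)) NULL else seed + 1L),
       truth = truth)
}
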