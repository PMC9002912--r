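#' Pipeline configuration
#'
#' Collects every physical scale, threshold and radius range the measurement
#' pipeline uses. Defaults match the package's synthetic scene
#' ([eye_scene]): 0.05 mm/px, a 2.5 mm pupil, a 1.5 mm LED array radius.
#'
#' @param pixel_scale mm per pixel.
#' @param calibration_k mm of centroid displacement per unit wavefront slope.
#' @param pupil_radius_mm pupil radius R in mm (used to normalize pupil
#'   coordinates and convert defocus to diopters).
#' @param ref_rho_mm ideal LED-array radius in mm (pupil centre to each
#'   reference spot).
#' @param iris_radius_range `c(min, max)` iris Hough radii, px.
#' @param spot_radius_range `c(min, max)` PIV-spot Hough radii, px.
#' @param piv_band inclusive PIV grey-level band `c(low, high)`; the default
#'   lower bound 30 excludes the dark-pupil background that shares the
#'   nominal 0--100 PIV range.
#' @param min_area minimum connected-component area (px) kept by noise
#'   removal.
#' @param edge_threshold Sobel gradient threshold for the iris Hough pass.
#' @param spot_min_score minimum accumulator votes for a PIV spot circle.
#' @param band_wavelengths list with `blue` and `red` nm intervals.
#' @param reference_at `"center"` (default) or `"edges"`: which
#'   representative wavelengths of the two bands the dispersion-model
#'   reference LCA is evaluated between.
#' @return object of class `lca_config` (validated list).
#' @export
lca_config <- function(pixel_scale = 0.05, calibration_k = 0.25,
                       pupil_radius_mm = 2.5, ref_rho_mm = 1.5,
                       iris_radius_range = c(60, 84),
                       spot_radius_range = c(3, 10),
                       piv_band = c(30, 100), min_area = 40,
                       edge_threshold = 150, spot_min_score = 6,
                       band_wavelengths = list(blue = c(440, 480),
                                               red = c(580, 640)),
                       reference_at = c("center", "edges")) {
  cfg <- list(pixel_scale = pixel_scale, calibration_k = calibration_k,
              pupil_radius_mm = pupil_radius_mm, ref_rho_mm = ref_rho_mm,
              iris_radius_range = as.numeric(iris_radius_range),
              spot_radius_range = as.numeric(spot_radius_range),
              piv_band = as.numeric(piv_band), min_area = min_area,
              edge_threshold = edge_threshold,
              spot_min_score = spot_min_score,
              band_wavelengths = band_wavelengths,
              reference_at = match.arg(reference_at))
  with(cfg, {
    if (any(c(pixel_scale, calibration_k, pupil_radius_mm, ref_rho_mm) <= 0))
      stop("physical scales must be positive", call. = FALSE)
    if (piv_band[1] > piv_band[2] || piv_band[1] < 0 || piv_band[2] > 255)
      stop("piv_band must be an interval within [0, 255]", call. = FALSE)
    if (ref_rho_mm >= pupil_radius_mm)
      stop("reference array must lie inside the pupil", call. = FALSE)
  })
  structure(cfg, class = "lca_config")
}

# Representative wavelengths (nm) of the two bands for the reference model.
band_reference_wavelengths <- function(config) {
  bw <- config$band_wavelengths
  if (config$reference_at == "center")
    c(blue = mean(bw$blue), red = mean(bw$red))
  else
    c(blue = bw$blue[1], red = bw$red[2])
}

#' Simulate one synthetic subject
#'
#' Builds the injected per-band coefficient vectors for a target LCA and
#' renders the two-band image pair. The red band carries the baseline
#' aberrations (`coeffs_red`); the blue band adds the defocus difference
#' \eqn{\Delta C_4 = D\,R^2/(4\sqrt3)} implied by `lca_d`.
#'
#' @param lca_d target LCA in diopters.
#' @param config an [lca_config].
#' @param scene an [eye_scene]; its `pixel_scale` should match the config.
#' @param coeffs_red baseline red-band coefficient values C0..C5 (um).
#' @param noise_sd grey-level noise SD passed to the renderer.
#' @param seed integer seed (noise and jitter).
#' @param centroid_jitter_px SD (px) of Gaussian jitter added to the true
#'   spot positions before rendering, emulating centroid-level measurement
#'   noise.
#' @return list with `blue`, `red` ([eye_image]s) and `truth`
#'   ([ground_truth]).
#' @export
simulate_subject <- function(lca_d, config = lca_config(),
                             scene = eye_scene(pixel_scale = config$pixel_scale),
                             coeffs_red = c(C1 = 0.05, C2 = -0.04, C3 = 0.02,
                                            C4 = 0.30, C5 = -0.03),
                             noise_sd = 0, seed = 1L,
                             centroid_jitter_px = 0) {
  R <- config$pupil_radius_mm
  cr <- zernike_coefficients(coeffs_red, pupil_radius = R)
  cb_vals <- unclass(cr)
  cb_vals[["C4"]] <- cb_vals[["C4"]] + lca_d * R^2 / (4 * sqrt(3))
  cb <- zernike_coefficients(cb_vals, pupil_radius = R)
  ctr_mm <- scene$pupil_center * scene$pixel_scale
  ref <- reference_pattern(config$ref_rho_mm, center_mm = ctr_mm,
                           pixel_scale = scene$pixel_scale)
  truth <- ground_truth(cb, cr, config$calibration_k, ref)
  if (centroid_jitter_px > 0) {
    jitter_mm <- local_seed(seed + 7L,
                            stats::rnorm(16, sd = centroid_jitter_px *
                                               scene$pixel_scale))
    piv_b <- forward_spot_positions(cb, ref, config$calibration_k,
                                    scene$pixel_scale)
    piv_r <- forward_spot_positions(cr, ref, config$calibration_k,
                                    scene$pixel_scale)
    piv_b$x_mm <- piv_b$x_mm + jitter_mm[1:4]
    piv_b$y_mm <- piv_b$y_mm + jitter_mm[5:8]
    piv_r$x_mm <- piv_r$x_mm + jitter_mm[9:12]
    piv_r$y_mm <- piv_r$y_mm + jitter_mm[13:16]
    pi_pat <- reflect_pattern(ref, scale = 1.9)
    return(list(blue = render_eye_image(scene, pi_pat, piv_b, noise_sd, seed),
                red = render_eye_image(scene, pi_pat, piv_r, noise_sd,
                                       seed + 1L),
                truth = truth))
  }
  make_image_pair(truth, scene, noise_sd = noise_sd, seed = seed)
}

#' Measure LCA from a two-band image pair
#'
#' Runs the full objective pipeline: PIV detection on each band, the
#' differential Hartmann slope field (blue pattern against the red pattern
#' as reference, evaluated on the ideal array geometry), the closed-form
#' modal fit, and the defocus-to-diopter conversion. Per-band fits against
#' the ideal reference grid are also computed; by linearity of the least
#' squares their defocus difference equals the differential fit's defocus,
#' and the residual gap between the two routes is reported as
#' `linearity_gap`.
#'
#' @param blue,red [eye_image]s or paths to 8-bit grayscale PNG/TIFF files.
#' @param config an [lca_config].
#' @param weighting centroid weighting passed to [detect_piv_spots].
#' @return object of class `lca_measurement`: a list with `lca` (diopters),
#'   `c4_blue`, `c4_red`, `c4_diff` (um), `fit_diff`, `fit_blue`, `fit_red`
#'   ([fit_zernike] objects), `patterns`, `pupil_radius`, `lca_reference`
#'   (dispersion-model value between the configured band wavelengths),
#'   `linearity_gap` and `config`.
#' @export
measure_lca <- function(blue, red, config = lca_config(),
                        weighting = c("none", "intensity")) {
  weighting <- match.arg(weighting)
  blue <- as_eye_image(blue, config$pixel_scale)
  red <- as_eye_image(red, config$pixel_scale)
  pb <- tryCatch(detect_piv_spots(blue, config, band = "blue", weighting),
                 error = function(e)
                   stop("blue band: ", conditionMessage(e), call. = FALSE))
  pr <- tryCatch(detect_piv_spots(red, config, band = "red", weighting),
                 error = function(e)
                   stop("red band: ", conditionMessage(e), call. = FALSE))

  R <- config$pupil_radius_mm
  rho <- config$ref_rho_mm / R
  ctr <- (attr(pb, "center_mm") + attr(pr, "center_mm")) / 2
  attr(pb, "center_mm") <- ctr
  attr(pr, "center_mm") <- ctr
  ref <- reference_pattern(config$ref_rho_mm, center_mm = ctr,
                           pixel_scale = config$pixel_scale)

  sf_diff <- slopes_from_patterns(pb, pr, config$calibration_k, R, rho = rho)
  fit_diff <- fit_zernike(sf_diff, pupil_radius = R)
  fit_blue <- fit_zernike(slopes_from_patterns(pb, ref, config$calibration_k,
                                               R, rho = rho),
                          pupil_radius = R)
  fit_red <- fit_zernike(slopes_from_patterns(pr, ref, config$calibration_k,
                                              R, rho = rho),
                         pupil_radius = R)
  c4d <- coef(fit_diff)[["C4"]]
  c4b <- coef(fit_blue)[["C4"]]
  c4r <- coef(fit_red)[["C4"]]
  wl <- band_reference_wavelengths(config)
  structure(list(lca = lca_from_defocus(c4d, 0, R),
                 c4_blue = c4b, c4_red = c4r, c4_diff = c4d,
                 fit_diff = fit_diff, fit_blue = fit_blue, fit_red = fit_red,
                 patterns = list(blue = pb, red = pr, reference = ref),
                 pupil_radius = R,
                 lca_reference = lca_reference(wl[["blue"]], wl[["red"]]),
                 reference_wavelengths = wl,
                 linearity_gap = abs((c4b - c4r) - c4d),
                 config = config),
            class = "lca_measurement")
}

#' @export
print.lca_measurement <- function(x, digits = 4, ...) {
  cat("Objective LCA measurement (blue vs red pulse band)\n")
  cat("  C4 blue: ", round(x$c4_blue, digits), " um,  C4 red: ",
      round(x$c4_red, digits), " um,  pupil R: ", x$pupil_radius, " mm\n",
      sep = "")
  cat("  LCA: ", round(x$lca, digits), " D\n", sep = "")
  cat("  dispersion-model reference (",
      x$reference_wavelengths[["blue"]], "-",
      x$reference_wavelengths[["red"]], " nm): ",
      round(x$lca_reference, digits), " D\n", sep = "")
  invisible(x)
}

#' @export
summary.lca_measurement <- function(object, ...) {
  print(object)
  cat("\nDifferential fit (blue - red):\n")
  print(object$fit_diff)
  cat("\nLinearity gap |(C4b - C4r) - C4diff|:",
      signif(object$linearity_gap, 3), "um\n")
  invisible(object)
}

#' Aggregate LCA measurements across subjects
#'
#' Arithmetic mean of the per-subject LCA values (the "Average" row of a
#' subject table), with optional repeatability SDs per band when repeated
#' acquisitions are supplied.
#'
#' @param results non-empty list of [measure_lca] results.
#' @param repeats_blue,repeats_red optional lists of repeated
#'   [spot_pattern]s for the repeatability statistic.
#' @return object of class `lca_report`: list with `per_subject` (data.frame
#'   of LCA and defocus per result), `mean_lca`, `lca_reference`, and
#'   `repeatability_mm` (named vector, possibly empty).
#' @export
lca_report <- function(results, repeats_blue = NULL, repeats_red = NULL) {
  if (length(results) < 1L)
    stop("need at least one measurement", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "lca_measurement")))
  per <- data.frame(subject = seq_along(results),
                    lca_d = vapply(results, `[[`, 0, "lca"),
                    c4_blue = vapply(results, `[[`, 0, "c4_blue"),
                    c4_red = vapply(results, `[[`, 0, "c4_red"))
  rep_sd <- c(if (!is.null(repeats_blue)) c(blue = repeatability_sd(repeats_blue)),
              if (!is.null(repeats_red)) c(red = repeatability_sd(repeats_red)))
  structure(list(per_subject = per, mean_lca = mean(per$lca_d),
                 lca_reference = results[[1]]$lca_reference,
                 repeatability_mm = rep_sd),
            class = "lca_report")
}

#' @export
print.lca_report <- function(x, digits = 4, ...) {
  cat("LCA report over", nrow(x$per_subject), "subject(s)\n")
  print(transform(x$per_subject, lca_d = round(lca_d, digits),
                  c4_blue = round(c4_blue, digits),
                  c4_red = round(c4_red, digits)))
  cat("Mean LCA:", round(x$mean_lca, digits), "D",
      "(dispersion-model reference:", round(x$lca_reference, digits), "D)\n")
  if (length(x$repeatability_mm))
    cat("Repeatability SD (mm):",
        paste(names(x$repeatability_mm),
              round(x$repeatability_mm, digits), collapse = ", "), "\n")
  invisible(x)
}
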