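#' Read an 8-bit grayscale eye image
#'
#' Reads PNG or TIFF (by file extension), converts to grey levels 0--255.
#' RGB(A) input is reduced to its luminance-equivalent first channel mean.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_scale mm per pixel to attach to the image.
#' @return an [eye_image].
#' @export
read_eye_image <- function(path, pixel_scale) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3])],
                                           c(1, 2), mean)
  eye_image(round(arr * 255), pixel_scale)
}

#' Write an eye image as 8-bit grayscale PNG or TIFF
#'
#' @param image an [eye_image].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_eye_image <- function(image, path) {
  stopifnot(inherits(image, "eye_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(arr, path),
         tif = ,
         tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Ground-truth JSON sidecar
#'
#' Serializes a [ground_truth] (coefficients in um, pupil radius in mm,
#' calibration in mm per unit slope, reference pattern in mm) so a simulated
#' acquisition can be scored later.
#'
#' @param truth a [ground_truth].
#' @param path output `.json` path.
#' @param seed optional integer recorded alongside.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  ref <- truth$reference_pattern
  obj <- list(coeffs_blue_um = as.list(unclass(truth$coeffs_blue)),
              coeffs_red_um = as.list(unclass(truth$coeffs_red)),
              pupil_radius_mm = truth$pupil_radius,
              calibration_k_mm = truth$calibration_k,
              reference_pattern_mm = list(label = ref$label,
                                          x_mm = ref$x_mm, y_mm = ref$y_mm,
                                          center_mm = attr(ref, "center_mm"),
                                          pixel_scale = attr(ref, "pixel_scale")),
              true_lca_d = truth$true_lca,
              seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @return `read_ground_truth`: the [ground_truth] rebuilt from the sidecar.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- obj$pupil_radius_mm
  rp <- obj$reference_pattern_mm
  ref <- spot_pattern(rp$x_mm, rp$y_mm, labels = rp$label,
                      center_mm = rp$center_mm,
                      pixel_scale = if (is.null(rp$pixel_scale)) NA_real_
                                    else rp$pixel_scale)
  ground_truth(zernike_coefficients(unlist(obj$coeffs_blue_um), R),
               zernike_coefficients(unlist(obj$coeffs_red_um), R),
               obj$calibration_k_mm, ref)
}

#' Export detected centroids as CSV
#'
#' One row per spot: band, label, pixel coordinates and mm coordinates.
#'
#' @param patterns list of [spot_pattern]s (e.g. one per band).
#' @param path output `.csv` path.
#' @return the written data.frame, invisibly.
#' @export
write_centroids_csv <- function(patterns, path) {
  rows <- lapply(patterns, function(p) {
    px <- pattern_px(p)
    data.frame(band = attr(p, "band"), label = p$label,
               x_px = px[, "x"], y_px = px[, "y"],
               x_mm = p$x_mm, y_mm = p$y_mm)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' JSON measurement report
#'
#' Writes per-band defocus, pupil radius, measured LCA, the dispersion-model
#' reference at the configured wavelengths, and (optionally) repeatability.
#'
#' @param measurement an [measure_lca] result, or an [lca_report].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_lca_json <- function(measurement, path) {
  obj <- if (inherits(measurement, "lca_measurement")) {
    list(c4_blue_um = measurement$c4_blue, c4_red_um = measurement$c4_red,
         c4_diff_um = measurement$c4_diff,
         pupil_radius_mm = measurement$pupil_radius,
         lca_d = measurement$lca,
         lca_reference_d = measurement$lca_reference,
         reference_wavelengths_nm = as.list(measurement$reference_wavelengths),
         linearity_gap_um = measurement$linearity_gap)
  } else if (inherits(measurement, "lca_report")) {
    list(per_subject = measurement$per_subject,
         mean_lca_d = measurement$mean_lca,
         lca_reference_d = measurement$lca_reference,
         repeatability_mm = as.list(measurement$repeatability_mm))
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

# Coerce a path or eye_image to eye_image.
as_eye_image <- function(x, pixel_scale) {
  if (inherits(x, "eye_image")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_eye_image(x, pixel_scale))
  stop("expected an eye_image or an image file path", call. = FALSE)
}
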