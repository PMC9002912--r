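#' Four-spot Purkinje pattern
#'
#' A labelled set of four spot centres in millimetre image coordinates
#' (x rightward, y downward, origin at the top-left pixel centre; mm = pixel
#' coordinate times the pixel scale). Labels follow a fixed quadrant
#' convention relative to the pupil centre: `a` = (+x, -y) (upper right in
#' image orientation), `b` = upper left, `c` = lower left, `d` = lower right.
#'
#' @param x_mm,y_mm numeric vectors of length 4, spot centres in mm.
#' @param labels character vector of labels; defaults to a,b,c,d in order.
#' @param band spectral band tag, `"blue"`, `"red"` or `NA`.
#' @param center_mm pupil centre `c(x, y)` in mm.
#' @param pixel_scale mm per pixel (kept so positions can be mapped back to
#'   pixels); may be `NA`.
#' @return object of class `spot_pattern`: a data.frame with columns
#'   `label`, `x_mm`, `y_mm` and attributes `band`, `center_mm`, `pixel_scale`.
#' @export
spot_pattern <- function(x_mm, y_mm, labels = c("a", "b", "c", "d"),
                         band = NA_character_, center_mm = c(0, 0),
                         pixel_scale = NA_real_) {
  stopifnot(length(x_mm) == 4L, length(y_mm) == 4L, length(labels) == 4L)
  if (any(!is.finite(x_mm)) || any(!is.finite(y_mm)))
    stop("non-finite spot coordinates", call. = FALSE)
  if (!setequal(labels, c("a", "b", "c", "d")))
    stop("labels must be a permutation of a, b, c, d", call. = FALSE)
  ord <- order(match(labels, c("a", "b", "c", "d")))
  df <- data.frame(label = labels[ord], x_mm = x_mm[ord], y_mm = y_mm[ord],
                   stringsAsFactors = FALSE)
  structure(df, band = band, center_mm = as.numeric(center_mm),
            pixel_scale = pixel_scale,
            class = c("spot_pattern", "data.frame"))
}

#' @export
print.spot_pattern <- function(x, ...) {
  cat("Spot pattern, band:", attr(x, "band"),
      " centre (mm): [", paste(round(attr(x, "center_mm"), 4), collapse = ", "),
      "]\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Assign quadrant labels a--d to four spot centres
#'
#' Deterministic labelling relative to the pupil centre, in image coordinates
#' (y downward): `a` is the (+x, -y) quadrant (upper right), `b` upper left,
#' `c` lower left, `d` lower right. Fails if any point lies on a quadrant
#' boundary or two points share a quadrant.
#'
#' @param x,y coordinates of exactly four points (any consistent unit).
#' @param center length-2 pupil centre in the same unit.
#' @return character vector of labels parallel to `x`.
#' @export
label_quadrants <- function(x, y, center) {
  if (length(x) != 4L || length(y) != 4L)
    stop("need exactly four points, got ", length(x), call. = FALSE)
  dx <- x - center[1]; dy <- y - center[2]
  if (any(dx == 0 | dy == 0))
    stop("point on a quadrant boundary; cannot label", call. = FALSE)
  lab <- ifelse(dx > 0 & dy < 0, "a",
         ifelse(dx < 0 & dy < 0, "b",
         ifelse(dx < 0 & dy > 0, "c", "d")))
  if (anyDuplicated(lab))
    stop("quadrant collision: two spots in one quadrant", call. = FALSE)
  lab
}

#' Ideal quadrangular reference pattern
#'
#' The reference (zero-aberration) spot positions of the square LED array:
#' four points at 45, 135, 225 and 315 degrees on a circle of radius
#' `rho_mm` around the pupil centre, labelled by quadrant.
#'
#' @param rho_mm array radius in mm (distance pupil centre to each spot).
#' @param center_mm pupil centre in mm.
#' @param band optional band tag.
#' @param pixel_scale optional mm per pixel.
#' @return a [spot_pattern].
#' @export
reference_pattern <- function(rho_mm, center_mm = c(0, 0),
                              band = NA_character_, pixel_scale = NA_real_) {
  stopifnot(rho_mm > 0)
  s <- rho_mm / sqrt(2)
  # a=(+x,-y), b=(-x,-y), c=(-x,+y), d=(+x,+y)
  sx <- c(1, -1, -1, 1); sy <- c(-1, -1, 1, 1)
  spot_pattern(center_mm[1] + sx * s, center_mm[2] + sy * s,
               band = band, center_mm = center_mm, pixel_scale = pixel_scale)
}

# Reflect a pattern through the pupil centre (PI is upright where PIV is
# inverted, so the PI pattern is the point reflection of the PIV reference),
# optionally scaled radially about the centre.
reflect_pattern <- function(pattern, scale = 1) {
  ctr <- attr(pattern, "center_mm")
  x <- ctr[1] - scale * (pattern$x_mm - ctr[1])
  y <- ctr[2] - scale * (pattern$y_mm - ctr[2])
  lab <- label_quadrants(x, y, ctr)
  spot_pattern(x, y, labels = lab, band = attr(pattern, "band"),
               center_mm = ctr, pixel_scale = attr(pattern, "pixel_scale"))
}

# Pattern coordinates in (0-based, possibly subpixel) pixels.
pattern_px <- function(pattern, pixel_scale = attr(pattern, "pixel_scale")) {
  if (!is.finite(pixel_scale))
    stop("pixel_scale unknown for this pattern", call. = FALSE)
  cbind(x = pattern$x_mm / pixel_scale, y = pattern$y_mm / pixel_scale)
}
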