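#' Longitudinal chromatic aberration from per-band defocus
#'
#' Converts the blue/red defocus coefficients to LCA in diopters,
#' \deqn{D = D_b - D_r = \frac{4\sqrt{3}\,(C_{b4} - C_{r4})}{R^2},}
#' with the defocus coefficients in micrometres and the pupil radius R in
#' millimetres (the standard defocus-equivalent relation for a Zernike
#' expansion on pupil-normalized coordinates). The sign is carried: blue
#' defocus minus red defocus.
#'
#' @param cb4 blue-band defocus coefficient C4, micrometres.
#' @param cr4 red-band defocus coefficient C4, micrometres.
#' @param pupil_radius pupil radius R in millimetres, positive.
#' @return LCA in diopters.
#' @examples
#' lca_from_defocus(0.66, 0.30, 2.5)  # 0.3991 D
#' @export
lca_from_defocus <- function(cb4, cr4, pupil_radius) {
  if (!is.finite(pupil_radius) || pupil_radius <= 0)
    stop("pupil_radius must be positive", call. = FALSE)
  if (any(!is.finite(c(cb4, cr4))))
    stop("non-finite defocus coefficients", call. = FALSE)
  4 * sqrt(3) * (cb4 - cr4) / pupil_radius^2
}

# Constants of the Atchison chromatic-difference-of-refraction model
# (diopters as a polynomial in 1/lambda^2, lambda in nm).
atchison_constants <- c(a0 = 1.60911, a2 = 6.70941e5,
                        a4 = 5.55334e10, a6 = 5.59998e15)

#' Chromatic difference of refraction (Atchison dispersion model)
#'
#' Evaluates
#' \deqn{R_x(\lambda) = 1.60911 - \frac{6.70941\times10^{5}}{\lambda^2}
#'   + \frac{5.55334\times10^{10}}{\lambda^4}
#'   - \frac{5.59998\times10^{15}}{\lambda^6}}
#' with \eqn{\lambda} in nanometres, giving the eye's refractive error in
#' diopters relative to the model's reference wavelength (near the 589 nm
#' sodium line, where \eqn{R_x \approx 0}).
#'
#' @param lambda_nm wavelength(s) in nm, within `valid_range`.
#' @param valid_range inclusive wavelength validity interval in nm.
#' @return diopters, same length as `lambda_nm`.
#' @examples
#' chromatic_refraction(589)                 # ~0 D
#' chromatic_refraction(750) - chromatic_refraction(365)  # ~3.2 D
#' @export
chromatic_refraction <- function(lambda_nm, valid_range = c(365, 950)) {
  if (any(!is.finite(lambda_nm)) ||
      any(lambda_nm < valid_range[1] | lambda_nm > valid_range[2]))
    stop("wavelength outside the model's validity range [",
         valid_range[1], ", ", valid_range[2], "] nm", call. = FALSE)
  k <- atchison_constants
  k[["a0"]] - k[["a2"]] / lambda_nm^2 + k[["a4"]] / lambda_nm^4 -
    k[["a6"]] / lambda_nm^6
}

#' Reference LCA between two wavelengths
#'
#' Difference of the dispersion model between a short and a long wavelength,
#' \eqn{R_x(\lambda_{long}) - R_x(\lambda_{short})}: the literature reference
#' value an objective two-band LCA measurement can be compared with.
#'
#' @param lambda_short,lambda_long wavelengths in nm,
#'   `lambda_short < lambda_long`, both within `valid_range`.
#' @inheritParams chromatic_refraction
#' @return diopters (positive, since the model increases with wavelength).
#' @export
lca_reference <- function(lambda_short, lambda_long,
                          valid_range = c(365, 950)) {
  if (!(lambda_short < lambda_long))
    stop("need lambda_short < lambda_long", call. = FALSE)
  chromatic_refraction(lambda_long, valid_range) -
    chromatic_refraction(lambda_short, valid_range)
}

#' Repeatability of repeated spot-pattern acquisitions
#'
#' Pooled standard deviation of the centroid positions over repeated
#' acquisitions of the same eye position: for each of the eight series
#' (four spot labels times two axes), deviations are taken from that
#' series' own mean, then pooled,
#' \deqn{s = \sqrt{\frac{\sum_{series}\sum_{repeats} d^2}{8\,(m-1)}}}
#' for m repeats. Reported in millimetres.
#'
#' @param patterns list of at least two four-point [spot_pattern]s with
#'   identical label sets (repeated acquisitions).
#' @param per_axis if `TRUE`, return `c(x = , y = )` pooled per axis
#'   (4 series each) instead of the single pooled value.
#' @return pooled SD in mm (length 1, or length 2 when `per_axis`).
#' @export
repeatability_sd <- function(patterns, per_axis = FALSE) {
  m <- length(patterns)
  if (m < 2L)
    stop("need at least 2 repeated acquisitions", call. = FALSE)
  stopifnot(all(vapply(patterns, inherits, TRUE, "spot_pattern")))
  X <- vapply(patterns, function(p) p$x_mm, numeric(4))  # 4 x m
  Y <- vapply(patterns, function(p) p$y_mm, numeric(4))
  dev2 <- function(M) (M - rowMeans(M))^2
  if (per_axis)
    c(x = sqrt(sum(dev2(X)) / (4 * (m - 1))),
      y = sqrt(sum(dev2(Y)) / (4 * (m - 1))))
  else
    sqrt((sum(dev2(X)) + sum(dev2(Y))) / (8 * (m - 1)))
}
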