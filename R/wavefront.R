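#' Wavefront slope field at the four array points
#'
#' Slopes \eqn{TA_x, TA_y} (micrometres of wavefront per unit of normalized
#' pupil coordinate) at the four quadrangular array points a--d, together
#' with the array radius \eqn{\rho} (distance from the pupil centre to each
#' point, in normalized pupil units).
#'
#' @param tax,tay numeric length-4 slope vectors, ordered a, b, c, d.
#' @param rho positive array radius in normalized pupil units.
#' @param band optional band tag.
#' @return object of class `slope_field`.
#' @export
slope_field <- function(tax, tay, rho, band = NA_character_) {
  stopifnot(length(tax) == 4L, length(tay) == 4L)
  if (any(!is.finite(tax)) || any(!is.finite(tay)))
    stop("non-finite slopes", call. = FALSE)
  if (!is.finite(rho) || rho <= 0)
    stop("rho must be positive", call. = FALSE)
  structure(list(tax = stats::setNames(as.numeric(tax), c("a", "b", "c", "d")),
                 tay = stats::setNames(as.numeric(tay), c("a", "b", "c", "d")),
                 rho = rho, band = band),
            class = "slope_field")
}

#' @export
print.slope_field <- function(x, digits = 4, ...) {
  cat("Slope field (um per normalized unit), rho =", round(x$rho, 4), "\n")
  print(round(rbind(TAx = x$tax, TAy = x$tay), digits))
  invisible(x)
}

# Normalized coordinates of the canonical array points a-d: 45/135/225/315
# degrees (image y downward) on a circle of radius rho.
canonical_points <- function(rho) {
  s <- rho / sqrt(2)
  cbind(x = c(1, -1, -1, 1) * s, y = c(-1, -1, 1, 1) * s)
}

# 8x5 design matrix of the four-point modal fit: rows are the x-slopes at
# a-d then the y-slopes at a-d; columns are the gradients of Z1..Z5.
slope_design <- function(rho, z5_sign = "printed") {
  p <- canonical_points(rho)
  A <- matrix(0, 8, 5)
  for (j in 1:5) {
    g <- zernike_gradient(j, p[, "x"], p[, "y"], z5_sign = z5_sign)
    A[, j] <- c(g$dx, g$dy)
  }
  A
}

#' Convert a pair of spot patterns to a slope field
#'
#' Hartmann inversion: the slope at each labelled point is the measured
#' displacement (measured minus reference position, in mm) divided by the
#' calibration constant. \eqn{\rho} is taken from the reference pattern
#' (mean distance to its centre over the pupil radius) unless supplied —
#' when the "reference" is itself a measured pattern (the differential
#' blue-minus-red path), pass the ideal array radius explicitly.
#'
#' @param measured,reference four-point [spot_pattern]s sharing labels and
#'   (approximately) the pupil centre.
#' @param calibration_k mm of displacement per unit slope.
#' @param pupil_radius pupil radius R in mm.
#' @param rho optional array radius in normalized units, overriding the
#'   value computed from `reference`.
#' @param center_tol maximum allowed distance between the two patterns'
#'   centres, mm.
#' @return a [slope_field] tagged with the measured pattern's band.
#' @export
slopes_from_patterns <- function(measured, reference, calibration_k,
                                 pupil_radius, rho = NULL,
                                 center_tol = 0.25) {
  stopifnot(inherits(measured, "spot_pattern"),
            inherits(reference, "spot_pattern"))
  if (!identical(measured$label, reference$label))
    stop("label mismatch between measured and reference patterns",
         call. = FALSE)
  if (!is.finite(calibration_k) || calibration_k <= 0)
    stop("calibration_k must be positive", call. = FALSE)
  if (!is.finite(pupil_radius) || pupil_radius <= 0)
    stop("pupil_radius must be positive", call. = FALSE)
  cm <- attr(measured, "center_mm"); cr <- attr(reference, "center_mm")
  if (sqrt(sum((cm - cr)^2)) > center_tol)
    stop("patterns do not share a pupil centre (offset ",
         round(sqrt(sum((cm - cr)^2)), 3), " mm)", call. = FALSE)
  if (is.null(rho)) {
    d <- sqrt((reference$x_mm - cr[1])^2 + (reference$y_mm - cr[2])^2)
    rho <- mean(d) / pupil_radius
  }
  slope_field((measured$x_mm - reference$x_mm) / calibration_k,
              (measured$y_mm - reference$y_mm) / calibration_k,
              rho, band = attr(measured, "band"))
}

#' Closed-form four-point modal fit
#'
#' Least-squares estimate of C1--C5 from the four-point slope field, written
#' in closed form. Because the gradient columns of the quadrangular design
#' are mutually orthogonal, each coefficient is a signed sum of slopes over
#' a fixed normalizer:
#' \deqn{C_1 = \tfrac14 \sum TA_x, \qquad C_2 = \tfrac14 \sum TA_y,}
#' \deqn{C_3 = \frac{(-TA_{xa}-TA_{xb}+TA_{xc}+TA_{xd}) +
#'   (TA_{ya}-TA_{yb}-TA_{yc}+TA_{yd})}{8\sqrt2\,\rho},}
#' \deqn{C_4 = \frac{(TA_{xa}-TA_{xb}-TA_{xc}+TA_{xd}) +
#'   (-TA_{ya}-TA_{yb}+TA_{yc}+TA_{yd})}{16\sqrt2\,\rho},}
#' \deqn{C_5 = \frac{(-TA_{xa}+TA_{xb}+TA_{xc}-TA_{xd}) +
#'   (-TA_{ya}-TA_{yb}+TA_{yc}+TA_{yd})}{8\sqrt2\,\rho}.}
#' C0 is reported as 0 and flagged unobservable: the gradient of a constant
#' vanishes, so no slope measurement constrains it. The closed form agrees
#' with the generic least-squares solver [fit_modal_lsq] to machine
#' precision on every valid input.
#'
#' @param slopes a [slope_field].
#' @param pupil_radius optional R (mm) recorded on the result.
#' @param z5_sign Z5 sign convention of the basis.
#' @return a [zernike_coefficients] with attribute `c0_observable = FALSE`.
#' @export
fit_modal_closed_form <- function(slopes, pupil_radius = NA_real_,
                                  z5_sign = c("printed", "ansi")) {
  z5_sign <- match.arg(z5_sign)
  stopifnot(inherits(slopes, "slope_field"))
  tx <- slopes$tax; ty <- slopes$tay; rho <- slopes$rho
  if (!is.finite(rho) || rho <= 0)
    stop("degenerate array radius rho", call. = FALSE)
  s5 <- if (z5_sign == "printed") 1 else -1
  cc <- c(0,
          sum(tx) / 4,
          sum(ty) / 4,
          ((-tx[1] - tx[2] + tx[3] + tx[4]) +
           ( ty[1] - ty[2] - ty[3] + ty[4])) / (8 * sqrt(2) * rho),
          (( tx[1] - tx[2] - tx[3] + tx[4]) +
           (-ty[1] - ty[2] + ty[3] + ty[4])) / (16 * sqrt(2) * rho),
          s5 * ((-tx[1] + tx[2] + tx[3] - tx[4]) +
                (-ty[1] - ty[2] + ty[3] + ty[4])) / (8 * sqrt(2) * rho))
  out <- zernike_coefficients(cc, pupil_radius, z5_sign)
  attr(out, "c0_observable") <- FALSE
  out
}

#' Generic least-squares modal fit
#'
#' Solves the 8-equation, 5-unknown linear system relating the observed
#' slopes to the coefficient-weighted basis gradients at the canonical array
#' points by QR least squares. Serves as the independent check of the closed
#' form; both give the unique minimizer because the four-point quadrangular
#' design has full column rank for Z1--Z5.
#'
#' @inheritParams fit_modal_closed_form
#' @return a [zernike_coefficients] with attribute `c0_observable = FALSE`.
#' @export
fit_modal_lsq <- function(slopes, pupil_radius = NA_real_,
                          z5_sign = c("printed", "ansi")) {
  z5_sign <- match.arg(z5_sign)
  stopifnot(inherits(slopes, "slope_field"))
  if (!is.finite(slopes$rho) || slopes$rho <= 0)
    stop("degenerate array radius rho", call. = FALSE)
  A <- slope_design(slopes$rho, z5_sign)
  qr_A <- qr(A)
  if (qr_A$rank < 5L)
    stop("rank-deficient slope design (collinear array points)",
         call. = FALSE)
  cc <- qr.coef(qr_A, c(slopes$tax, slopes$tay))
  out <- zernike_coefficients(c(0, cc), pupil_radius, z5_sign)
  attr(out, "c0_observable") <- FALSE
  out
}

#' Fit low-order Zernike coefficients to a slope field
#'
#' Front end over the two modal solvers, returning a fitted-model object
#' with the usual accessors.
#'
#' @inheritParams fit_modal_closed_form
#' @param method `"closed_form"` (default) or `"lsq"`.
#' @return object of class `zernike_fit` with components `coefficients`
#'   ([zernike_coefficients]), `slopes`, `fitted` (slopes reproduced by the
#'   fit), `residuals` and `method`.
#' @examples
#' sf <- slope_field(tax = c(1, 1, 1, 1), tay = rep(0, 4), rho = 0.6)
#' fit <- fit_zernike(sf)
#' coef(fit)      # pure x-tilt: C1 = 1
#' @export
fit_zernike <- function(slopes, pupil_radius = NA_real_,
                        method = c("closed_form", "lsq"),
                        z5_sign = c("printed", "ansi")) {
  method <- match.arg(method)
  z5_sign <- match.arg(z5_sign)
  cc <- switch(method,
               closed_form = fit_modal_closed_form(slopes, pupil_radius, z5_sign),
               lsq = fit_modal_lsq(slopes, pupil_radius, z5_sign))
  A <- slope_design(slopes$rho, z5_sign)
  fitted <- as.numeric(A %*% unclass(cc)[2:6])
  obs <- c(slopes$tax, slopes$tay)
  structure(list(coefficients = cc, slopes = slopes,
                 fitted = fitted, residuals = obs - fitted,
                 method = method, z5_sign = z5_sign),
            class = "zernike_fit")
}

#' @export
coef.zernike_fit <- function(object, ...) object$coefficients

#' @export
residuals.zernike_fit <- function(object, ...) object$residuals

#' @export
print.zernike_fit <- function(x, digits = 4, ...) {
  cat("Four-point modal Zernike fit (", x$method, ")\n", sep = "")
  print(x$coefficients, digits = digits)
  cat("C0 is unobservable from slopes and reported as 0\n")
  cat("RMS slope residual:", signif(sqrt(mean(x$residuals^2)), 3), "\n")
  invisible(x)
}

#' @param object,x a `zernike_fit`.
#' @param x_norm,y_norm normalized pupil coordinates at which to evaluate
#'   the reconstructed wavefront.
#' @rdname fit_zernike
#' @export
predict.zernike_fit <- function(object, x_norm, y_norm, ...) {
  reconstruct_wavefront(object$coefficients, x_norm, y_norm)
}

#' @param n grid resolution of the wavefront map.
#' @rdname fit_zernike
#' @export
plot.zernike_fit <- function(x, n = 101, ...) {
  g <- seq(-1, 1, length.out = n)
  xx <- rep(g, times = n); yy <- rep(g, each = n)
  w <- rep(NA_real_, n * n)
  inside <- xx^2 + yy^2 <= 1
  w[inside] <- predict(x, xx[inside], yy[inside])
  graphics::image(g, g, matrix(w, n, n), asp = 1,
                  xlab = "x (pupil units)", ylab = "y (pupil units)",
                  main = "Reconstructed wavefront (um)", ...)
  graphics::contour(g, g, matrix(w, n, n), add = TRUE)
  invisible(x)
}
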