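#' Cartesian Zernike basis, orders 0--5
#'
#' The low-order Cartesian Zernike polynomials used for modal wavefront
#' reconstruction from a four-point spot array:
#' \deqn{Z_0 = 1,\; Z_1 = x,\; Z_2 = y,\; Z_3 = 2xy,\; Z_4 = -1 + 2x^2 + 2y^2,\;
#'       Z_5 = y^2 - x^2}
#' Coordinates are normalized by the pupil radius, so the basis lives on the
#' closed unit disc. \eqn{Z_4} is defocus; \eqn{Z_3} and \eqn{Z_5} are the two
#' primary astigmatisms; \eqn{Z_1}, \eqn{Z_2} are tilts.
#'
#' The default sign of \eqn{Z_5} is \eqn{y^2 - x^2}; the ANSI convention
#' (\eqn{x^2 - y^2}) is available via `z5_sign = "ansi"`.
#'
#' @param i basis index, integer in 0..5.
#' @param x,y normalized pupil coordinates (unit disc), vectors of equal length.
#' @param z5_sign `"printed"` (default, \eqn{y^2 - x^2}) or `"ansi"`
#'   (\eqn{x^2 - y^2}).
#' @return `zernike_value`: numeric vector of polynomial values.
#' @examples
#' zernike_value(4, 0, 0)    # -1 at the pupil centre (defocus)
#' zernike_value(3, 1, 1)    # 2
#' @export
zernike_value <- function(i, x, y, z5_sign = c("printed", "ansi")) {
  z5_sign <- match.arg(z5_sign)
  check_zernike_index(i)
  stopifnot(length(x) == length(y))
  switch(i + 1L,
    rep(1, length(x)),              # Z0
    x,                              # Z1
    y,                              # Z2
    2 * x * y,                      # Z3
    -1 + 2 * x^2 + 2 * y^2,         # Z4
    if (z5_sign == "printed") y^2 - x^2 else x^2 - y^2)
}

#' @rdname zernike_value
#' @return `zernike_gradient`: a list with components `dx` and `dy`, the
#'   analytic partial derivatives of \eqn{Z_i}.
#' @examples
#' zernike_gradient(4, 0.5, -0.5)  # (2, -2)
#' @export
zernike_gradient <- function(i, x, y, z5_sign = c("printed", "ansi")) {
  z5_sign <- match.arg(z5_sign)
  check_zernike_index(i)
  stopifnot(length(x) == length(y))
  zero <- rep(0, length(x))
  s5 <- if (z5_sign == "printed") 1 else -1
  switch(i + 1L,
    list(dx = zero, dy = zero),                 # Z0
    list(dx = zero + 1, dy = zero),             # Z1
    list(dx = zero, dy = zero + 1),             # Z2
    list(dx = 2 * y, dy = 2 * x),               # Z3
    list(dx = 4 * x, dy = 4 * y),               # Z4
    list(dx = -2 * s5 * x, dy = 2 * s5 * y))    # Z5
}

check_zernike_index <- function(i) {
  if (length(i) != 1L || !is.finite(i) || i != as.integer(i) || i < 0 || i > 5)
    stop("Zernike index must be a single integer in 0..5", call. = FALSE)
  invisible(i)
}

#' Zernike coefficient vector C0--C5
#'
#' Container for the six low-order coefficients (in micrometres) together with
#' the pupil radius used for coordinate normalization.
#'
#' @param values numeric vector of length 6, coefficients C0..C5 in micrometres.
#'   A named subset (e.g. `c(C4 = 0.5)`) fills the rest with zeros.
#' @param pupil_radius pupil radius R in millimetres (used by the
#'   defocus-to-diopter conversion).
#' @param z5_sign sign convention tag for Z5, `"printed"` or `"ansi"`.
#' @return an object of class `zernike_coefficients`: a named numeric vector
#'   with attributes `pupil_radius` and `z5_sign`.
#' @export
zernike_coefficients <- function(values = numeric(6), pupil_radius = NA_real_,
                                 z5_sign = c("printed", "ansi")) {
  z5_sign <- match.arg(z5_sign)
  nm <- paste0("C", 0:5)
  if (!is.null(names(values)) && all(names(values) %in% nm)) {
    v <- stats::setNames(numeric(6), nm)
    v[names(values)] <- values
    values <- v
  }
  if (length(values) != 6L)
    stop("need 6 coefficients C0..C5", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite Zernike coefficients", call. = FALSE)
  structure(stats::setNames(as.numeric(values), nm),
            pupil_radius = pupil_radius, z5_sign = z5_sign,
            class = "zernike_coefficients")
}

#' @export
print.zernike_coefficients <- function(x, digits = 4, ...) {
  cat("Zernike coefficients C0..C5 (um), Z5 convention:",
      attr(x, "z5_sign"), "\n")
  print(round(unclass(x), digits))
  if (is.finite(attr(x, "pupil_radius")))
    cat("pupil radius R =", attr(x, "pupil_radius"), "mm\n")
  invisible(x)
}

#' Evaluate a reconstructed wavefront on a grid
#'
#' Computes \eqn{W(x,y) = \sum_{i=0}^{5} C_i Z_i(x,y)} at normalized pupil
#' coordinates. Points must lie on the closed unit disc.
#'
#' @param coeffs a [zernike_coefficients] object (or plain length-6 vector).
#' @param x,y normalized coordinates, equal-length vectors.
#' @return numeric vector of wavefront values in micrometres.
#' @export
reconstruct_wavefront <- function(coeffs, x, y) {
  if (!inherits(coeffs, "zernike_coefficients"))
    coeffs <- zernike_coefficients(coeffs)
  stopifnot(length(x) == length(y))
  if (any(x^2 + y^2 > 1 + 1e-9))
    stop("grid points outside the unit pupil disc", call. = FALSE)
  z5 <- attr(coeffs, "z5_sign")
  w <- rep(0, length(x))
  for (i in 0:5)
    w <- w + coeffs[[i + 1L]] * zernike_value(i, x, y, z5_sign = z5)
  w
}

# Wavefront slope field (sum of coefficient-weighted basis gradients) at
# arbitrary normalized points; used by the forward spot model and the fits.
wavefront_slopes <- function(coeffs, x, y) {
  if (!inherits(coeffs, "zernike_coefficients"))
    coeffs <- zernike_coefficients(coeffs)
  z5 <- attr(coeffs, "z5_sign")
  dx <- rep(0, length(x)); dy <- rep(0, length(x))
  for (i in 0:5) {
    g <- zernike_gradient(i, x, y, z5_sign = z5)
    dx <- dx + coeffs[[i + 1L]] * g$dx
    dy <- dy + coeffs[[i + 1L]] * g$dy
  }
  list(dx = dx, dy = dy)
}
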