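# Shared fixtures: everything is generated in code at test time.

test_config <- function(...) lca_config(...)

# Slope field synthesized from a known coefficient vector by evaluating the
# analytic basis gradients at the canonical array points (forward oracle for
# the modal fits).
slopes_from_coeffs <- function(cvals, rho, z5_sign = "printed",
                               band = NA_character_) {
  s <- rho / sqrt(2)
  px <- c(1, -1, -1, 1) * s
  py <- c(-1, -1, 1, 1) * s
  cc <- zernike_coefficients(cvals, z5_sign = z5_sign)
  tax <- numeric(4); tay <- numeric(4)
  for (i in 0:5) {
    g <- zernike_gradient(i, px, py, z5_sign = z5_sign)
    tax <- tax + cc[[i + 1]] * g$dx
    tay <- tay + cc[[i + 1]] * g$dy
  }
  slope_field(tax, tay, rho, band = band)
}

# Central finite differences of a scalar function of (x, y).
fd_gradient <- function(f, x, y, h = 1e-6) {
  c((f(x + h, y) - f(x - h, y)) / (2 * h),
    (f(x, y + h) - f(x, y - h)) / (2 * h))
}

# Exhaustive circle-Hough oracle: for every candidate centre and radius,
# count the edge pixels whose distance to the centre rounds to the radius.
# Returns the single best circle under the implementation's tie-break
# (score desc, radius asc, then y, then x).
hough_oracle <- function(px, radius_range, edge_threshold) {
  mag <- purkinjelca:::sobel_magnitude(px)
  idx <- which(mag >= edge_threshold)
  ny <- nrow(px); nx <- ncol(px)
  ex <- (idx - 1) %/% ny; ey <- (idx - 1) %% ny
  best <- NULL
  for (r in radius_range[1]:radius_range[2]) {
    for (cy in 0:(ny - 1)) for (cx in 0:(nx - 1)) {
      score <- sum(round(sqrt((ex - cx)^2 + (ey - cy)^2)) == r)
      if (is.null(best) || score > best$score)
        best <- list(x = cx, y = cy, r = r, score = score)
    }
  }
  best
}

# True displaced PIV pattern of one band of a simulated subject.
true_piv_pattern <- function(truth, band, pixel_scale) {
  cc <- if (band == "blue") truth$coeffs_blue else truth$coeffs_red
  forward_spot_positions(cc, truth$reference_pattern, truth$calibration_k,
                         pixel_scale)
}

# Largest centroid error (px) of a detected pattern against the truth.
max_centroid_err_px <- function(detected, truth_pattern, pixel_scale) {
  stopifnot(identical(detected$label, truth_pattern$label))
  max(sqrt((detected$x_mm - truth_pattern$x_mm)^2 +
           (detected$y_mm - truth_pattern$y_mm)^2)) / pixel_scale
}
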