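#' Sobel gradient magnitude
#'
#' 3x3 difference operator used as the edge front-end of the circle Hough
#' transform. Borders are replicated.
#'
#' @param px numeric matrix (rows = y).
#' @return matrix of gradient magnitudes, same size.
#' @keywords internal
sobel_magnitude <- function(px) {
  ny <- nrow(px); nx <- ncol(px)
  p <- px[c(1, 1:ny, ny), c(1, 1:nx, nx)]  # replicate-pad by 1
  s <- function(di, dj) p[(1:ny) + 1 + di, (1:nx) + 1 + dj]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
        (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
        (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  sqrt(gx^2 + gy^2)
}

# Integer circle-perimeter offsets for one radius: all (dx, dy) whose
# distance from the origin rounds to r. Voting with this set makes the
# accumulator identical to exhaustively counting, for every candidate
# centre, the edge pixels whose distance rounds to r.
.offset_cache <- new.env(parent = emptyenv())

circle_offsets <- function(r) {
  key <- as.character(r)
  if (!is.null(.offset_cache[[key]])) return(.offset_cache[[key]])
  d <- -r:r
  dx <- rep(d, times = length(d)); dy <- rep(d, each = length(d))
  keep <- round(sqrt(dx^2 + dy^2)) == r
  .offset_cache[[key]] <- cbind(dx = dx[keep], dy = dy[keep])
}

#' Circle Hough transform
#'
#' Detects circles by voting: every edge pixel (Sobel magnitude at or above
#' `edge_threshold`) votes for all centres at each candidate radius, and the
#' returned centres are accumulator maxima. Deterministic tie-breaking:
#' highest score, then smallest radius, then lowest (y, x). Non-maximum
#' suppression removes any further maximum whose centre lies within one
#' radius of an already accepted circle.
#'
#' @param image an [eye_image] or numeric matrix.
#' @param radius_range `c(min, max)` candidate radii in pixels (integers).
#' @param edge_threshold gradient-magnitude threshold for edge pixels.
#' @param max_circles maximum number of circles to return.
#' @param min_score minimum accumulator votes for a detection.
#' @param mask optional logical matrix; only edges inside it vote.
#' @return data.frame with columns `x`, `y` (0-based pixel centre), `r`
#'   (radius, px) and `score` (votes), sorted by descending score; zero rows
#'   if nothing reaches `min_score`.
#' @export
hough_circles <- function(image, radius_range, edge_threshold = 150,
                          max_circles = 1L, min_score = 10L, mask = NULL) {
  px <- if (inherits(image, "eye_image")) image$pixels else image
  stopifnot(is.matrix(px))
  ny <- nrow(px); nx <- ncol(px)
  if (length(radius_range) != 2L || radius_range[1] > radius_range[2] ||
      floor(radius_range[2]) < 1)
    stop("empty or invalid radius range", call. = FALSE)
  radii <- seq.int(max(1, ceiling(radius_range[1])), floor(radius_range[2]))
  if (max(radii) >= min(nx, ny))
    stop("radius range exceeds the image extent", call. = FALSE)

  mag <- sobel_magnitude(px)
  edge <- mag >= edge_threshold
  if (!is.null(mask)) edge <- edge & mask
  if (!any(edge)) return(empty_circles())
  idx <- which(edge)
  ex <- (idx - 1L) %/% ny   # 0-based x (column)
  ey <- (idx - 1L) %% ny    # 0-based y (row)

  npx <- nx * ny
  acc <- matrix(0L, npx, length(radii))  # accumulator: pixel index x radius
  for (k in seq_along(radii)) {
    off <- circle_offsets(radii[k])
    acc[, k] <- .hough_vote(as.integer(ex), as.integer(ey),
                            as.integer(off[, 1]), as.integer(off[, 2]),
                            as.integer(nx), as.integer(ny))
  }

  out <- empty_circles()
  # accumulator is scanned radius-major then (y, x)-major, so which.max's
  # first-occurrence rule realizes the documented tie-break
  all_y <- rep(0:(ny - 1), each = nx)  # linear pixel index -> y, x
  all_x <- rep(0:(nx - 1), times = ny)
  for (i in seq_len(max_circles)) {
    best <- which.max(acc)
    if (acc[best] < min_score) break
    kr <- (best - 1L) %/% npx + 1L
    pix <- (best - 1L) %% npx
    cx0 <- pix %% nx; cy0 <- pix %/% nx
    out <- rbind(out, data.frame(x = cx0, y = cy0, r = radii[kr],
                                 score = acc[best]))
    # suppress every candidate centre within one radius of this circle
    sup <- (all_x - cx0)^2 + (all_y - cy0)^2 <= radii[kr]^2
    acc[sup, ] <- 0L
  }
  out
}

empty_circles <- function() {
  data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
             score = numeric(0))
}

#' Segment the iris with the circle Hough transform
#'
#' Finds the dominant circular boundary in the given radius range and returns
#' the circle together with a logical mask of its interior; all later
#' processing is restricted to that mask.
#'
#' @inheritParams hough_circles
#' @return list with `circle` (one-row data.frame) and `mask` (logical
#'   matrix, `TRUE` inside the detected circle).
#' @export
segment_iris <- function(image, radius_range, edge_threshold = 150,
                         min_score = 10L) {
  circ <- hough_circles(image, radius_range, edge_threshold,
                        max_circles = 1L, min_score = min_score)
  if (nrow(circ) == 0L)
    stop("iris not found: no circle in radius range [",
         radius_range[1], ", ", radius_range[2], "]", call. = FALSE)
  px <- if (inherits(image, "eye_image")) image$pixels else image
  ny <- nrow(px); nx <- ncol(px)
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), times = nx), ny, nx)
  mask <- (xs - circ$x)^2 + (ys - circ$y)^2 <= circ$r^2
  list(circle = circ, mask = mask)
}

#' Intensity band threshold
#'
#' `TRUE` exactly where the mask is true and the grey level lies in
#' `[low, high]`. With the PIV defaults (low above the dark-pupil background,
#' high = 100), pixels of the bright PI pattern (200--255) are excluded.
#'
#' @param image an [eye_image] or numeric matrix.
#' @param mask logical matrix restricting the region (e.g. the iris mask).
#' @param low,high inclusive grey-level band, `low <= high`.
#' @return logical matrix.
#' @export
band_threshold <- function(image, mask, low, high) {
  if (low > high) stop("need low <= high", call. = FALSE)
  px <- if (inherits(image, "eye_image")) image$pixels else image
  stopifnot(identical(dim(px), dim(mask)))
  mask & px >= low & px <= high
}

#' Remove small connected components
#'
#' Deletes 8-connected components with fewer than `min_area` pixels
#' (the noise-removal step that strips speckle and stray reflections before
#' spot detection). Larger components are untouched.
#'
#' @param mask logical matrix.
#' @param min_area minimum surviving component area in pixels (>= 1).
#' @return logical matrix.
#' @export
denoise <- function(mask, min_area) {
  if (min_area < 1) stop("min_area must be >= 1", call. = FALSE)
  if (min_area == 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Detect the four PIV spots
#'
#' Full detection chain of one band: iris segmentation (Hough), PIV intensity
#' banding, connected-component noise removal, a second small-radius Hough
#' pass to locate the spots, then pixel-sum centroids — each centroid is the
#' unweighted mean of its spot's pixel positions (an intensity-weighted
#' variant is available via `weighting`). Centroids are labelled by quadrant
#' relative to the detected iris centre and converted to mm.
#'
#' @param image an [eye_image].
#' @param config an [lca_config].
#' @param band band tag recorded on the returned pattern.
#' @param weighting `"none"` (pixel-sum rule, default) or `"intensity"`.
#' @return a [spot_pattern] (positions in mm); its `center_mm` is the
#'   detected iris centre.
#' @export
detect_piv_spots <- function(image, config = lca_config(),
                             band = NA_character_,
                             weighting = c("none", "intensity")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(image, "eye_image"))
  iris <- segment_iris(image, config$iris_radius_range,
                       config$edge_threshold)
  bw <- band_threshold(image, iris$mask,
                       config$piv_band[1], config$piv_band[2])
  bw <- denoise(bw, config$min_area)

  lab <- EBImage::bwlabel(bw * 1)
  ncomp <- max(lab)
  if (ncomp != 4L)
    stop("PIV spot count ", ncomp, " (expected 4)", call. = FALSE)

  # small-radius Hough on the spot mask: one circle per spot
  circ <- hough_circles(bw * 255, config$spot_radius_range,
                        edge_threshold = 200, max_circles = 4L,
                        min_score = config$spot_min_score)
  if (nrow(circ) != 4L)
    stop("PIV spot count ", nrow(circ), " (expected 4)", call. = FALSE)
  ny <- nrow(lab)
  comp_of <- lab[cbind(circ$y + 1L, circ$x + 1L)]
  if (anyDuplicated(comp_of[comp_of > 0]) || any(comp_of == 0))
    stop("ambiguous PIV detection: spot circles do not match components 1:1",
         call. = FALSE)

  cx <- numeric(4); cy <- numeric(4)
  for (k in 1:4) {
    idx <- which(lab == comp_of[k])
    xpix <- (idx - 1L) %/% ny   # 0-based x
    ypix <- (idx - 1L) %% ny    # 0-based y
    w <- if (weighting == "intensity")
      image$pixels[idx] else rep(1, length(idx))
    cx[k] <- sum(w * xpix) / sum(w)
    cy[k] <- sum(w * ypix) / sum(w)
  }
  labels <- label_quadrants(cx, cy, c(iris$circle$x, iris$circle$y))
  ps <- image$pixel_scale
  spot_pattern(cx * ps, cy * ps, labels = labels, band = band,
               center_mm = c(iris$circle$x, iris$circle$y) * ps,
               pixel_scale = ps)
}
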