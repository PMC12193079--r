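# Closed planar contours in a resection-plane frame. The canonical
# parameterization (counter-clockwise, arc length zero on the +e2 ray from
# the centroid, with e2 chosen as the anterior direction when planes are
# built from anatomy) is what makes arc-length ignore zones comparable
# between a bone contour and an implant contour.

#' Construct a closed planar contour
#'
#' @param points n x 2 matrix of in-plane coordinates (mm); implicit closure
#'   (first point is not repeated)
#' @param origin 3D origin of the plane frame (mm)
#' @param e1,e2 in-plane orthonormal axes (3D unit vectors)
#' @param canonicalize reorder to counter-clockwise with arc length zero at
#'   the +e2 crossing (default TRUE)
#' @return a `PlanarContour`
#' @export
planar_contour <- function(points, origin = c(0, 0, 0), e1 = c(1, 0, 0),
                           e2 = c(0, 1, 0), canonicalize = TRUE) {
  points <- matrix(as.double(points), ncol = 2)
  if (nrow(points) >= 2 &&
      sqrt(sum((points[1, ] - points[nrow(points), ])^2)) < 1e-12) {
    points <- points[-nrow(points), , drop = FALSE]
  }
  if (nrow(points) < 8) stop("a closed contour needs at least 8 points")
  if (canonicalize) {
    if (shoelace_area(points) < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
    ctr <- polygon_centroid(points)
    ang <- atan2(points[, 2] - ctr[2], points[, 1] - ctr[1])
    # start at the sample whose direction is closest to +e2 (angle pi/2)
    d <- abs(((ang - pi / 2 + pi) %% (2 * pi)) - pi)
    s <- which.min(d)
    if (s > 1) points <- points[c(s:nrow(points), 1:(s - 1)), , drop = FALSE]
  }
  structure(list(points = points, origin = as.numeric(origin),
                 e1 = as.numeric(e1), e2 = as.numeric(e2), closed = TRUE),
            class = "PlanarContour")
}

#' @export
print.PlanarContour <- function(x, ...) {
  cat(sprintf("PlanarContour: %d points, perimeter %.1f mm, area %.1f mm^2\n",
              nrow(x$points), contour_perimeter(x), abs(shoelace_area(x$points))))
  invisible(x)
}

shoelace_area <- function(p) {
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]) / 2
}

polygon_centroid <- function(p) {
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  cr <- p[, 1] * q[, 2] - q[, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(p))
  c(sum((p[, 1] + q[, 1]) * cr), sum((p[, 2] + q[, 2]) * cr)) / (6 * a)
}

#' Perimeter of a closed contour (mm)
#' @param contour a `PlanarContour`
#' @export
contour_perimeter <- function(contour) {
  p <- contour$points
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  sum(sqrt(rowSums((q - p)^2)))
}

#' Enclosed area of a closed contour (mm^2)
#' @param contour a `PlanarContour`
#' @export
contour_area <- function(contour) abs(shoelace_area(contour$points))

#' Area centroid of a closed contour (mm, in-plane)
#' @param contour a `PlanarContour`
#' @export
contour_centroid <- function(contour) polygon_centroid(contour$points)

#' Resample a contour at a fixed arc step
#' @param contour a `PlanarContour`
#' @param step maximum arc step (mm)
#' @return list with `points` (m x 2) and `frac` (normalized arc positions)
#' @export
contour_resample <- function(contour, step = 0.5) {
  p <- contour$points
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  seg <- sqrt(rowSums((q - p)^2))
  per <- sum(seg)
  n <- max(nrow(p), ceiling(per / step))
  s_target <- seq(0, per, length.out = n + 1)[-(n + 1)]
  s_cum <- c(0, cumsum(seg))
  idx <- findInterval(s_target, s_cum, rightmost.closed = TRUE)
  idx[idx > nrow(p)] <- nrow(p)
  t <- (s_target - s_cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  pts <- p[idx, , drop = FALSE] + (q[idx, , drop = FALSE] - p[idx, , drop = FALSE]) * t
  list(points = pts, frac = s_target / per)
}

#' Point-in-polygon test (even-odd rule)
#' @param pt length-2 point
#' @param contour a `PlanarContour`
#' @export
contour_contains <- function(pt, contour) {
  p <- contour$points
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  crosses <- ((p[, 2] > pt[2]) != (q[, 2] > pt[2])) &
    (pt[1] < p[, 1] + (q[, 1] - p[, 1]) * (pt[2] - p[, 2]) / (q[, 2] - p[, 2]))
  sum(crosses) %% 2 == 1
}

#' Check that a contour is simple (non-self-intersecting)
#'
#' O(n^2) segment test on a decimated copy; adequate at design scale.
#' @param contour a `PlanarContour`
#' @export
contour_is_simple <- function(contour) {
  p <- contour$points
  if (nrow(p) > 200) {
    keep <- unique(round(seq(1, nrow(p), length.out = 200)))
    p <- p[keep, , drop = FALSE]
  }
  n <- nrow(p)
  q <- p[c(2:n, 1), , drop = FALSE]
  seg_int <- function(a0, a1, b0, b1) {
    d1 <- (b1[1] - b0[1]) * (a0[2] - b0[2]) - (b1[2] - b0[2]) * (a0[1] - b0[1])
    d2 <- (b1[1] - b0[1]) * (a1[2] - b0[2]) - (b1[2] - b0[2]) * (a1[1] - b0[1])
    d3 <- (a1[1] - a0[1]) * (b0[2] - a0[2]) - (a1[2] - a0[2]) * (b0[1] - a0[1])
    d4 <- (a1[1] - a0[1]) * (b1[2] - a0[2]) - (a1[2] - a0[2]) * (b1[1] - a0[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(p[i, ], q[i, ], p[j, ], q[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Lift in-plane contour points to 3D patient coordinates
#' @param contour a `PlanarContour`
#' @return n x 3 matrix (mm)
#' @export
contour_to_3d <- function(contour) {
  sweep(outer(contour$points[, 1], contour$e1) +
        outer(contour$points[, 2], contour$e2), 2, contour$origin, "+")
}
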