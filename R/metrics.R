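# Evaluation metrics: Dice on label masks, RMSE/Hausdorff on meshes and on
# planar contours. Symmetric variants are the defaults for reported numbers.

distance_report <- function(distances, direction) {
  distances <- as.numeric(distances)
  structure(list(
    rmse = sqrt(mean(distances^2)),
    hausdorff = max(distances),
    distances = distances,
    direction = direction
  ), class = "DistanceReport")
}

#' @export
print.DistanceReport <- function(x, ...) {
  cat(sprintf("DistanceReport (%s): RMSE %.4g mm, Hausdorff %.4g mm, n=%d\n",
              x$direction, x$rmse, x$hausdorff, length(x$distances)))
  invisible(x)
}

#' Dice overlap coefficient between two label masks
#'
#' 2|A n B| / (|A| + |B|) over voxels equal to `label`; returns 1 when both
#' masks are empty for that label. Symmetric in its arguments and bounded in
#' [0, 1].
#'
#' @param maskA,maskB `LabelMask` objects (or integer arrays) of equal shape
#' @param label label value compared (default 1)
#' @return Dice fraction
#' @export
dice <- function(maskA, maskB, label = 1L) {
  a <- if (inherits(maskA, "LabelMask")) maskA$labels else maskA
  b <- if (inherits(maskB, "LabelMask")) maskB$labels else maskB
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  av <- a == label
  bv <- b == label
  na <- sum(av)
  nb <- sum(bv)
  if (na + nb == 0) return(1.0)
  2 * sum(av & bv) / (na + nb)
}

#' Surface distance report between two meshes
#'
#' Distances from the source mesh's vertices to the target's triangulated
#' surface (exact point-to-triangle). RMSE uses the vertex samples without
#' area weighting; the symmetric mode averages the RMSE of both directions
#' and takes the maximum of both Hausdorff distances.
#'
#' @param meshA,meshB `TriMesh` objects
#' @param symmetric symmetric (default) or A-to-B only
#' @return a `DistanceReport`
#' @export
surface_distance <- function(meshA, meshB, symmetric = TRUE) {
  if (nrow(meshA$vertices) == 0 || nrow(meshB$vertices) == 0) {
    stop("empty mesh")
  }
  dab <- point_mesh_distance(meshA$vertices, meshB)$dist
  if (!symmetric) return(distance_report(dab, "a_to_b"))
  dba <- point_mesh_distance(meshB$vertices, meshA)$dist
  rep_ <- distance_report(c(dab, dba), "symmetric")
  rep_$rmse <- (sqrt(mean(dab^2)) + sqrt(mean(dba^2))) / 2
  rep_$hausdorff <- max(max(dab), max(dba))
  rep_
}

#' Over/under-hang distance between two closed planar contours
#'
#' Samples the source contour at arc steps of at most `step` mm, excludes
#' samples whose normalized arc-length position falls inside any ignore zone,
#' and measures unsigned distances to the other contour's polyline. The
#' symmetric mode averages RMSEs and takes the max Hausdorff, applying each
#' contour's own arc-length zones to its samples.
#'
#' @param contourA,contourB `PlanarContour` objects in the same plane frame
#' @param ignore_zones list of c(lo, hi) normalized arc-length intervals
#' @param symmetric symmetric (default) or A-to-B only
#' @param step sampling step (mm)
#' @return a `DistanceReport`
#' @export
contour_distance <- function(contourA, contourB, ignore_zones = list(),
                             symmetric = TRUE, step = 0.5) {
  stopifnot(inherits(contourA, "PlanarContour"), inherits(contourB, "PlanarContour"))
  one_way <- function(src, dst) {
    s <- contour_resample(src, step)
    keep <- !in_zones(s$frac, ignore_zones)
    if (!any(keep)) stop("empty after exclusion: ignore zones cover every sample")
    polyline_point_distance(s$points[keep, , drop = FALSE], dst$points)
  }
  dab <- one_way(contourA, contourB)
  if (!symmetric) return(distance_report(dab, "a_to_b"))
  dba <- one_way(contourB, contourA)
  rep_ <- distance_report(c(dab, dba), "symmetric")
  rep_$rmse <- (sqrt(mean(dab^2)) + sqrt(mean(dba^2))) / 2
  rep_$hausdorff <- max(max(dab), max(dba))
  rep_
}

in_zones <- function(frac, zones) {
  if (length(zones) == 0) return(rep(FALSE, length(frac)))
  hit <- rep(FALSE, length(frac))
  for (z in zones) {
    if (z[2] - z[1] >= 1) return(rep(TRUE, length(frac)))
    lo <- z[1] %% 1
    hi <- z[2] %% 1
    if (lo <= hi) {
      hit <- hit | (frac >= lo & frac <= hi)
    } else {  # wrapped interval
      hit <- hit | (frac >= lo | frac <= hi)
    }
  }
  hit
}

# unsigned distances from 2D points to a closed polyline (n x 2 matrix)
polyline_point_distance <- function(points, poly) {
  p0 <- poly
  p1 <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  e <- p1 - p0
  el2 <- pmax(rowSums(e^2), .Machine$double.eps)
  vapply(seq_len(nrow(points)), function(i) {
    w0 <- sweep(p0, 2, points[i, ], "-")
    t <- pmin(pmax(-(w0[, 1] * e[, 1] + w0[, 2] * e[, 2]) / el2, 0), 1)
    dx <- w0[, 1] + t * e[, 1]
    dy <- w0[, 2] + t * e[, 2]
    sqrt(min(dx^2 + dy^2))
  }, numeric(1))
}
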