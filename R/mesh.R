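#' Triangle mesh container
#'
#' A `TriMesh` is a watertight (where stated) triangle surface in millimetres,
#' right-handed patient coordinates: +z proximal, +y anterior, +x lateral for
#' a right-side bone.
#'
#' @param vertices numeric matrix, V x 3, coordinates in mm.
#' @param faces integer matrix, F x 3, 1-based vertex indices.
#' @return An object of class `TriMesh` with elements `vertices` and `faces`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  if (nrow(faces) > 0L) {
    rng <- range(faces)
    if (rng[1] < 1L || rng[2] > nrow(vertices)) stop("face indices out of range")
  }
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  structure(list(vertices = vertices, faces = faces), class = "TriMesh")
}

#' @export
print.TriMesh <- function(x, ...) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_tri_mesh <- function(x) inherits(x, "TriMesh")

#' Per-face areas, normals and centroids
#' @param mesh a `TriMesh`
#' @return list with `areas` (mm^2), `normals` (F x 3 unit), `centroids` (F x 3)
#' @export
mesh_face_data <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- sqrt(rowSums(cr^2))
  list(
    areas = nrm / 2,
    normals = cr / pmax(nrm, .Machine$double.eps),
    centroids = (a + b + c) / 3
  )
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `TriMesh`
#' @export
mesh_area <- function(mesh) sum(mesh_face_data(mesh)$areas)

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Positive for outward-oriented (counter-clockwise) faces.
#' @param mesh a `TriMesh`
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(
    a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
    a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  ) / 6
}

#' Check watertightness (every edge shared by exactly two faces)
#' @param mesh a `TriMesh`
#' @return logical
#' @export
mesh_is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) return(FALSE)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Area-weighted vertex normals
#' @param mesh a `TriMesh`
#' @return V x 3 matrix of unit normals
#' @export
mesh_vertex_normals <- function(mesh) {
  fd <- mesh_face_data(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  n <- matrix(0, nrow(V), 3)
  w <- fd$normals * fd$areas
  for (j in 1:3) {
    for (cc in 1:3) {
      acc <- rowsum(w[, cc], F[, j])
      idx <- as.integer(rownames(acc))
      n[idx, cc] <- n[idx, cc] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.eps)
}

#' Distances from points to a mesh surface
#'
#' Exact point-to-triangle closest points; ties broken by lowest triangle
#' index.
#' @param points n x 3 matrix of query points (mm)
#' @param mesh a `TriMesh`
#' @return list with `dist` (mm), `closest` (n x 3), `tri` (1-based indices)
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- matrix(as.double(points), ncol = 3)
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  cpp_point_mesh_dist(points, mesh$vertices, mesh$faces)
}

#' Remove vertices not referenced by any face
#' @param mesh a `TriMesh`
#' @return a compacted `TriMesh`; vertex order of survivors is preserved
#' @export
mesh_drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[mesh$faces], ncol = 3))
}

#' Apply an affine map x -> R diag(s) x + t to a mesh
#' @param mesh a `TriMesh`
#' @param scale scalar or length-3 scale
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 vector (mm)
#' @export
mesh_transform <- function(mesh, scale = 1, rotation = diag(3), translation = c(0, 0, 0)) {
  s <- rep(scale, length.out = 3)
  V <- sweep(mesh$vertices, 2, s, "*") %*% t(rotation)
  V <- sweep(V, 2, translation, "+")
  tri_mesh(V, mesh$faces)
}

transform_points <- function(P, scale = 1, rotation = diag(3), translation = c(0, 0, 0)) {
  s <- rep(scale, length.out = 3)
  sweep(sweep(P, 2, s, "*") %*% t(rotation), 2, translation, "+")
}
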