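#' Icosphere primitive
#'
#' Recursively subdivided icosahedron projected onto a sphere. Used throughout
#' the test suite as an analytic oracle surface.
#'
#' @param radius sphere radius (mm)
#' @param center length-3 center (mm)
#' @param subdivisions number of 4-to-1 subdivision rounds (0 = icosahedron)
#' @return a watertight `TriMesh`
#' @export
make_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  V <- V / sqrt(rowSums(V^2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      m <- (V[i, ] + V[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1L]] <<- m
      id <- nv + length(newV)
      midcache[[key]] <- id
      id
    }
    newF <- matrix(0L, nrow(F) * 4, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; cc <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[(f - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca)
      )
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  V <- V * radius
  V <- sweep(V, 2, center, "+")
  tri_mesh(V, F)
}

#' Closed cylinder primitive along +z
#'
#' @param radius cylinder radius (mm)
#' @param height cylinder height (mm), base at z = 0
#' @param n_theta azimuthal resolution
#' @param n_z number of rings along the axis
#' @return a watertight `TriMesh`
#' @export
make_cylinder <- function(radius = 20, height = 100, n_theta = 48, n_z = 10) {
  make_tube(
    z_levels = seq(0, height, length.out = n_z),
    radius_fun = function(theta, z) rep(radius, length(theta)),
    n_theta = n_theta
  )
}

#' Closed tube of revolution with an arbitrary radius field
#'
#' Surface parameterized by rings at `z_levels` and `n_theta` angular samples,
#' closed by fan caps through pole vertices on the axis. The workhorse behind
#' the synthetic bone templates.
#'
#' @param z_levels increasing z positions of the rings (mm)
#' @param radius_fun function(theta, z) -> radii (mm), vectorized over theta
#' @param n_theta azimuthal resolution
#' @return a watertight `TriMesh`; vertex 1 and 2 are the distal (z min) and
#'   proximal (z max) poles, ring vertices follow ring-major
#' @export
make_tube <- function(z_levels, radius_fun, n_theta = 44) {
  nz <- length(z_levels)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  V <- matrix(0, 2 + nz * n_theta, 3)
  V[1, ] <- c(0, 0, z_levels[1])
  V[2, ] <- c(0, 0, z_levels[nz])
  for (i in seq_len(nz)) {
    r <- radius_fun(theta, z_levels[i])
    idx <- 2 + (i - 1) * n_theta + seq_len(n_theta)
    V[idx, ] <- cbind(r * cos(theta), r * sin(theta), z_levels[i])
  }
  ring <- function(i) 2 + (i - 1) * n_theta + seq_len(n_theta)
  F <- matrix(0L, 2 * n_theta * (nz - 1) + 2 * n_theta, 3)
  nf <- 0L
  for (i in seq_len(nz - 1)) {
    r0 <- ring(i)
    r1 <- ring(i + 1)
    for (j in seq_len(n_theta)) {
      jn <- if (j == n_theta) 1L else j + 1L
      F[nf + 1L, ] <- c(r0[j], r0[jn], r1[j])
      F[nf + 2L, ] <- c(r0[jn], r1[jn], r1[j])
      nf <- nf + 2L
    }
  }
  r0 <- ring(1)
  r1 <- ring(nz)
  for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    F[nf + 1L, ] <- c(1L, r0[jn], r0[j])     # distal cap, outward = -z
    F[nf + 2L, ] <- c(2L, r1[j], r1[jn])     # proximal cap, outward = +z
    nf <- nf + 2L
  }
  tri_mesh(V, F)
}
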