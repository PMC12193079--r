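# Synthetic femur/tibia generator: parametric templates with analytic
# landmarks, a smooth orthonormal deformation basis for population variation,
# osteophyte bumps, extremity cropping and pseudo-CT rasterization. Serves as
# ground truth for every downstream stage.

femur_landmark_spec <- function(L) {
  # (theta deg, z mm) targets; theta 0 = lateral (+x), 90 = anterior (+y)
  list(
    MedialPosterior   = c(225, 12),
    LateralPosterior  = c(315, 12),
    MedialDistal      = c(225, 4),
    LateralDistal     = c(315, 4),
    MedialEpicondyle  = c(180, 30),
    LateralEpicondyle = c(0, 30),
    MedialAnterior    = c(140, 32),
    LateralAnterior   = c(40, 32),
    TopGroove         = c(90, 40),
    TopNotch          = c(270, 16),
    APSizingPoint     = c(90, 55),
    FemoralHeadCenter = c(180, L - 18)
  )
}

tibia_landmark_spec <- function(L) {
  list(
    KneeCenter          = c(NA, NA),     # proximal pole vertex
    AnkleJointCenter    = c(NA, NA),     # distal pole vertex
    MedialWearPoint     = c(200, L - 4),
    LateralWearPoint    = c(340, L - 4),
    MedialCondyleCenter = c(200, L - 10),
    LateralCondyleCenter = c(340, L - 10)
  )
}

ang_diff <- function(theta, center) {
  d <- (theta - center) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

bump <- function(theta, z, h, theta_c_deg, z_c, sig_theta_deg, sig_z) {
  dth <- ang_diff(theta, theta_c_deg * pi / 180)
  h * exp(-(dth / (sig_theta_deg * pi / 180))^2 - ((z - z_c) / sig_z)^2)
}

femur_radius <- function(theta, z, L) {
  r <- 14 + 20 * exp(-(z / 40)^2) + 7 * exp(-((z - L) / 50)^2)
  r <- r + bump(theta, z, 12, 225, 14, 35, 16)     # medial posterior condyle
  r <- r + bump(theta, z, 11, 315, 14, 35, 16)     # lateral posterior condyle
  r <- r + bump(theta, z, -7, 90, 28, 25, 22)      # trochlear groove
  r <- r + bump(theta, z, 4, 180, 30, 20, 12)      # medial epicondyle
  r <- r + bump(theta, z, 4, 0, 30, 20, 12)        # lateral epicondyle
  r <- r + bump(theta, z, 26, 180, L - 18, 40, 22) # femoral head
  r <- r + bump(theta, z, 10, 0, L - 8, 30, 14)    # greater trochanter
  r
}

tibia_radius <- function(theta, z, L) {
  r <- 13 + 18 * exp(-((z - L) / 35)^2) + 5 * exp(-(z / 40)^2)
  r <- r + bump(theta, z, 9, 200, L - 6, 45, 12)   # medial plateau lobe
  r <- r + bump(theta, z, 6, 340, L - 6, 45, 12)   # lateral plateau lobe
  r <- r + bump(theta, z, 8, 90, L - 45, 22, 18)   # tibial tuberosity
  r <- r + bump(theta, z, 9, 180, 8, 30, 12)       # medial malleolus
  r
}

#' Deterministic femur/tibia template with analytic landmarks
#'
#' Right-side bone in the package coordinate frame (+z proximal, +y anterior,
#' +x lateral): a tapered tube blended with joint-end primitives (femur:
#' posterior condylar bumps, trochlear groove, head sphere, greater
#' trochanter; tibia: plateau lobes, tuberosity, medial malleolus). Every
#' landmark is attached to a mesh vertex, so it lies exactly on the surface
#' and is carried exactly by any vertex deformation field.
#'
#' @param bone_kind `"femur"` or `"tibia"`
#' @param n_theta azimuthal resolution of the template tube
#' @param n_z number of rings along the long axis
#' @return a `GroundTruthBone`: list with `mesh` (`TriMesh`), `landmarks`
#'   (`LandmarkSet`), `landmark_vidx` (vertex attachment), `latent`,
#'   `bone_kind`, `side`, `seed`, `length_mm`
#' @export
make_template <- function(bone_kind = c("femur", "tibia"), n_theta = 44L, n_z = 57L) {
  bone_kind <- match.arg(bone_kind)
  L <- if (bone_kind == "femur") 380 else 360
  rfun <- if (bone_kind == "femur") {
    function(theta, z) femur_radius(theta, z, L)
  } else {
    function(theta, z) tibia_radius(theta, z, L)
  }
  zl <- seq(0, L, length.out = n_z)
  mesh <- make_tube(zl, rfun, n_theta = n_theta)

  spec <- if (bone_kind == "femur") femur_landmark_spec(L) else tibia_landmark_spec(L)
  vidx <- integer(length(spec))
  names(vidx) <- names(spec)
  for (nm in names(spec)) {
    tz <- spec[[nm]]
    if (nm == "KneeCenter") { vidx[nm] <- 2L; next }       # proximal pole
    if (nm == "AnkleJointCenter") { vidx[nm] <- 1L; next } # distal pole
    i <- which.min(abs(zl - tz[2]))
    theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    j <- which.min(ang_diff(theta, tz[1] * pi / 180))
    vidx[nm] <- 2L + (i - 1L) * n_theta + j
  }
  lms <- landmark_set(names(vidx), mesh$vertices[vidx, , drop = FALSE],
                      default_risk_weights(names(vidx)))
  structure(list(
    mesh = mesh, landmarks = lms, landmark_vidx = vidx,
    latent = numeric(0), bone_kind = bone_kind, side = "right",
    seed = NA_integer_, length_mm = L, scale = 1
  ), class = "GroundTruthBone")
}

#' @export
print.GroundTruthBone <- function(x, ...) {
  cat(sprintf("GroundTruthBone: %s (%s), %d vertices, %d landmarks\n",
              x$bone_kind, x$side, nrow(x$mesh$vertices), length(x$landmarks$names)))
  invisible(x)
}

default_risk_weights <- function(names, cfg = default_config()$morpho) {
  w <- rep(cfg$default_risk_weight, length(names))
  for (i in seq_along(names)) {
    if (!is.null(cfg$risk_weights[[names[i]]])) w[i] <- cfg$risk_weights[[names[i]]]
  }
  w
}

# Smooth deformation basis: low-order polynomial vector fields of normalized
# coordinates, evaluated at the template vertices and Gram-Schmidt
# orthonormalized so that a unit coefficient produces 1 mm RMS per-vertex
# displacement.
smooth_basis_fields <- function(template, k_latent) {
  V <- template$mesh$vertices
  nv <- nrow(V)
  zr <- range(V[, 3])
  xt <- V[, 1] / 50
  yt <- V[, 2] / 50
  zt <- 2 * (V[, 3] - zr[1]) / (zr[2] - zr[1]) - 1
  zero <- rep(0, nv)
  # every entry keeps a substantial surface-normal component on a tubular
  # shape; near-tangential fields (pure lengthening, torsion, axial shear)
  # are deliberately absent because they mostly re-parameterize the surface,
  # which would make the latent coefficients unrecoverable from geometry
  catalogue <- list(
    cbind(zt, zero, zero),                # bend in x
    cbind(zero, zt, zero),                # bend in y
    cbind(xt, yt, zero),                  # transverse inflation
    cbind(xt * zt, yt * zt, zero),        # taper
    cbind(zt^2, zero, zero),              # C-bow in x
    cbind(zero, zt^2, zero),              # C-bow in y
    cbind(xt * (1 - zt^2), yt * (1 - zt^2), zero),  # mid-shaft bulge
    cbind(1 - zt^2, zero, zero),          # mid-shaft shift in x
    cbind(zero, 1 - zt^2, zero),          # mid-shaft shift in y
    cbind(xt * zt^2, yt * zt^2, zero),    # end-weighted inflation
    cbind(xt * yt, zero, zero),           # oblique transverse pattern
    cbind(zero, xt * yt, zero)            # oblique transverse pattern (y)
  )
  if (k_latent > length(catalogue)) {
    stop(sprintf("k_latent must be <= %d", length(catalogue)))
  }
  fields <- matrix(0, 3 * nv, k_latent)
  ip <- function(u, v) sum(u * v) / nv
  for (m in seq_len(k_latent)) {
    f <- as.vector(catalogue[[m]])
    if (m > 1) {
      for (p in seq_len(m - 1)) f <- f - ip(f, fields[, p]) * fields[, p]
    }
    nrm <- sqrt(ip(f, f))
    if (nrm < 1e-12) stop("degenerate basis field")
    fields[, m] <- f / nrm
  }
  fields
}

#' Sample a synthetic bone population in exact correspondence
#'
#' Each member shares the template topology and is deformed by a linear
#' combination of `k_latent` fixed smooth orthonormal basis fields with
#' i.i.d. normal(0, sd^2) coefficients, followed by a recorded global
#' isotropic scale jitter (uniform over the configured range). Landmarks ride
#' on their attachment vertices, so generator correspondence is exact.
#'
#' @param template a `GroundTruthBone` from [make_template()]
#' @param n number of members (>= 2)
#' @param k_latent latent dimension (1..12)
#' @param sd coefficient standard deviation (mm RMS surface displacement
#'   per unit coefficient)
#' @param seed integer seed
#' @param scale_jitter logical; apply the uniform(0.92, 1.08) scale jitter
#' @return list of `GroundTruthBone`
#' @export
sample_population <- function(template, n, k_latent = 6L, sd = 2, seed = 1L,
                              scale_jitter = TRUE) {
  if (n < 2) stop("n must be >= 2")
  if (k_latent < 1) stop("k_latent must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  fields <- smooth_basis_fields(template, k_latent)
  nv <- nrow(template$mesh$vertices)
  jrange <- default_config()$synth$scale_jitter
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  coeff <- matrix(stats::rnorm(n * k_latent, 0, sd), n, k_latent)
  scales <- if (scale_jitter) stats::runif(n, jrange[1], jrange[2]) else rep(1, n)
  lapply(seq_len(n), function(i) {
    disp <- matrix(fields %*% coeff[i, ], nv, 3)
    V <- template$mesh$vertices + disp
    ctr <- colMeans(V)
    V <- sweep(sweep(V, 2, ctr, "-") * scales[i], 2, ctr, "+")
    mesh <- tri_mesh(V, template$mesh$faces)
    lm_pts <- V[template$landmark_vidx, , drop = FALSE]
    lms <- landmark_set(template$landmarks$names, lm_pts, template$landmarks$weights)
    structure(list(
      mesh = mesh, landmarks = lms, landmark_vidx = template$landmark_vidx,
      latent = coeff[i, ], bone_kind = template$bone_kind, side = template$side,
      seed = as.integer(seed), length_mm = template$length_mm, scale = scales[i]
    ), class = "GroundTruthBone")
  })
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Add osteophyte-like bumps near the joint margins
#'
#' 3-8 localized radial (vertex-normal) bumps with Gaussian profiles, radius
#' 4-10 mm and height up to `6 * severity` mm, centered at joint-margin
#' vertices. Landmark coordinates are deliberately NOT displaced: osteophytes
#' are what the model fitting must ignore.
#'
#' @param bone a `GroundTruthBone`
#' @param severity in [0, 1]
#' @param seed integer seed
#' @return a new `GroundTruthBone` flagged `pathological`; the attribute
#'   `max_displacement` records the largest applied vertex displacement (mm)
#' @export
add_osteophytes <- function(bone, severity, seed = 1L) {
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  V <- bone$mesh$vertices
  out <- bone
  if (severity == 0) {
    attr(out, "max_displacement") <- 0
    return(out)
  }
  zr <- range(V[, 3])
  L <- zr[2] - zr[1]
  margin <- if (bone$bone_kind == "femur") {
    which(V[, 3] < zr[1] + 0.15 * L & V[, 3] > zr[1] + 0.01 * L)
  } else {
    which(V[, 3] > zr[2] - 0.15 * L & V[, 3] < zr[2] - 0.01 * L)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n_bumps <- sample(3:8, 1)
  centers <- sample(margin, n_bumps)
  radii <- stats::runif(n_bumps, 4, 10)
  heights <- stats::runif(n_bumps, 0.3, 1) * 6 * severity
  normals <- mesh_vertex_normals(bone$mesh)
  total <- rep(0, nrow(V))
  for (b in seq_len(n_bumps)) {
    d <- sqrt(rowSums(sweep(V, 2, V[centers[b], ], "-")^2))
    total <- total + heights[b] * exp(-(d / (radii[b] / 2))^2)
  }
  out$mesh <- tri_mesh(V + normals * total, bone$mesh$faces)
  out$pathological <- TRUE
  attr(out, "max_displacement") <- max(total)
  out
}

#' Crop a bone mesh to proximal/distal extremities
#'
#' Splits along the longitudinal (z) extent: faces whose centroids lie in the
#' top `proximal_frac` of the z-range go to the proximal part, those in the
#' bottom `distal_frac` to the distal part. Open boundaries at the crop planes
#' are permitted, mirroring clinical acquisitions restricted to the joints.
#'
#' @param mesh a `TriMesh`
#' @param proximal_frac,distal_frac fractions in (0, 1], summing to <= 1
#' @return list with `proximal` and `distal` `TriMesh`
#' @export
crop_extremities <- function(mesh, proximal_frac = 0.3, distal_frac = 0.3) {
  if (proximal_frac <= 0 || distal_frac <= 0 || proximal_frac + distal_frac > 1) {
    stop("fractions must be positive and sum to <= 1")
  }
  cz <- mesh_face_data(mesh)$centroids[, 3]
  zr <- range(mesh$vertices[, 3])
  span <- zr[2] - zr[1]
  keep_p <- cz >= zr[2] - proximal_frac * span
  keep_d <- cz <= zr[1] + distal_frac * span
  list(
    proximal = mesh_drop_unreferenced(tri_mesh(mesh$vertices, mesh$faces[keep_p, , drop = FALSE])),
    distal = mesh_drop_unreferenced(tri_mesh(mesh$vertices, mesh$faces[keep_d, , drop = FALSE]))
  )
}

#' Rasterize bones into a pseudo-CT volume and paired label mask
#'
#' Voxel centers inside a bone take the cortical-shell intensity (700 HU) on
#' the outer 2-voxel rim and the interior intensity (300 HU) inside it;
#' background is 40 HU; additive Gaussian noise with `noise_sd`. The label
#' mask is noise-free ground truth (1 = femur, 2 = tibia).
#'
#' @param bones list of `GroundTruthBone` (or lists with `mesh`, `bone_kind`)
#' @param spacing scalar or length-3 voxel spacing (mm)
#' @param noise_sd additive Gaussian noise sd (HU)
#' @param seed integer seed for the noise
#' @param zlim optional z window (mm) emulating a joint-limited acquisition
#' @param pad padding around the bone bounding box (mm)
#' @return list with `volume` (`CTVolume`) and `mask` (`LabelMask`)
#' @export
rasterize_ct <- function(bones, spacing = 1, noise_sd = 0, seed = 1L,
                         zlim = NULL, pad = 10) {
  if (length(bones) == 0) stop("empty bone list")
  if (any(spacing <= 0)) stop("spacing must be positive")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  scfg <- default_config()$synth
  allV <- do.call(rbind, lapply(bones, function(b) b$mesh$vertices))
  lo <- apply(allV, 2, min) - pad
  hi <- apply(allV, 2, max) + pad
  if (!is.null(zlim)) {
    lo[3] <- max(lo[3], zlim[1])
    hi[3] <- min(hi[3], zlim[2])
  }
  dims <- pmax(as.integer(floor((hi - lo) / spacing)) + 1L, 2L)
  origin <- lo
  labels <- array(0L, dims)
  inten <- array(scfg$background_hu, dims)
  for (b in bones) {
    lab <- if (b$bone_kind == "femur") 1L else 2L
    inside <- cpp_voxelize(b$mesh$vertices, b$mesh$faces, origin, spacing, dims)
    interior <- cpp_erode6(inside, dims, scfg$shell_voxels)
    inten[inside == 1L] <- scfg$shell_hu
    inten[interior == 1L] <- scfg$interior_hu
    labels[inside == 1L] <- lab
  }
  if (noise_sd > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    inten <- inten + array(stats::rnorm(length(inten), 0, noise_sd), dims)
  }
  list(
    volume = ct_volume(inten, spacing, origin),
    mask = label_mask(labels, spacing, origin)
  )
}

#' Translate a ground-truth bone (mesh and landmarks together)
#' @param bone a `GroundTruthBone`
#' @param t length-3 translation (mm)
#' @export
translate_bone <- function(bone, t) {
  bone$mesh <- tri_mesh(sweep(bone$mesh$vertices, 2, t, "+"), bone$mesh$faces)
  bone$landmarks <- landmark_set(bone$landmarks$names,
                                 sweep(bone$landmarks$points, 2, t, "+"),
                                 bone$landmarks$weights)
  bone
}

#' Assemble a knee scene from a femur and a tibia
#'
#' Positions the femur above the tibia with a `gap` mm joint space and
#' reports the z window of a knee-limited acquisition covering the distal
#' `frac` of the femur and proximal `frac` of the tibia.
#'
#' @param femur,tibia `GroundTruthBone`s in their native frames
#' @param gap joint-space gap (mm)
#' @param frac fraction of each bone inside the knee field of view
#' @return list with translated `femur`, `tibia`, and `knee_window` (z range)
#' @export
knee_scene <- function(femur, tibia, gap = 4, frac = 0.3) {
  fz <- range(femur$mesh$vertices[, 3])
  tz <- range(tibia$mesh$vertices[, 3])
  femur2 <- translate_bone(femur, c(0, 0, gap / 2 - fz[1]))
  tibia2 <- translate_bone(tibia, c(0, 0, -gap / 2 - tz[2]))
  Lf <- fz[2] - fz[1]
  Lt <- tz[2] - tz[1]
  list(
    femur = femur2, tibia = tibia2,
    knee_window = c(-gap / 2 - frac * Lt, gap / 2 + frac * Lf)
  )
}
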