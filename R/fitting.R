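# Three-stage reconstruction of full bones from cropped proximal/distal
# extremities: bounding-box scaling, globally initialized rigid/similarity
# ICP, and ridge-regularized, trimmed (osteophyte-robust) mode fitting.

#' Partial observation of a bone (two cropped extremities)
#' @param proximal,distal open `TriMesh` pieces (mm, patient space)
#' @param bone_kind `"femur"` or `"tibia"`
#' @param side `"right"` or `"left"`
#' @return a `PartialObservation`
#' @export
partial_observation <- function(proximal, distal, bone_kind = "femur", side = "right") {
  if (nrow(proximal$vertices) == 0 || nrow(distal$vertices) == 0) {
    stop("both extremities must be non-empty")
  }
  structure(list(proximal = proximal, distal = distal,
                 bone_kind = bone_kind, side = side),
            class = "PartialObservation")
}

merge_meshes <- function(a, b) {
  tri_mesh(rbind(a$vertices, b$vertices),
           rbind(a$faces, b$faces + nrow(a$vertices)))
}

# longitudinal axis of a partial observation: unit vector from the distal
# piece centroid to the proximal piece centroid (equivariant, sign-stable)
partial_axis <- function(partial) {
  u <- colMeans(partial$proximal$vertices) - colMeans(partial$distal$vertices)
  n <- sqrt(sum(u^2))
  if (!is.finite(n) || n < 1e-9) stop("degenerate input: zero extent between extremities")
  u / n
}

# extents used by the bounding-box scale stage: longitudinal extent over both
# pieces along the piece-centroid axis, transverse extents of the distal
# piece along its principal directions orthogonal to that axis (sorted
# descending). The same procedure runs on model and data, so a partial cut
# from the model itself yields ratios of exactly 1.
partial_extents <- function(partial) {
  u <- partial_axis(partial)
  allv <- rbind(partial$proximal$vertices, partial$distal$vertices)
  long <- diff(range(allv %*% u))
  # cross-section widths come from the plane-projected points; raw points
  # would leak longitudinal spread into the transverse extents when a piece
  # is bent or tilted relative to the global axis
  widths <- function(piece) {
    pc <- sweep(piece$vertices, 2, colMeans(piece$vertices))
    pperp <- pc - (pc %*% u) %*% t(u)
    ev <- eigen(crossprod(pperp) / nrow(pperp), symmetric = TRUE)
    list(trans = sort(c(diff(range(pperp %*% ev$vectors[, 1])),
                        diff(range(pperp %*% ev$vectors[, 2]))),
                      decreasing = TRUE),
         axes = ev$vectors[, 1:2, drop = FALSE])
  }
  wd <- widths(partial$distal)
  wp <- widths(partial$proximal)
  list(long = long, trans = wd$trans, trans_prox = wp$trans,
       axis = u, trans_axes = wd$axes)
}

model_partial <- function(model, frac = c(0.3, 0.3)) {
  mean_mesh <- synthesize(model)$mesh
  cr <- crop_extremities(mean_mesh, frac[1], frac[2])
  partial_observation(cr$proximal, cr$distal, model$bone_kind %||% "femur")
}

#' Initial per-axis scale from bounding-box extents
#'
#' Ratio of the partial data's longitudinal extent (across both pieces,
#' along the piece-centroid axis) and the distal piece's two transverse
#' extents to the matching extents of the model mean cropped the same way.
#' Larger transverse extent is matched to larger.
#'
#' @param model a `ShapeModel`
#' @param partial a `PartialObservation`
#' @param frac crop fractions assumed when cropping the model mean
#' @return length-3 scale (x, y, z) in model axes
#' @export
init_scale <- function(model, partial, frac = c(0.3, 0.3)) {
  pe <- partial_extents(partial)
  if (pe$long < 1e-9 || any(pe$trans < 1e-9)) stop("degenerate input: zero extent")
  me <- partial_extents(model_partial(model, frac))
  sz <- pe$long / me$long
  # transverse ratios measured by the identical procedure on both sides
  # (sorted principal cross-section extents), averaged over the two pieces so
  # a locally atypical joint end cannot dictate the global scale, then
  # clamped to a moderate anisotropy around the longitudinal ratio (the
  # deformation modes absorb the remainder)
  s1 <- (pe$trans[1] / me$trans[1] + pe$trans_prox[1] / me$trans_prox[1]) / 2
  s2 <- (pe$trans[2] / me$trans[2] + pe$trans_prox[2] / me$trans_prox[2]) / 2
  s1 <- min(max(s1, 0.8 * sz), 1.25 * sz)
  s2 <- min(max(s2, 0.8 * sz), 1.25 * sz)
  ax1 <- me$trans_axes[, 1]
  if (abs(ax1[1]) >= abs(ax1[2])) c(s1, s2, sz) else c(s2, s1, sz)
}

#' Rigid/similarity registration of the scaled mean to partial data
#'
#' Point-to-surface ICP between the scaled mean's proximal/distal thirds and
#' the partial surfaces. Globally initialized from the partial's longitudinal
#' axis and transverse principal directions; all four azimuthal sign
#' candidates and both z-orientations are scored by a short ICP and the best
#' is refined, which defuses the 180-degree flip trap.
#'
#' @param model a `ShapeModel`
#' @param partial a `PartialObservation`
#' @param scale3 per-axis scale from [init_scale()]
#' @param cfg fitting configuration
#' @param top_k number of refined candidate poses kept per longitudinal
#'   orientation (default 1; with 1 the single best pose is returned)
#' @return list with `R`, `t`, `s_iso`, `rmse` (mm); with `top_k > 1`, a list
#'   of refined poses (both orientations represented) sorted by residual
#' @export
rigid_register <- function(model, partial, scale3 = c(1, 1, 1),
                           cfg = default_config()$fitting, top_k = 1L,
                           frac = c(0.3, 0.3)) {
  target <- merge_meshes(partial$proximal, partial$distal)
  Vm <- sweep(synthesize(model)$mesh$vertices, 2, scale3, "*")
  zr <- range(Vm[, 3])
  span <- zr[2] - zr[1]
  # sample points inside the assumed observed extremity fractions, inset by a
  # margin at the crop-plane side only (the anatomical ends stay in play)
  mrg <- cfg$crop_margin_mm
  sel <- Vm[, 3] <= zr[1] + frac[2] * span - mrg |
         Vm[, 3] >= zr[2] - frac[1] * span + mrg
  if (sum(sel) < 50) sel <- rep(TRUE, nrow(Vm))
  X <- Vm[sel, , drop = FALSE]

  pe <- partial_extents(partial)
  u <- pe$axis
  v1 <- pe$trans_axes[, 1]
  v1 <- v1 - sum(v1 * u) * u
  v1 <- v1 / sqrt(sum(v1^2))
  w <- c(u[2] * v1[3] - u[3] * v1[2],
         u[3] * v1[1] - u[1] * v1[3],
         u[1] * v1[2] - u[2] * v1[1])
  tc <- colMeans(rbind(partial$proximal$vertices, partial$distal$vertices))

  icp <- function(Xp, R0, t0, iters, with_scale = TRUE, s0 = 1) {
    tr <- list(s = s0, R = R0, t = t0)
    P <- apply_similarity(Xp, tr)
    for (it in seq_len(iters)) {
      m <- point_mesh_distance(P, target)
      tr <- procrustes_similarity(Xp, m$closest, scale = with_scale)
      Pn <- apply_similarity(Xp, tr)
      if (sqrt(mean((Pn - P)^2)) < cfg$icp_tol) {
        P <- Pn
        break
      }
      P <- Pn
    }
    list(tr = tr, rmse = sqrt(mean(point_mesh_distance(P, target)$dist^2)))
  }

  # candidates: both longitudinal orientations x 8 azimuths about the axis
  # (azimuth is weakly determined by near-tubular cross-sections, so a sweep
  # beats trusting the transverse principal direction). Each candidate gets a
  # short subsampled ICP and a SYMMETRIC score: forward residual plus the
  # residual of the data to the posed model - a wrong azimuth can hug the
  # data one-way while leaving lobes unexplained, which only the reverse
  # direction exposes. The `top_k` best are refined on all points so the
  # deformation stage can disambiguate what remains.
  Xs <- X[seq(1, nrow(X), by = max(1L, nrow(X) %/% 400L)), , drop = FALSE]
  tv_all <- target$vertices
  Ts <- tv_all[seq(1, nrow(tv_all), by = max(1L, nrow(tv_all) %/% 400L)), , drop = FALSE]
  mean_mesh_s <- tri_mesh(Vm, synthesize(model)$mesh$faces)
  cands <- list()
  scores <- numeric(0)
  orient <- integer(0)
  oi <- 0L
  for (uz in list(u, -u)) {
    oi <- oi + 1L
    for (phi in seq(0, 2 * pi, length.out = 9)[-9]) {
      a <- cos(phi) * v1 + sin(phi) * w
      a <- a - sum(a * uz) * uz
      a <- a / sqrt(sum(a^2))
      b <- c(uz[2] * a[3] - uz[3] * a[2],
             uz[3] * a[1] - uz[1] * a[3],
             uz[1] * a[2] - uz[2] * a[1])
      R0 <- cbind(a, b, uz)
      t0 <- tc - as.vector(R0 %*% colMeans(X))
      cand <- icp(Xs, R0, t0, iters = 8)
      posed <- mesh_transform(mean_mesh_s, cand$tr$s, cand$tr$R, cand$tr$t)
      rev_rmse <- sqrt(mean(point_mesh_distance(Ts, posed)$dist^2))
      cands[[length(cands) + 1]] <- cand
      scores <- c(scores, cand$rmse + rev_rmse)
      orient <- c(orient, oi)
    }
  }
  # refine the best candidates of EACH longitudinal orientation: for unusual
  # shapes the upside-down pose can out-score the true one on rigid
  # residuals, and only the later deformation stage can tell them apart
  pick <- c(
    which(orient == 1L)[order(scores[orient == 1L])][seq_len(min(top_k, 8L))],
    which(orient == 2L)[order(scores[orient == 2L])][seq_len(min(top_k, 8L))]
  )
  raw <- lapply(cands, function(cc)
    list(R = cc$tr$R, t = cc$tr$t, s_iso = cc$tr$s, rmse = cc$rmse))
  # longitudinal anchoring: ICP can slide along the near-cylindrical shaft,
  # but the two pieces span the bone's full length, so the z placement is
  # determined - recenter the pulled-back data range onto the model range
  zmr <- range(Vm[, 3])
  anchor_z <- function(tr) {
    tv <- rbind(partial$proximal$vertices, partial$distal$vertices)
    zp <- range((sweep(tv, 2, tr$t) %*% tr$R)[, 3] / tr$s)
    dz <- mean(zmr) - mean(zp)
    tr$t <- tr$t - tr$s * as.vector(tr$R %*% c(0, 0, dz))
    tr
  }
  # point-to-plane Gauss-Newton polish: closest-point ICP converges slowly in
  # the shaft's sliding directions; the linearized normal-distance solve with
  # a tiny damping (which leaves the sliding null space untouched) finishes
  # the pose to numerical precision
  fd_target <- mesh_face_data(target)
  polish <- function(tr) {
    for (it in 1:10) {
      P <- apply_similarity(X, tr)
      m <- point_mesh_distance(P, target)
      n <- fd_target$normals[m$tri, , drop = FALSE]
      r <- rowSums((P - m$closest) * n)
      J <- cbind(
        P[, 2] * n[, 3] - P[, 3] * n[, 2],
        P[, 3] * n[, 1] - P[, 1] * n[, 3],
        P[, 1] * n[, 2] - P[, 2] * n[, 1],
        n
      )
      delta <- tryCatch(solve(crossprod(J) + 1e-8 * diag(6), -crossprod(J, r)),
                        error = function(e) rep(0, 6))
      w <- delta[1:3]
      th <- sqrt(sum(w^2))
      Rd <- if (th < 1e-14) diag(3) else {
        K <- rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0)) / th
        diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      }
      tr$R <- Rd %*% tr$R
      tr$t <- as.vector(Rd %*% tr$t) + delta[4:6]
      if (max(abs(delta)) < 1e-12) break
    }
    tr
  }
  poses <- list()
  for (idx in pick) {
    ref <- icp(X, cands[[idx]]$tr$R, cands[[idx]]$tr$t, iters = cfg$icp_max_iter)
    tr <- anchor_z(polish(ref$tr))
    P <- apply_similarity(X, tr)
    rmse <- sqrt(mean(point_mesh_distance(P, target)$dist^2))
    poses[[length(poses) + 1]] <- list(R = tr$R, t = tr$t,
                                       s_iso = tr$s, rmse = rmse)
  }
  poses <- poses[order(vapply(poses, function(p) p$rmse, numeric(1)))]
  if (poses[[1]]$rmse > cfg$register_fail_mm) {
    stop(sprintf("registration failure: residual %.1f mm > %.1f mm",
                 poses[[1]]$rmse, cfg$register_fail_mm))
  }
  if (top_k == 1) return(poses[[1]])
  attr(poses, "raw_candidates") <- raw
  poses
}

#' Robust regularized mode fitting to partial data
#'
#' Alternates: (1) match model vertices lying inside the observed
#' longitudinal ranges to closest points on the partial surfaces; (2) discard
#' matches beyond `match_cap_mm` and the `trim_frac` largest residuals
#' (robustness to osteophytes); (3) solve the ridge-regularized least squares
#' for the mode coefficients b (Mahalanobis prior in sd units) and refresh
#' the similarity pose. Stops when the coefficient update drops below
#' `dB_tol` or after `iters` iterations.
#'
#' @param model a truncated `ShapeModel`
#' @param partial a `PartialObservation`
#' @param pose output of [rigid_register()]
#' @param scale3 per-axis scale from [init_scale()]
#' @param ridge ridge weight on b (default 1)
#' @param trim_frac fraction of worst matches discarded (default 0.10)
#' @param iters maximum alternations (default 15)
#' @param cfg fitting configuration
#' @return a `FitResult`: similarity pose, coefficients `b`, `reconstructed`
#'   mesh and `landmarks` in patient space, `residual_rmse`, `inlier_fraction`
#' @export
deform_fit <- function(model, partial, pose, scale3 = c(1, 1, 1),
                       ridge = 1.0, trim_frac = 0.10, iters = 40L,
                       refine_pose = TRUE, b_init = NULL,
                       cfg = default_config()$fitting) {
  target <- merge_meshes(partial$proximal, partial$distal)
  N <- length(model$variances)
  nV <- model$V
  sqrtl <- sqrt(model$variances)
  mean_v <- model$mean[seq_len(3 * nV)]
  modes_v <- model$modes[seq_len(3 * nV), , drop = FALSE]

  s_iso <- pose$s_iso
  R <- pose$R
  t <- pose$t
  b <- if (is.null(b_init)) rep(0, N) else as.numeric(b_init)

  to_patient <- function(Vm) {
    sweep(s_iso * sweep(Vm, 2, scale3, "*") %*% t(R), 2, t, "+")
  }
  model_z <- function(piece) {
    # observed z-range of a piece pulled back into the (unscaled) model frame
    Pm <- sweep(sweep(piece$vertices, 2, t) %*% R, 2, scale3 * s_iso, "/")
    range(Pm[, 3])
  }
  # margin insets only the crop-plane side of each window; the anatomical end
  # caps carry the length information and stay matched (slight overshoot past
  # the data end is allowed so an over-long model is pulled back)
  mrg <- cfg$crop_margin_mm
  # the warm phase (no trimming, generous cap) runs until the coefficient
  # updates settle: residual trimming only separates osteophytes from honest
  # misfit once the shape is close, so engaging it earlier destabilizes hard
  # cases

  res <- NA_real_
  inlier <- NA_real_
  robust <- FALSE
  db_last <- Inf
  trim_ids <- NULL
  for (it in seq_len(iters)) {
    zr_p <- model_z(partial$proximal)
    zr_d <- model_z(partial$distal)
    verts <- vec_to_shape(mean_v + as.vector(modes_v %*% (b * sqrtl)))
    inside <- (verts[, 3] >= zr_p[1] + mrg & verts[, 3] <= zr_p[2] + mrg) |
              (verts[, 3] >= zr_d[1] - mrg & verts[, 3] <= zr_d[2] - mrg)
    sel <- which(inside)
    P <- to_patient(verts[sel, , drop = FALSE])
    m <- point_mesh_distance(P, target)
    if (!robust && it > 3 && (db_last < 50 * cfg$dB_tol || it > iters %/% 2)) {
      robust <- TRUE
    }
    cap <- if (robust) cfg$match_cap_mm else 3 * cfg$match_cap_mm
    keep <- m$dist <= cap
    if (robust && trim_frac > 0) {
      if (is.null(trim_ids)) {
        # osteophyte-aware trimming, decided once at the start of the robust
        # phase and frozen by vertex id: only matches far above the typical
        # residual level are trimmable, so accurate but informative regions
        # (joint ends, condyles) are never sacrificed on clean bone, and a
        # stable exclusion set keeps the alternation from oscillating
        floor_mm <- max(3 * stats::quantile(m$dist, 0.90, names = FALSE), 1.0)
        trimmable <- which(keep & m$dist > floor_mm)
        n_trim <- min(length(trimmable), floor(trim_frac * length(m$dist)))
        trim_ids <- if (n_trim > 0) {
          sel[trimmable[order(m$dist[trimmable], decreasing = TRUE)][seq_len(n_trim)]]
        } else integer(0)
      }
      keep <- keep & !(sel %in% trim_ids)
    }
    if (sum(keep) < cfg$min_matches) {
      stop(sprintf("insufficient overlap: %d surviving matches", sum(keep)))
    }
    inlier <- mean(keep)
    ks <- sel[keep]
    Tp <- m$closest[keep, , drop = FALSE]
    # pull targets back to the model frame and solve for b
    Tm <- sweep(sweep(Tp, 2, t) %*% R, 2, scale3 * s_iso, "/")
    rows <- as.vector(t(matrix(3 * (ks - 1), nrow = length(ks), ncol = 3) +
                          matrix(1:3, nrow = length(ks), ncol = 3, byrow = TRUE)))
    A <- modes_v[rows, , drop = FALSE] * rep(sqrtl, each = length(rows))
    d <- shape_to_vec(Tm) - mean_v[rows]
    bn <- solve(crossprod(A) + ridge * diag(N), crossprod(A, d))
    db <- sqrt(sum((bn - b)^2))
    db_last <- db
    b <- as.vector(bn)
    # optionally refresh the similarity pose against the matched targets
    verts <- vec_to_shape(mean_v + as.vector(modes_v %*% (b * sqrtl)))
    if (refine_pose) {
      Y <- sweep(verts[ks, , drop = FALSE], 2, scale3, "*")
      tr <- procrustes_similarity(Y, Tp)
      s_iso <- tr$s
      R <- tr$R
      t <- tr$t
    }
    res <- sqrt(mean(point_mesh_distance(to_patient(verts[ks, , drop = FALSE]),
                                         target)$dist^2))
    if (robust && db < cfg$dB_tol) break
  }

  # canonicalize: the working parameterization carries the anisotropic
  # initialization scale, which keeps the pose search robust but leaves the
  # coefficients entangled with it. Re-express the converged reconstruction
  # as (pure similarity pose) x (mode coefficients): align it to the model
  # mean, project onto the modes, and re-fit the similarity pose.
  verts <- vec_to_shape(mean_v + as.vector(modes_v %*% (b * sqrtl)))
  Yp <- to_patient(verts)
  mu_v <- vec_to_shape(mean_v)
  tr_al <- procrustes_similarity(Yp, mu_v)
  al <- apply_similarity(Yp, tr_al)
  b_can <- as.vector(crossprod(modes_v, shape_to_vec(al) - mean_v)) / sqrtl
  Xc <- vec_to_shape(mean_v + as.vector(modes_v %*% (b_can * sqrtl)))
  tr_pose <- procrustes_similarity(Xc, Yp)

  fit <- structure(list(
    scale = rep(tr_pose$s, 3), rotation = tr_pose$R, translation = tr_pose$t,
    b = b_can, residual_rmse = res, inlier_fraction = inlier,
    bone_kind = model$bone_kind
  ), class = "FitResult")
  rec <- reconstruct(model, fit)
  fit$reconstructed <- rec$mesh
  fit$landmarks <- rec$landmarks
  fit$residual_rmse <- sqrt(mean(point_mesh_distance(
    rec$mesh$vertices[sel, , drop = FALSE], target)$dist^2))
  fit
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult (%s): |b| = %.2f over %d modes, residual %.3f mm, inliers %.0f%%\n",
              x$bone_kind %||% "?", sqrt(sum(x$b^2)), length(x$b),
              x$residual_rmse, 100 * x$inlier_fraction))
  invisible(x)
}

#' Reconstruct the full bone from a fit
#'
#' Synthesizes the model at the fitted coefficients and maps mesh and
#' landmarks through the fitted scale/rotation/translation into patient space.
#'
#' @param model a `ShapeModel`
#' @param fit a `FitResult`
#' @return list with `mesh` and `landmarks` in patient space
#' @export
reconstruct <- function(model, fit) {
  syn <- synthesize(model, fit$b)
  mp <- function(P) {
    sweep(sweep(P, 2, fit$scale, "*") %*% t(fit$rotation), 2, fit$translation, "+")
  }
  list(
    mesh = tri_mesh(mp(syn$mesh$vertices), syn$mesh$faces),
    landmarks = landmark_set(syn$landmarks$names, mp(syn$landmarks$points),
                             syn$landmarks$weights)
  )
}

#' Full three-stage fit of a model to a partial observation
#'
#' Convenience wrapper: [init_scale()], [rigid_register()], [deform_fit()].
#'
#' @param model a truncated `ShapeModel`
#' @param partial a `PartialObservation`
#' @param ridge,trim_frac,iters passed to [deform_fit()]
#' @param frac crop fractions assumed for the scale stage
#' @param cfg fitting configuration
#' @return a `FitResult`
#' @export
fit_partial <- function(model, partial, ridge = 1.0, trim_frac = 0.10,
                        iters = 40L, frac = c(0.3, 0.3),
                        cfg = default_config()$fitting) {
  s3 <- init_scale(model, partial, frac)
  poses <- rigid_register(model, partial, s3, cfg, top_k = 3L, frac = frac)
  # screen every raw orientation/azimuth candidate with a short deformation:
  # its residual separates the true basin from flips and false azimuths far
  # more sharply than any rigid score, because a wrong basin must distort
  # the modes to chase the data
  raw <- attr(poses, "raw_candidates")
  screen <- vapply(raw, function(pose) {
    f <- tryCatch(deform_fit(model, partial, pose, scale3 = s3, ridge = ridge,
                             trim_frac = trim_frac, iters = 6L, cfg = cfg),
                  error = function(e) NULL)
    if (is.null(f)) Inf else f$residual_rmse
  }, numeric(1))
  keep_raw <- raw[order(screen)[seq_len(min(3L, length(raw)))]]
  fits <- lapply(c(keep_raw, poses[1]), function(pose) {
    tryCatch(deform_fit(model, partial, pose, scale3 = s3, ridge = ridge,
                        trim_frac = trim_frac, iters = iters, cfg = cfg),
             error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) stop("deformation failed for every candidate pose")
  best <- fits[[which.min(vapply(fits, function(f) f$residual_rmse, numeric(1)))]]
  # warm-restart rounds for stubborn cases: re-deform from the canonicalized
  # pose and coefficients, where matching runs against an already-close shape
  for (round in 1:2) {
    if (best$residual_rmse <= 0.3) break
    pose2 <- list(R = best$rotation, t = best$translation, s_iso = best$scale[1])
    again <- tryCatch(deform_fit(model, partial, pose2, scale3 = c(1, 1, 1),
                                 ridge = ridge, trim_frac = trim_frac,
                                 iters = iters, b_init = best$b, cfg = cfg),
                      error = function(e) NULL)
    if (is.null(again) || again$residual_rmse >= best$residual_rmse) break
    best <- again
  }
  best
}
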