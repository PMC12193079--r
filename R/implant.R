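# Parametric medial-pivot implant design at desk scale: resection planning,
# planar section contours, femoral/tibial/insert profiles (2.5D: sagittal
# arcs + planar footprint contours) and over/under-hang scoring with
# anatomically anchored ignore zones.

#' Plan the three resection planes from secondary parameters
#'
#' femoral_distal: orthogonal to the femoral mechanical axis, `distal_cut`
#' proximal to the more distal condyle point. femoral_posterior: orthogonal
#' to the AP direction, `posterior_cut` anterior to the more posterior
#' condyle point. tibial_proximal: orthogonal to the tibial mechanical axis
#' tilted posteriorly by `tibial_slope`, `tibial_cut` below the higher wear
#' point.
#'
#' @param sp a `SecondaryParams`
#' @param cfg implant configuration
#' @return a `ResectionPlan`: named planes with `point` and unit `normal`
#' @export
plan_resections <- function(sp, cfg = default_config()$implant) {
  need <- c("frame", "refs", "ap_size", "ml_width")
  miss <- setdiff(need, names(sp))
  if (length(miss)) stop(sprintf("missing secondary parameters: %s", paste(miss, collapse = ", ")))
  z <- sp$frame$z_proximal
  y <- sp$frame$y_anterior
  x <- sp$frame$x_lateral

  dp <- sp$refs$distal_points
  most_distal <- dp[which.min(dp %*% z), ]
  femoral_distal <- list(point = most_distal + cfg$distal_cut_mm * z, normal = z)

  pp <- sp$refs$posterior_points
  most_post <- pp[which.min(pp %*% y), ]
  femoral_posterior <- list(point = most_post + cfg$posterior_cut_mm * y, normal = y)

  zt <- sp$refs$tibial_axis_dir
  a <- cfg$tibial_slope_deg * pi / 180
  yt <- unit(y - sum(y * zt) * zt)
  nt <- unit(cos(a) * zt + sin(a) * yt)   # tilted anteriorly -> posterior slope
  wp <- sp$refs$wear_points
  high_wear <- wp[which.max(wp %*% zt), ]
  tibial_proximal <- list(point = high_wear - cfg$tibial_cut_mm * zt, normal = nt)

  structure(list(
    femoral_distal = femoral_distal,
    femoral_posterior = femoral_posterior,
    tibial_proximal = tibial_proximal,
    config = cfg[c("distal_cut_mm", "posterior_cut_mm", "tibial_cut_mm",
                   "tibial_slope_deg")]
  ), class = "ResectionPlan")
}

#' Intersect a mesh with a plane and keep the largest closed loop
#'
#' The contour is expressed in the plane frame with `e2` along the projection
#' of `anterior` (so arc-length ignore zones are anatomically anchored) and
#' `e1 = e2 x normal`; canonical orientation counter-clockwise starting on
#' the +e2 ray.
#'
#' @param mesh a `TriMesh`
#' @param plane list with `point` and unit `normal`
#' @param anterior in-plane reference direction (default +y)
#' @return a `PlanarContour`
#' @export
section_contour <- function(mesh, plane, anterior = c(0, 1, 0)) {
  n <- unit(plane$normal)
  e2 <- anterior - sum(anterior * n) * n
  if (sqrt(sum(e2^2)) < 1e-9) stop("anterior direction parallel to plane normal")
  e2 <- unit(e2)
  e1 <- c(e2[2] * n[3] - e2[3] * n[2],
          e2[3] * n[1] - e2[1] * n[3],
          e2[1] * n[2] - e2[2] * n[1])
  V <- mesh$vertices
  F <- mesh$faces
  d <- as.vector(sweep(V, 2, plane$point, "-") %*% n)
  d[abs(d) < 1e-9] <- 1e-9
  sgn <- d > 0
  tri_sgn <- cbind(sgn[F[, 1]], sgn[F[, 2]], sgn[F[, 3]])
  cut <- which(rowSums(tri_sgn) %in% c(1, 2))
  if (length(cut) == 0) stop("empty section: plane does not intersect mesh")

  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ept <- new.env(hash = TRUE)
  edge_point <- function(i, j) {
    k <- ekey(i, j)
    p <- ept[[k]]
    if (!is.null(p)) return(p)
    t <- d[i] / (d[i] - d[j])
    p <- V[i, ] + t * (V[j, ] - V[i, ])
    ept[[k]] <- p
    p
  }
  segs <- vector("list", length(cut))
  keys <- character(2 * length(cut))
  for (s in seq_along(cut)) {
    f <- F[cut[s], ]
    cross_edges <- list()
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- f[pair[1]]; j <- f[pair[2]]
      if (sgn[i] != sgn[j]) cross_edges[[length(cross_edges) + 1]] <- c(i, j)
    }
    if (length(cross_edges) != 2) next
    k1 <- ekey(cross_edges[[1]][1], cross_edges[[1]][2])
    k2 <- ekey(cross_edges[[2]][1], cross_edges[[2]][2])
    edge_point(cross_edges[[1]][1], cross_edges[[1]][2])
    edge_point(cross_edges[[2]][1], cross_edges[[2]][2])
    segs[[s]] <- c(k1, k2)
    keys[2 * s - 1] <- k1
    keys[2 * s] <- k2
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) stop("empty section: no crossing triangles")

  # chain segments into loops via the edge-key adjacency
  adj <- new.env(hash = TRUE)
  for (sg in segs) {
    adj[[sg[1]]] <- c(adj[[sg[1]]], sg[2])
    adj[[sg[2]]] <- c(adj[[sg[2]]], sg[1])
  }
  unvisited <- new.env(hash = TRUE)
  for (k in unique(unlist(segs))) unvisited[[k]] <- TRUE
  loops <- list()
  for (start in ls(unvisited)) {
    if (is.null(unvisited[[start]])) next
    loop <- character(0)
    cur <- start
    prev <- ""
    repeat {
      loop <- c(loop, cur)
      rm(list = cur, envir = unvisited)
      nbrs <- setdiff(adj[[cur]], prev)
      nbrs <- nbrs[!vapply(nbrs, function(k) is.null(unvisited[[k]]), logical(1))]
      if (length(nbrs) == 0) break
      prev <- cur
      cur <- nbrs[1]
    }
    closed <- start %in% adj[[loop[length(loop)]]]
    if (closed && length(loop) >= 8) loops[[length(loops) + 1]] <- loop
  }
  if (length(loops) == 0) stop("empty section: no closed loop")

  to2d <- function(loop) {
    P <- do.call(rbind, lapply(loop, function(k) ept[[k]]))
    cbind(as.vector(sweep(P, 2, plane$point, "-") %*% e1),
          as.vector(sweep(P, 2, plane$point, "-") %*% e2))
  }
  areas <- vapply(loops, function(l) abs(shoelace_area(to2d(l))), numeric(1))
  planar_contour(to2d(loops[[which.max(areas)]]), origin = plane$point,
                 e1 = e1, e2 = e2)
}

#' Medial-pivot sphere radius from the antero-posterior size
#'
#' A configurable linear law: radius = ratio * ap_size.
#' @param ap_size antero-posterior size (mm, > 0)
#' @param ratio linear coefficient (default 0.33)
#' @return radius (mm)
#' @export
pivot_radius <- function(ap_size, ratio = 0.33) {
  if (ap_size <= 0 || ratio <= 0) stop("ap_size and ratio must be positive")
  ratio * ap_size
}

# per-sample offset of a closed CCW contour along inward normals, with a
# small circular Gaussian smoothing of the result (fillet proxy)
offset_contour_inward <- function(contour, offsets, fillet_sigma_mm = 2,
                                  step = 0.5) {
  s <- contour_resample(contour, step)
  p <- s$points
  n <- nrow(p)
  offs <- if (is.function(offsets)) offsets(s$frac) else rep(offsets, length.out = n)
  nxt <- p[c(2:n, 1), , drop = FALSE]
  prv <- p[c(n, 1:(n - 1)), , drop = FALSE]
  tg <- nxt - prv
  tl <- pmax(sqrt(rowSums(tg^2)), .Machine$double.eps)
  inw <- cbind(-tg[, 2], tg[, 1]) / tl  # left normal of a CCW loop = inward
  q <- p + inw * offs
  if (fillet_sigma_mm > 0) {
    k <- max(1L, round(fillet_sigma_mm / step))
    w <- stats::dnorm(seq(-3, 3, length.out = 2 * k + 1))
    w <- w / sum(w)
    smooth_circ <- function(x) {
      xx <- c(utils::tail(x, k), x, utils::head(x, k))
      stats::filter(xx, w, sides = 2)[k + seq_along(x)]
    }
    q <- cbind(smooth_circ(q[, 1]), smooth_circ(q[, 2]))
  }
  q
}

#' Design the tibial baseplate from the resected contour
#'
#' Inward offset of the resected-bone contour by `rim_offset`, with the
#' posterior sector additionally retreated by `posterior_retreat` (smooth
#' shoulders) to avoid muscle impingement; corners filleted; keel at the
#' baseplate area centroid with stem length `stem_scale * ml_width`.
#' A collapsing offset is reported as a design failure, not an exception.
#'
#' @param resected_contour `PlanarContour` of the tibial cut
#' @param ml_width ML width of the knee (mm) for the stem rule
#' @param cfg implant configuration
#' @return list with `status` ("ok"/"design-failure"), `contour`, `keel`
#'   (position, stem length), and the posterior sector used
#' @export
design_tibial_baseplate <- function(resected_contour, ml_width,
                                    cfg = default_config()$implant) {
  zone <- cfg$zones$tibial_posterior
  retreat_fun <- function(frac) {
    base <- cfg$rim_offset_mm
    hw <- 0.05  # smooth shoulder width in arc fraction
    ramp <- function(f) {
      inside <- f >= zone[1] & f <= zone[2]
      d_edge <- pmin(abs(f - zone[1]), abs(f - zone[2]))
      w <- ifelse(inside, pmin(d_edge / hw, 1), 0)
      w
    }
    base + cfg$posterior_retreat_mm * ramp(frac)
  }
  q <- offset_contour_inward(resected_contour, retreat_fun,
                             fillet_sigma_mm = cfg$fillet_radius_mm,
                             step = cfg$contour_step_mm)
  # a valid inward offset keeps the original (CCW) orientation and shrinks
  ok <- all(is.finite(q)) && shoelace_area(q) > 100 &&
    shoelace_area(q) < contour_area(resected_contour)
  cont <- NULL
  if (ok) {
    cont <- tryCatch(planar_contour(q, resected_contour$origin,
                                    resected_contour$e1, resected_contour$e2),
                     error = function(e) NULL)
    ok <- !is.null(cont) && contour_is_simple(cont)
  }
  if (!ok) {
    return(list(status = "design-failure", contour = NULL, keel = NULL,
                reason = "offset collapses the resected contour"))
  }
  keel_pos <- contour_centroid(cont)
  list(
    status = "ok",
    contour = cont,
    keel = list(position = keel_pos, stem_length = cfg$stem_scale * ml_width,
                inside = contour_contains(keel_pos, cont)),
    posterior_zone = zone
  )
}

#' Design the femoral profile (condylar arcs + footprint contour)
#'
#' Sagittal condylar arcs are circles of the per-condyle pivot radius
#' positioned tangent to both the distal and posterior resection planes; the
#' rollback arc truncates the posterior-proximal arc; the anterior flange is
#' the line through the anterior landmarks preserving the sulcus angle. The
#' footprint on the distal cut is the bone contour inset by the femoral rim
#' offset, hence never overhangs by construction.
#'
#' @param sp a `SecondaryParams`
#' @param distal_contour bone contour on the femoral distal cut
#' @param posterior_contour bone contour on the femoral posterior cut
#' @param cfg implant configuration
#' @return an `ImplantProfile` list (or `status = "design-failure"`)
#' @export
design_femoral_profile <- function(sp, distal_contour, posterior_contour,
                                   cfg = default_config()$implant) {
  p <- distal_contour$points
  med <- p[p[, 1] < 0, , drop = FALSE]   # e1 is lateral: medial = negative
  lat <- p[p[, 1] >= 0, , drop = FALSE]
  if (nrow(med) < 3 || nrow(lat) < 3) {
    return(list(status = "design-failure", reason = "contour does not span both condyles"))
  }
  ap_med <- diff(range(med[, 2]))
  ap_lat <- diff(range(lat[, 2]))
  r_med <- pivot_radius(ap_med, cfg$pivot_ratio)
  r_lat <- pivot_radius(ap_lat, cfg$pivot_ratio)
  # tangency feasibility: the circle must fit in its condyle's AP extent
  if (2 * r_med > ap_med / cfg$pivot_ratio || 2 * r_lat > ap_lat / cfg$pivot_ratio) {
    return(list(status = "design-failure", reason = "arc cannot be tangent to both cuts"))
  }
  # arc centers in patient space: r above the distal plane, r anterior of the
  # posterior plane -> tangent to both
  zd <- unit(sp$frame$z_proximal)
  ya <- unit(sp$frame$y_anterior)
  center_for <- function(xc) {
    distal_contour$origin + xc * distal_contour$e1 + r_med * zd
  }
  footprint <- offset_contour_inward(distal_contour, cfg$femoral_rim_offset_mm,
                                     fillet_sigma_mm = 0,
                                     step = cfg$contour_step_mm)
  fp <- tryCatch(planar_contour(footprint, distal_contour$origin,
                                distal_contour$e1, distal_contour$e2),
                 error = function(e) NULL)
  if (is.null(fp)) {
    return(list(status = "design-failure", reason = "footprint offset collapsed"))
  }
  list(
    status = "ok",
    medial_radius = r_med,
    lateral_radius = r_lat,
    medial_center = center_for(stats::median(med[, 1])),
    lateral_center = center_for(stats::median(lat[, 1])),
    rollback_angle_deg = cfg$rollback_angle_deg,
    anterior_flange = list(sulcus_angle_deg = sp$sulcus_angle_deg),
    footprint = fp,
    ml_extent = diff(range(fp$points[, 1])),
    bone_ml_extent = diff(range(p[, 1])),
    distal_plane = list(point = distal_contour$origin, normal = zd),
    posterior_plane = list(point = posterior_contour$origin, normal = ya)
  )
}

#' Design the tibial insert profile
#'
#' Medial socket = medial pivot radius + clearance; lateral = low-congruence
#' convex surface (congruence_factor times the lateral condyle radius);
#' outline = baseplate inset by the insert margin with an anterior cut at
#' `anterior_frac` of the AP extent.
#'
#' @param femoral_profile output of [design_femoral_profile()]
#' @param baseplate output of [design_tibial_baseplate()]
#' @param cfg implant configuration
#' @return insert specification list
#' @export
design_insert_profile <- function(femoral_profile, baseplate,
                                  cfg = default_config()$implant) {
  if (cfg$clearance_mm < 0) stop("clearance must be >= 0")
  if (identical(baseplate$status, "design-failure") ||
      identical(femoral_profile$status, "design-failure")) {
    return(list(status = "design-failure", reason = "upstream design failed"))
  }
  warn <- NULL
  if (cfg$congruence_factor <= 1) {
    warn <- "fully congruent lateral surface: boundary case"
    warning(warn)
  }
  q <- offset_contour_inward(baseplate$contour, cfg$insert_margin_mm,
                             fillet_sigma_mm = 0, step = cfg$contour_step_mm)
  yr <- range(q[, 2])
  ycut <- yr[1] + cfg$anterior_frac * (yr[2] - yr[1])
  qc <- q[q[, 2] <= ycut, , drop = FALSE]
  outline <- tryCatch(planar_contour(qc, baseplate$contour$origin,
                                     baseplate$contour$e1, baseplate$contour$e2),
                      error = function(e) NULL)
  list(
    status = if (is.null(outline)) "design-failure" else "ok",
    socket_radius = femoral_profile$medial_radius + cfg$clearance_mm,
    lateral_radius = cfg$congruence_factor * femoral_profile$lateral_radius,
    anterior_cut = ycut,
    outline = outline,
    warning = warn
  )
}

#' Arc-length ignore zones for a bone contour
#'
#' Tibial: the fixed posterior sector. Femoral: sectors centered on the
#' arc positions nearest the intercondylar-notch and trochlear-groove
#' landmark projections, with configured half-widths.
#'
#' @param bone `"femur"` or `"tibia"`
#' @param contour the bone `PlanarContour`
#' @param femoral_lms femoral `LandmarkSet` (needed for femur zones)
#' @param cfg implant configuration
#' @return list of c(lo, hi) normalized arc intervals (possibly wrapped)
#' @export
ignore_zones_for <- function(bone, contour, femoral_lms = NULL,
                             cfg = default_config()$implant) {
  if (bone == "tibia") return(list(tibial_posterior = cfg$zones$tibial_posterior))
  stopifnot(!is.null(femoral_lms))
  s <- contour_resample(contour, 1.0)
  frac_near <- function(pt3) {
    rel <- pt3 - contour$origin
    p2 <- c(sum(rel * contour$e1), sum(rel * contour$e2))
    s$frac[which.min(colSums((t(s$points) - p2)^2))]
  }
  fn <- frac_near(lm_pt(femoral_lms, "TopNotch"))
  fa <- frac_near(lm_pt(femoral_lms, "TopGroove"))
  hwn <- cfg$zones$femoral_notch_halfwidth
  hwa <- cfg$zones$femoral_anterior_halfwidth
  list(
    femoral_notch = c((fn - hwn) %% 1, (fn + hwn) %% 1),
    femoral_anterior_proximal = c((fa - hwa) %% 1, (fa + hwa) %% 1)
  )
}

#' Bone-implant over/under-hang report outside the ignore zones
#'
#' Delegates to [contour_distance()] with the named ignore zones mapped to
#' arc-length sectors; RMSE and Hausdorff are unsigned over/under-hang.
#'
#' @param bone_contour,implant_contour coplanar `PlanarContour`s
#' @param zones list of arc intervals (see [ignore_zones_for()])
#' @return a `DistanceReport`
#' @export
coverage_report <- function(bone_contour, implant_contour, zones = list()) {
  contour_distance(bone_contour, implant_contour, ignore_zones = zones)
}

#' Design both implants for one subject and score coverage
#'
#' End-to-end design step: secondary parameters, resection planes, section
#' contours, femoral profile, tibial baseplate, insert, and coverage reports
#' outside the ignore zones.
#'
#' @param femoral_lms,tibial_lms primary `LandmarkSet`s
#' @param femur_mesh,tibia_mesh full bone meshes (mm, patient space)
#' @param cfg implant configuration
#' @return list with `params`, `plan`, `femoral`, `tibial`, `insert`,
#'   `coverage` (per-bone `DistanceReport`s) and `status`
#' @export
design_knee_implants <- function(femoral_lms, tibial_lms, femur_mesh, tibia_mesh,
                                 cfg = default_config()$implant) {
  sp <- secondary_parameters(femoral_lms, tibial_lms)
  plan <- plan_resections(sp, cfg)
  ya <- sp$frame$y_anterior
  dist_c <- section_contour(femur_mesh, plan$femoral_distal, anterior = ya)
  post_c <- section_contour(femur_mesh, plan$femoral_posterior,
                            anterior = sp$frame$z_proximal)
  tib_c <- section_contour(tibia_mesh, plan$tibial_proximal, anterior = ya)

  fem <- design_femoral_profile(sp, dist_c, post_c, cfg)
  tib <- design_tibial_baseplate(tib_c, sp$ml_width, cfg)
  ins <- design_insert_profile(fem, tib, cfg)

  coverage <- list()
  if (identical(fem$status, "ok")) {
    zf <- ignore_zones_for("femur", dist_c, femoral_lms, cfg)
    coverage$femur <- coverage_report(dist_c, fem$footprint, zf)
  }
  if (identical(tib$status, "ok")) {
    zt <- ignore_zones_for("tibia", tib_c, cfg = cfg)
    coverage$tibia <- coverage_report(tib_c, tib$contour, zt)
  }
  status <- if (identical(fem$status, "ok") && identical(tib$status, "ok") &&
                identical(ins$status, "ok")) "ok" else "design-failure"
  list(params = sp, plan = plan, femoral = fem, tibial = tib, insert = ins,
       contours = list(femoral_distal = dist_c, femoral_posterior = post_c,
                       tibial_proximal = tib_c),
       coverage = coverage, status = status)
}
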