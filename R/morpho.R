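# Landmark propagation from the fitted model, osteophyte-risk-weighted
# refinement to the segmented surface, and secondary morphometric parameters.

#' Propagate landmarks from a completed fit
#'
#' Returns the reconstructed model's landmark block in patient space with
#' per-name default risk weights (osteophyte-prone names get low weights and
#' are barely adjusted later).
#'
#' @param fit a `FitResult`
#' @param cfg morpho configuration (risk-weight table)
#' @return a `LandmarkSet`
#' @export
propagate_landmarks <- function(fit, cfg = default_config()$morpho) {
  lms <- fit$landmarks
  landmark_set(lms$names, lms$points, default_risk_weights(lms$names, cfg))
}

#' Adjust landmarks toward a segmented mesh, weighted by osteophyte risk
#'
#' p' = p + w * clamp(proj(p) - p, max_shift), where proj is the closest
#' point on the segmented mesh and w the per-landmark risk weight: w = 0
#' leaves osteophyte-prone landmarks untouched, w = 1 projects fully.
#'
#' @param landmarks a `LandmarkSet`
#' @param segmented_mesh a `TriMesh`
#' @param max_shift maximum adjustment magnitude (mm, default 5)
#' @return the refined `LandmarkSet`
#' @export
refine_landmarks <- function(landmarks, segmented_mesh, max_shift = 5) {
  if (nrow(segmented_mesh$vertices) == 0 || nrow(segmented_mesh$faces) == 0) {
    stop("segmented mesh is empty")
  }
  if (max_shift <= 0) stop("max_shift must be positive")
  m <- point_mesh_distance(landmarks$points, segmented_mesh)
  delta <- m$closest - landmarks$points
  len <- sqrt(rowSums(delta^2))
  fac <- ifelse(len > max_shift, max_shift / len, 1)
  pts <- landmarks$points + delta * (fac * landmarks$weights)
  landmark_set(landmarks$names, pts, landmarks$weights)
}

lm_pt <- function(lms, name) {
  i <- match(name, lms$names)
  if (is.na(i)) stop(sprintf("missing landmark: %s", name))
  lms$points[i, ]
}

unit <- function(v) v / sqrt(sum(v^2))

#' Secondary morphometric parameters from primary landmarks
#'
#' Computes the femoral and tibial mechanical axes, knee centers, AP size,
#' ML width, condylar line, sulcus angle and the points referenced by the
#' resection planner. All quantities are built covariantly from landmark
#' positions, so they are invariant (lengths, angles) or equivariant (axes)
#' under global rigid motion.
#'
#' Definitions: the femoral knee center is the top-notch point projected onto
#' the plane through the mid-distal-condyle point orthogonal to the
#' head-to-mid-condyle direction; the tibial knee center is the midpoint of
#' the two condyle centers; the anatomical frame has z along the femoral
#' mechanical axis (proximal), x along the projected transepicondylar line
#' (lateral), y = z x x (anterior).
#'
#' @param femoral_lms,tibial_lms `LandmarkSet`s with the primary names
#' @return a `SecondaryParams` list
#' @export
secondary_parameters <- function(femoral_lms, tibial_lms) {
  need_f <- c("FemoralHeadCenter", "MedialDistal", "LateralDistal", "TopNotch",
              "MedialEpicondyle", "LateralEpicondyle", "MedialPosterior",
              "LateralPosterior", "APSizingPoint", "MedialAnterior",
              "LateralAnterior", "TopGroove")
  need_t <- c("MedialCondyleCenter", "LateralCondyleCenter", "AnkleJointCenter",
              "MedialWearPoint", "LateralWearPoint")
  miss <- c(setdiff(need_f, femoral_lms$names), setdiff(need_t, tibial_lms$names))
  if (length(miss) > 0) {
    stop(sprintf("missing required landmarks: %s", paste(miss, collapse = ", ")))
  }
  fhc <- lm_pt(femoral_lms, "FemoralHeadCenter")
  md <- lm_pt(femoral_lms, "MedialDistal")
  ld <- lm_pt(femoral_lms, "LateralDistal")
  tn <- lm_pt(femoral_lms, "TopNotch")
  me <- lm_pt(femoral_lms, "MedialEpicondyle")
  le <- lm_pt(femoral_lms, "LateralEpicondyle")
  mp <- lm_pt(femoral_lms, "MedialPosterior")
  lp <- lm_pt(femoral_lms, "LateralPosterior")
  ap_pt <- lm_pt(femoral_lms, "APSizingPoint")
  ma <- lm_pt(femoral_lms, "MedialAnterior")
  la <- lm_pt(femoral_lms, "LateralAnterior")
  tg <- lm_pt(femoral_lms, "TopGroove")
  mcc <- lm_pt(tibial_lms, "MedialCondyleCenter")
  lcc <- lm_pt(tibial_lms, "LateralCondyleCenter")
  ajc <- lm_pt(tibial_lms, "AnkleJointCenter")
  mw <- lm_pt(tibial_lms, "MedialWearPoint")
  lw <- lm_pt(tibial_lms, "LateralWearPoint")

  mid_d <- (md + ld) / 2
  a0 <- unit(fhc - mid_d)                       # provisional proximal direction
  kc_fem <- tn - sum((tn - mid_d) * a0) * a0    # TopNotch projected to condyle level
  zup <- unit(fhc - kc_fem)                     # femoral mechanical axis (proximal)
  epi <- unit(le - me)
  xlat <- unit(epi - sum(epi * zup) * zup)      # lateral in the axis-normal plane
  yant <- c(zup[2] * xlat[3] - zup[3] * xlat[2],
            zup[3] * xlat[1] - zup[1] * xlat[3],
            zup[1] * xlat[2] - zup[2] * xlat[1])

  kc_tib <- (mcc + lcc) / 2
  mid_post <- (mp + lp) / 2
  ap_size <- abs(sum((ap_pt - mid_post) * yant))
  ml_width <- sqrt(sum((me - le)^2))
  sulcus <- angle_deg(ma - tg, la - tg)

  structure(list(
    femoral_axis = rbind(FemoralHeadCenter = fhc, KneeCenter = kc_fem),
    tibial_axis = rbind(KneeCenter = kc_tib, AnkleJointCenter = ajc),
    knee_center_femoral = kc_fem,
    knee_center_tibial = kc_tib,
    ap_size = ap_size,
    ml_width = ml_width,
    condylar_line = rbind(medial = mcc, lateral = lcc),
    sulcus_angle_deg = sulcus,
    frame = list(x_lateral = xlat, y_anterior = yant, z_proximal = zup),
    refs = list(
      distal_points = rbind(medial = md, lateral = ld),
      posterior_points = rbind(medial = mp, lateral = lp),
      wear_points = rbind(medial = mw, lateral = lw),
      tibial_axis_dir = unit(kc_tib - ajc)
    )
  ), class = "SecondaryParams")
}

angle_deg <- function(u, v) {
  cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Angular error of the condylar line from plateau edge points
#'
#' Each condyle center is the centroid of its edge points (>= 3 per plateau);
#' the error is the angle between the predicted and reference center-to-center
#' lines, in [0, 90] degrees, invariant to point ordering.
#'
#' @param pred_edge_pts,ref_edge_pts lists with `medial` and `lateral`
#'   point matrices (n x 3, n >= 3)
#' @return angular error in degrees
#' @export
condylar_line_error <- function(pred_edge_pts, ref_edge_pts) {
  ctrs <- function(e) {
    if (nrow(e$medial) < 3 || nrow(e$lateral) < 3) {
      stop("need at least 3 edge points per plateau")
    }
    colMeans(e$lateral) - colMeans(e$medial)
  }
  u <- ctrs(pred_edge_pts)
  v <- ctrs(ref_edge_pts)
  if (sqrt(sum(u^2)) < 1e-12 || sqrt(sum(v^2)) < 1e-12) {
    stop("degenerate: coincident condyle centers")
  }
  a <- angle_deg(u, v)
  min(a, 180 - a)
}

#' Mean landmark error against a reference set (mm)
#'
#' Matches landmarks by name; errors averaged over the common names.
#' @param pred,ref `LandmarkSet`s
#' @return mean Euclidean error (mm), per-name errors in attribute `per_name`
#' @export
landmark_error <- function(pred, ref) {
  common <- intersect(pred$names, ref$names)
  if (length(common) == 0) stop("no common landmark names")
  e <- vapply(common, function(nm) {
    sqrt(sum((lm_pt(pred, nm) - lm_pt(ref, nm))^2))
  }, numeric(1))
  out <- mean(e)
  attr(out, "per_name") <- e
  out
}
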