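test_that("landmark propagation carries the model names and the mean at b = 0", {
  m <- coarse_model("femur", P = 10)
  fit0 <- structure(list(scale = c(1, 1, 1), rotation = diag(3),
                         translation = c(0, 0, 0), b = rep(0, length(m$variances)),
                         bone_kind = "femur"),
                    class = "FitResult")
  rec <- reconstruct(m, fit0)
  fit0$landmarks <- rec$landmarks
  prop <- propagate_landmarks(fit0)
  expect_setequal(prop$names, m$landmark_names)
  expect_equal(prop$points, synthesize(m)$landmarks$points,
               ignore_attr = TRUE, tolerance = 1e-12)
  # osteophyte-prone names carry low risk weights
  expect_equal(prop$weights[match("MedialEpicondyle", prop$names)], 0.2)
})

test_that("refinement moves landmarks by weight-scaled clamped projections", {
  sph <- make_icosphere(20, c(0, 0, 0), subdivisions = 4)
  # w = 0: untouched
  lm0 <- landmark_set("P", matrix(c(25, 0, 0), 1), 0)
  expect_equal(refine_landmarks(lm0, sph)$points, lm0$points, ignore_attr = TRUE)
  # already on the mesh with w = 1: unchanged
  v1 <- sph$vertices[10, , drop = FALSE]
  lm1 <- landmark_set("P", v1, 1)
  expect_lt(max(abs(refine_landmarks(lm1, sph)$points - v1)), 1e-9)
  # 2 mm off the sphere with w = 0.5: moves 1 mm toward the surface
  lm2 <- landmark_set("P", matrix(c(22, 0, 0), 1), 0.5)
  ref2 <- refine_landmarks(lm2, sph)
  moved <- sqrt(sum((ref2$points - lm2$points)^2))
  expect_equal(moved, 1.0, tolerance = 0.02)
  # shifts never exceed w * max_shift
  set.seed(3)
  far <- landmark_set(paste0("L", 1:6),
                      matrix(rnorm(18, 0, 60), 6), runif(6))
  reff <- refine_landmarks(far, sph, max_shift = 5)
  shifts <- sqrt(rowSums((reff$points - far$points)^2))
  expect_true(all(shifts <= far$weights * 5 + 1e-9))
  expect_error(refine_landmarks(lm2, tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))))
})

test_that("secondary parameters match an independent projection of the template landmarks", {
  ks <- knee_scene(make_template("femur"), make_template("tibia"))
  sp <- secondary_parameters(ks$femur$landmarks, ks$tibia$landmarks)
  flm <- ks$femur$landmarks
  # independent recomputation from raw landmark coordinates
  g <- function(n, l = flm) l$points[match(n, l$names), ]
  mid_d <- (g("MedialDistal") + g("LateralDistal")) / 2
  a0 <- g("FemoralHeadCenter") - mid_d; a0 <- a0 / sqrt(sum(a0^2))
  kc <- g("TopNotch") - sum((g("TopNotch") - mid_d) * a0) * a0
  z <- g("FemoralHeadCenter") - kc; z <- z / sqrt(sum(z^2))
  e <- g("LateralEpicondyle") - g("MedialEpicondyle"); e <- e / sqrt(sum(e^2))
  x <- e - sum(e * z) * z; x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
  ap <- abs(sum((g("APSizingPoint") - (g("MedialPosterior") + g("LateralPosterior")) / 2) * y))
  expect_equal(sp$ap_size, ap, tolerance = 0.1)
  expect_equal(sp$ml_width,
               sqrt(sum((g("MedialEpicondyle") - g("LateralEpicondyle"))^2)),
               tolerance = 1e-9)
  expect_gt(sp$sulcus_angle_deg, 0)
  expect_lt(sp$sulcus_angle_deg, 180)
  # missing landmarks are all listed
  few <- landmark_set(flm$names[1:3], flm$points[1:3, ], flm$weights[1:3])
  expect_error(secondary_parameters(few, ks$tibia$landmarks), "FemoralHeadCenter")
})

test_that("secondary parameters are invariant under global rigid motion", {
  ks <- knee_scene(make_template("femur"), make_template("tibia"))
  sp <- secondary_parameters(ks$femur$landmarks, ks$tibia$landmarks)
  th <- 0.7; ax <- c(1, 2, 0.5) / sqrt(5.25)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  t <- c(15, -40, 8)
  move <- function(l) landmark_set(l$names, sweep(l$points %*% t(R), 2, t, "+"), l$weights)
  sp2 <- secondary_parameters(move(ks$femur$landmarks), move(ks$tibia$landmarks))
  expect_equal(sp2$ap_size, sp$ap_size, tolerance = 1e-9)
  expect_equal(sp2$ml_width, sp$ml_width, tolerance = 1e-9)
  expect_equal(sp2$sulcus_angle_deg, sp$sulcus_angle_deg, tolerance = 1e-9)
  # axes transform covariantly
  ax1 <- sp$femoral_axis[2, ] - sp$femoral_axis[1, ]
  ax2 <- sp2$femoral_axis[2, ] - sp2$femoral_axis[1, ]
  expect_equal(ax2, as.vector(R %*% ax1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the condylar line angular error measures constructed rotations", {
  set.seed(11)
  # in-plane point sets (z = 0) so an in-plane rotation changes the
  # center-to-center line by exactly the rotation angle
  med <- cbind(rnorm(5, -25, 2), rnorm(5, 0, 2), 0)
  lat <- cbind(rnorm(5, 25, 2), rnorm(5, 2, 2), 0)
  pts <- list(medial = med, lateral = lat)
  expect_equal(condylar_line_error(pts, pts), 0)
  # rotate the reference line by exactly 5 degrees in the xy plane
  th <- 5 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- (colMeans(med) + colMeans(lat)) / 2
  rot <- function(P) sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, "+")
  expect_equal(condylar_line_error(pts, list(medial = rot(med), lateral = rot(lat))),
               5, tolerance = 1e-6)
  # invariant to point ordering
  perm <- list(medial = med[c(3, 1, 5, 2, 4), ], lateral = lat[c(5, 4, 1, 3, 2), ])
  expect_equal(condylar_line_error(perm, pts), 0)
  # swapping medial/lateral flips direction but preserves the unsigned angle
  swapped <- list(medial = lat, lateral = med)
  expect_equal(condylar_line_error(swapped, pts), 0, tolerance = 1e-9)
  same <- list(medial = med, lateral = med)
  expect_error(condylar_line_error(same, same), "degenerate")
})
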