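template_params <- function() {
  ks <- knee_scene(make_template("femur"), make_template("tibia"))
  list(ks = ks, sp = secondary_parameters(ks$femur$landmarks, ks$tibia$landmarks))
}

test_that("resection planes follow the mechanical axes and configured cuts", {
  tp <- template_params()
  sp <- tp$sp
  plan <- plan_resections(sp)
  z <- sp$frame$z_proximal
  cr <- crossprod(plan$femoral_distal$normal, z)
  expect_equal(abs(as.numeric(cr)), 1, tolerance = 1e-9)
  # zero cut depth: plane passes through the most distal condyle point
  cfg0 <- default_config()$implant
  cfg0$distal_cut_mm <- 0
  plan0 <- plan_resections(sp, cfg0)
  dp <- sp$refs$distal_points
  most_distal <- dp[which.min(dp %*% z), ]
  expect_lt(abs(sum((most_distal - plan0$femoral_distal$point) *
                      plan0$femoral_distal$normal)), 1e-9)
  # posterior slope is exactly the configured angle
  zt <- sp$refs$tibial_axis_dir
  ang <- acos(pmin(sum(plan$tibial_proximal$normal * zt), 1)) * 180 / pi
  expect_equal(ang, 3.0, tolerance = 1e-6)
  expect_error(plan_resections(list(ap_size = 1)), "missing")
})

test_that("section contours recover analytic cylinder and sphere cuts", {
  cyl <- make_cylinder(radius = 20, height = 100, n_theta = 128, n_z = 20)
  cont <- section_contour(cyl, list(point = c(0, 0, 50), normal = c(0, 0, 1)))
  expect_equal(contour_perimeter(cont), 2 * pi * 20, tolerance = 0.005)
  sph <- make_icosphere(25, c(0, 0, 0), subdivisions = 4)
  cs <- section_contour(sph, list(point = c(0, 0, 0), normal = c(0, 0, 1)))
  rr <- sqrt(rowSums(cs$points^2))
  expect_equal(mean(rr), 25, tolerance = 0.01)
  expect_error(section_contour(sph, list(point = c(0, 0, 40), normal = c(0, 0, 1))),
               "empty section")
})

test_that("the pivot radius is a linear law with input validation", {
  expect_equal(pivot_radius(60, 0.33), 19.8)
  expect_equal(pivot_radius(40, 0.5), 20.0)
  expect_equal(pivot_radius(88, 0.33), 2 * pivot_radius(44, 0.33))
  expect_error(pivot_radius(-3, 0.33))
  expect_error(pivot_radius(60, 0))
})

test_that("the tibial baseplate offsets, retreats and fails honestly", {
  c30 <- circle_contour(30)
  cfg <- default_config()$implant
  cfg$posterior_retreat_mm <- 0
  bp <- design_tibial_baseplate(c30, ml_width = 63, cfg)
  expect_identical(bp$status, "ok")
  rr <- sqrt(rowSums(bp$contour$points^2))
  expect_equal(mean(rr), 29.5, tolerance = 0.1 / 29.5)
  expect_true(bp$keel$inside)
  expect_equal(bp$keel$stem_length, 0.35 * 63)
  # with the posterior retreat the posterior sector sits ~3.5 mm inside
  bp3 <- design_tibial_baseplate(c30, ml_width = 63)
  unzoned <- contour_distance(c30, bp3$contour)
  expect_equal(unzoned$hausdorff, 3.5, tolerance = 0.3)
  zoned <- coverage_report(c30, bp3$contour,
                           ignore_zones_for("tibia", c30))
  expect_lt(zoned$hausdorff, 1)
  # collapsing offset is a reported failure, not an exception
  cfg_bad <- default_config()$implant
  cfg_bad$rim_offset_mm <- 40
  bad <- design_tibial_baseplate(circle_contour(20), ml_width = 63, cfg_bad)
  expect_identical(bad$status, "design-failure")
})

test_that("the femoral profile is symmetric for symmetric bones and tangent to its cuts", {
  tp <- template_params()
  sp <- tp$sp
  plan <- plan_resections(sp)
  dist_c <- section_contour(tp$ks$femur$mesh, plan$femoral_distal,
                            anterior = sp$frame$y_anterior)
  post_c <- section_contour(tp$ks$femur$mesh, plan$femoral_posterior,
                            anterior = sp$frame$z_proximal)
  # symmetrize the distal contour: equal condyle AP extents by construction
  pts <- dist_c$points
  sym <- planar_contour(rbind(pts, cbind(-pts[, 1], pts[, 2])),
                        dist_c$origin, dist_c$e1, dist_c$e2)
  prof_sym <- design_femoral_profile(sp, sym, post_c)
  expect_identical(prof_sym$status, "ok")
  expect_equal(prof_sym$medial_radius, prof_sym$lateral_radius, tolerance = 0.1)

  prof <- design_femoral_profile(sp, dist_c, post_c)
  expect_identical(prof$status, "ok")
  # no overhang by construction: footprint ML extent inside the bone's
  expect_lte(prof$ml_extent, prof$bone_ml_extent)
  # tangency: the arc's lowest point lies on the distal plane
  low <- prof$medial_center - prof$medial_radius * prof$distal_plane$normal
  gap <- sum((low - prof$distal_plane$point) * prof$distal_plane$normal)
  expect_lt(abs(gap), 0.05)
  # signed containment: every footprint sample inside the bone contour
  rs <- contour_resample(prof$footprint, 2)$points
  inside <- vapply(seq_len(nrow(rs)), function(i) contour_contains(rs[i, ], dist_c),
                   logical(1))
  expect_true(all(inside))
})

test_that("the insert is additive on radii and nests inside the baseplate", {
  tp <- template_params()
  d <- design_knee_implants(tp$ks$femur$landmarks, tp$ks$tibia$landmarks,
                            tp$ks$femur$mesh, tp$ks$tibia$mesh)
  expect_identical(d$status, "ok")
  expect_equal(d$insert$socket_radius, d$femoral$medial_radius + 0.5)
  expect_equal(d$insert$lateral_radius, 2.0 * d$femoral$lateral_radius)
  rs <- contour_resample(d$insert$outline, 2)$points
  inside <- vapply(seq_len(nrow(rs)), function(i)
    contour_contains(rs[i, ], d$tibial$contour), logical(1))
  expect_true(all(inside))
  # fully congruent lateral surface is a flagged boundary case
  cfg1 <- default_config()$implant
  cfg1$congruence_factor <- 1.0
  expect_warning(design_insert_profile(d$femoral, d$tibial, cfg1), "congruent")
})

test_that("coverage reporting matches analytic offsets and design is deterministic", {
  c30 <- circle_contour(30)
  expect_equal(coverage_report(c30, c30)$rmse, 0)
  c29 <- circle_contour(29)
  cv <- coverage_report(c30, c29)
  expect_equal(cv$rmse, 1.0, tolerance = 0.02)
  tp <- template_params()
  d1 <- design_knee_implants(tp$ks$femur$landmarks, tp$ks$tibia$landmarks,
                             tp$ks$femur$mesh, tp$ks$tibia$mesh)
  d2 <- design_knee_implants(tp$ks$femur$landmarks, tp$ks$tibia$landmarks,
                             tp$ks$femur$mesh, tp$ks$tibia$mesh)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
})
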