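test_that("templates are deterministic, watertight, with the full landmark catalogue", {
  tf <- make_template("femur")
  expect_setequal(tf$landmarks$names, c(
    "MedialPosterior", "LateralPosterior", "MedialDistal", "LateralDistal",
    "MedialEpicondyle", "LateralEpicondyle", "MedialAnterior", "LateralAnterior",
    "TopGroove", "TopNotch", "APSizingPoint", "FemoralHeadCenter"
  ))
  expect_length(tf$landmarks$names, 12L)
  tt1 <- make_template("tibia")
  tt2 <- make_template("tibia")
  expect_identical(tt1$mesh$vertices, tt2$mesh$vertices)
  expect_setequal(tt1$landmarks$names, c(
    "KneeCenter", "AnkleJointCenter", "MedialWearPoint", "LateralWearPoint",
    "MedialCondyleCenter", "LateralCondyleCenter"
  ))
  expect_true(mesh_is_watertight(tf$mesh))
  expect_true(mesh_is_watertight(tt1$mesh))
  # every landmark lies on the surface
  d <- point_mesh_distance(tf$landmarks$points, tf$mesh)$dist
  expect_lt(max(d), 1e-6)
  expect_error(make_template("patella"))
})

test_that("population sampling preserves correspondence and latent statistics", {
  tp <- coarse_template("femur")
  # zero variance, no jitter: members identical to the template
  p0 <- sample_population(tp, 3, 6, sd = 0, seed = 1, scale_jitter = FALSE)
  for (b in p0) expect_equal(b$mesh$vertices, tp$mesh$vertices, tolerance = 1e-12)
  # determinism
  pa <- sample_population(tp, 4, 6, 2, seed = 11)
  pb <- sample_population(tp, 4, 6, 2, seed = 11)
  expect_identical(pa[[3]]$mesh$vertices, pb[[3]]$mesh$vertices)
  expect_identical(pa[[3]]$latent, pb[[3]]$latent)
  # shared topology = exact correspondence
  expect_identical(pa[[1]]$mesh$faces, tp$mesh$faces)
  # landmarks ride their vertices exactly
  expect_equal(pa[[2]]$landmarks$points,
               pa[[2]]$mesh$vertices[pa[[2]]$landmark_vidx, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-12)
  # latent coefficients ~ N(0, sd^2) i.i.d.: sample covariance near 4 I
  pop <- sample_population(tp, 200, 6, 2, seed = 5)
  lat <- do.call(rbind, lapply(pop, function(b) b$latent))
  cv <- stats::cov(lat)
  expect_true(all(abs(diag(cv) - 4) < 1.3))
  expect_true(max(abs(cv[upper.tri(cv)])) < 1.0)
  expect_error(sample_population(tp, 1, 6, 2, seed = 1))
})

test_that("osteophytes bump the surface but not the landmarks", {
  tp <- coarse_template("femur")
  b0 <- add_osteophytes(tp, 0, seed = 3)
  expect_equal(b0$mesh$vertices, tp$mesh$vertices, tolerance = 1e-12)
  b1 <- add_osteophytes(tp, 1, seed = 3)
  disp <- sqrt(rowSums((b1$mesh$vertices - tp$mesh$vertices)^2))
  expect_lte(max(disp), 6 + 1e-9)
  expect_identical(b1$landmarks$points, tp$landmarks$points)
  expect_true(isTRUE(b1$pathological))
  # Hausdorff against the clean mesh matches the max applied displacement
  b5 <- add_osteophytes(tp, 0.5, seed = 9)
  hd <- surface_distance(b5$mesh, tp$mesh)$hausdorff
  expect_equal(hd, attr(b5, "max_displacement"), tolerance = 0.1)
  expect_error(add_osteophytes(tp, 1.5, seed = 1))
})

test_that("extremity cropping splits by longitudinal fraction", {
  tp <- coarse_template("tibia")
  cr <- crop_extremities(tp$mesh, 0.5, 0.5)
  expect_equal(nrow(cr$proximal$faces) + nrow(cr$distal$faces), nrow(tp$mesh$faces))
  cr3 <- crop_extremities(tp$mesh, 0.3, 0.3)
  zr <- range(tp$mesh$vertices[, 3])
  # proximal vertices stay in the top fraction (one face-edge of slack)
  ring_h <- diff(zr) / 28
  expect_gte(min(cr3$proximal$vertices[, 3]), zr[1] + 0.7 * diff(zr) - ring_h)
  expect_lt(mesh_area(cr3$proximal) + mesh_area(cr3$distal), mesh_area(tp$mesh))
  expect_error(crop_extremities(tp$mesh, 0.7, 0.6))
})

test_that("rasterization matches the analytic sphere volume and is deterministic", {
  sp <- make_icosphere(20, c(0, 0, 0), subdivisions = 4)
  bone <- list(mesh = sp, bone_kind = "femur")
  rc <- rasterize_ct(list(bone), spacing = 1, noise_sd = 0)
  cnt <- sum(rc$mask$labels == 1L)
  expect_equal(cnt, 4 / 3 * pi * 20^3, tolerance = 0.02)
  expect_identical(dim(rc$mask$labels), dim(rc$volume$intensities))
  r1 <- rasterize_ct(list(bone), spacing = 2, noise_sd = 25, seed = 4)
  r2 <- rasterize_ct(list(bone), spacing = 2, noise_sd = 25, seed = 4)
  expect_identical(r1$volume$intensities, r2$volume$intensities)
  expect_error(rasterize_ct(list(), spacing = 1))
})
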