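test_that("the default slice predictor thresholds exactly", {
  pred <- default_slice_predictor(200)
  lo <- matrix(40, 8, 9)
  expect_true(all(pred(lo) == 0))
  hi <- matrix(700, 8, 9)
  expect_true(all(pred(hi) == 1))
  set.seed(1)
  mix <- matrix(runif(72, 0, 800), 8, 9)
  expect_equal(sum(pred(mix)), sum(mix >= 200))
  expect_error(default_slice_predictor(Inf))
})

test_that("post-processing separates disjoint and touching bone pairs", {
  # disjoint spheres: two labels with per-sphere voxel counts
  s1 <- make_icosphere(15, c(0, 0, 25), 3)
  s2 <- make_icosphere(15, c(0, 0, -25), 3)
  rc <- rasterize_ct(list(list(mesh = s1, bone_kind = "femur"),
                          list(mesh = s2, bone_kind = "tibia")), 1, 0)
  seg <- segment_volume(rc$volume, default_slice_predictor(200), "knee",
                        smoothing_iters = 0L)
  expect_setequal(sort(unique(as.vector(seg$mask$labels))), c(0L, 1L, 2L))
  expect_equal(sum(seg$mask$labels == 1L), sum(rc$mask$labels == 1L), tolerance = 0.02)
  expect_equal(sum(seg$mask$labels == 2L), sum(rc$mask$labels == 2L), tolerance = 0.02)
  # femur is the more proximal (higher z) component
  d <- dim(seg$mask$labels)
  zf <- mean(arrayInd(which(seg$mask$labels == 1L), d)[, 3])
  zt <- mean(arrayInd(which(seg$mask$labels == 2L), d)[, 3])
  expect_gt(zf, zt)

  # overlapping spheres: watershed splits, centroids near the true centers
  s3 <- make_icosphere(15, c(0, 0, 14), 3)
  s4 <- make_icosphere(15, c(0, 0, -14), 3)
  rc2 <- rasterize_ct(list(list(mesh = s3, bone_kind = "femur"),
                           list(mesh = s4, bone_kind = "tibia")), 1, 0)
  seg2 <- segment_volume(rc2$volume, default_slice_predictor(200), "knee",
                         smoothing_iters = 0L)
  expect_true("watershed_used" %in% seg2$flags)
  d2 <- dim(seg2$mask$labels)
  for (lab in 1:2) {
    ij <- arrayInd(which(seg2$mask$labels == lab), d2)
    ctr <- colMeans(ij - 1) * rc2$mask$spacing + rc2$mask$origin
    truez <- if (lab == 1L) 14 else -14
    expect_lt(max(abs(ctr - c(0, 0, truez))), 1.5)
  }
})

test_that("post-processing is idempotent on a clean non-touching mask", {
  s1 <- make_icosphere(12, c(0, 0, 20), 3)
  s2 <- make_icosphere(12, c(0, 0, -20), 3)
  rc <- rasterize_ct(list(list(mesh = s1, bone_kind = "femur"),
                          list(mesh = s2, bone_kind = "tibia")), 1.5, 0)
  m1 <- postprocess_masks((rc$mask$labels > 0) * 1, rc$mask$spacing, "knee",
                          origin = rc$mask$origin)
  m2 <- postprocess_masks((m1$labels > 0) * 1, m1$spacing, "knee",
                          origin = m1$origin)
  expect_identical(m1$labels, m2$labels)
})

test_that("empty input yields a flagged empty mask, not an error", {
  vol <- ct_volume(array(40, c(20, 20, 10)), 2)
  seg <- segment_volume(vol, default_slice_predictor(200), "knee")
  expect_true("empty" %in% seg$flags)
  expect_true(all(seg$mask$labels == 0L))
  expect_length(seg$meshes, 0)
})

test_that("mask meshing tracks the analytic sphere and the voxel volume", {
  sp <- make_icosphere(20, c(0, 0, 0), subdivisions = 4)
  rc <- rasterize_ct(list(list(mesh = sp, bone_kind = "femur")), 1, 0)
  m <- mask_to_mesh(rc$mask, 1L, smoothing_iters = 10L)
  expect_true(mesh_is_watertight(m))
  d <- abs(sqrt(rowSums(m$vertices^2)) - 20)
  expect_lt(mean(d), 0.5)
  expect_equal(mesh_volume(m), sum(rc$mask$labels == 1L), tolerance = 0.03)
  # unsmoothed vertices sit on the half-integer voxel lattice
  m0 <- mask_to_mesh(rc$mask, 1L, smoothing_iters = 0L)
  vox <- sweep(m0$vertices, 2, rc$mask$origin) / rep(rc$mask$spacing, each = nrow(m0$vertices))
  fr <- (vox * 2) %% 1
  expect_lt(max(pmin(fr, 1 - fr)), 1e-9)
  expect_error(mask_to_mesh(rc$mask, 2L), "not found")
})

test_that("segmentation Dice degrades monotonically with CT noise", {
  tf <- coarse_template("femur")
  tt <- coarse_template("tibia")
  mean_dice <- sapply(c(0, 30, 80), function(noise) {
    mean(sapply(1:5, function(s) {
      ks <- knee_scene(sample_population(tf, 2, 6, 2, seed = s)[[1]],
                       sample_population(tt, 2, 6, 2, seed = s + 50)[[1]])
      rc <- rasterize_ct(list(ks$femur, ks$tibia), 2, noise, seed = s,
                         zlim = ks$knee_window)
      seg <- segment_volume(rc$volume, default_slice_predictor(200), "knee",
                            smoothing_iters = 0L)
      (dice(seg$mask, rc$mask, 1L) + dice(seg$mask, rc$mask, 2L)) / 2
    }))
  })
  expect_true(all(diff(mean_dice) <= 1e-6))
  expect_gt(mean_dice[1], 0.97)
})

test_that("meshing a rasterized bone converges to the surface as spacing shrinks", {
  tt <- coarse_template("tibia")
  L <- tt$length_mm
  win <- c(L - 70, L + 10)
  rmse_at <- function(sp) {
    rc <- rasterize_ct(list(tt), sp, 0, zlim = win)
    m <- mask_to_mesh(rc$mask, 2L, smoothing_iters = 5L)
    sel <- tt$mesh$vertices[, 3] > win[1] + 6 & tt$mesh$vertices[, 3] < L - 1
    sqrt(mean(point_mesh_distance(tt$mesh$vertices[sel, , drop = FALSE], m)$dist^2))
  }
  expect_lt(rmse_at(0.5), rmse_at(2))
})
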