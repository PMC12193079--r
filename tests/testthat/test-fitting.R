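rot_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

test_that("the bounding-box scale stage recovers known scalings", {
  m <- coarse_model("femur", P = 10)
  mean_mesh <- synthesize(m)$mesh
  cr <- crop_extremities(mean_mesh, 0.3, 0.3)
  po <- partial_observation(cr$proximal, cr$distal, "femur")
  expect_equal(init_scale(m, po), c(1, 1, 1), tolerance = 1e-6)
  big <- mesh_transform(mean_mesh, scale = 1.2)
  crb <- crop_extremities(big, 0.3, 0.3)
  pob <- partial_observation(crb$proximal, crb$distal, "femur")
  expect_equal(init_scale(m, pob), c(1.2, 1.2, 1.2), tolerance = 0.012)
  flat <- tri_mesh(cbind(cr$distal$vertices[, 1:2], 0), cr$distal$faces)
  expect_error(init_scale(m, partial_observation(flat, flat, "femur")),
               "degenerate")
})

test_that("rigid registration recovers identity, small rotations and the 180-degree flip", {
  m <- coarse_model("femur", P = 10)
  mean_mesh <- synthesize(m)$mesh
  cr <- crop_extremities(mean_mesh, 0.3, 0.3)
  po <- partial_observation(cr$proximal, cr$distal, "femur")
  pose <- rigid_register(m, po)
  expect_lt(max(abs(pose$R - diag(3))), 1e-4)
  expect_lt(max(abs(pose$t)), 1e-3)

  angle_err <- function(R, R0) {
    acos(pmin(pmax((sum(diag(crossprod(R0, R))) - 1) / 2, -1), 1)) * 180 / pi
  }
  R10 <- rot_z(10)
  rot_mesh <- mesh_transform(mean_mesh, rotation = R10)
  crr <- crop_extremities(rot_mesh, 0.3, 0.3)
  poser <- rigid_register(m, partial_observation(crr$proximal, crr$distal, "femur"))
  expect_lt(angle_err(poser$R, R10), 0.5)

  Rflip <- diag(c(1, -1, -1))  # 180 degrees about x: upside-down bone
  flip_mesh <- mesh_transform(mean_mesh, rotation = Rflip)
  crf <- crop_extremities(flip_mesh, 0.3, 0.3)
  posef <- rigid_register(m, partial_observation(crf$proximal, crf$distal, "femur"))
  expect_lt(angle_err(posef$R, Rflip), 0.5)
})

test_that("deformation fitting recovers generating coefficients from cropped data", {
  m <- coarse_model("femur", P = 14, seed = 7)
  N <- length(m$variances)
  set.seed(21)
  bstar <- rnorm(N) * 0.8
  gt <- synthesize(m, bstar)
  cr <- crop_extremities(gt$mesh, 0.3, 0.3)
  po <- partial_observation(cr$proximal, cr$distal, "femur")
  fit <- fit_partial(m, po)
  expect_lt(max(abs(fit$b - bstar)), 0.15)
  expect_lt(surface_distance(fit$reconstructed, gt$mesh)$rmse, 0.3)
  # fitting the cropped mean: the prior keeps b near zero
  crm <- crop_extremities(synthesize(m)$mesh, 0.3, 0.3)
  fitm <- fit_partial(m, partial_observation(crm$proximal, crm$distal, "femur"))
  expect_lt(sqrt(sum(fitm$b^2)), 0.1)
})

test_that("reconstruction maps the model through the fitted pose", {
  m <- coarse_model("tibia", P = 10, seed = 8)
  fit0 <- structure(list(scale = c(1, 1, 1), rotation = diag(3),
                         translation = c(0, 0, 0), b = rep(0, length(m$variances))),
                    class = "FitResult")
  rec <- reconstruct(m, fit0)
  expect_equal(rec$mesh$vertices, synthesize(m)$mesh$vertices, tolerance = 1e-12)
  expect_length(rec$landmarks$names, m$L)
  # round trip through crop + fit
  gt <- synthesize(m, rnorm_fixed(length(m$variances), seed = 4))
  cr <- crop_extremities(gt$mesh, 0.3, 0.3)
  fit <- fit_partial(m, partial_observation(cr$proximal, cr$distal, "tibia"))
  expect_lt(surface_distance(fit$reconstructed, gt$mesh)$rmse, 0.5)
  expect_identical(fit$landmarks$names, gt$landmarks$names)
})

test_that("fitting is equivariant under rotation of the partial input", {
  # the cropped mean gives a sharply determined optimum, so the two runs
  # converge to the same fixed point; for strongly deformed inputs the
  # flat (sliding) directions only converge to the stopping tolerance and
  # reconstructions agree to ~0.01 mm instead
  m <- coarse_model("femur", P = 10)
  gt <- synthesize(m)
  cr <- crop_extremities(gt$mesh, 0.3, 0.3)
  fit1 <- fit_partial(m, partial_observation(cr$proximal, cr$distal, "femur"))
  R <- rot_z(35) %*% rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  po2 <- partial_observation(mesh_transform(cr$proximal, rotation = R),
                             mesh_transform(cr$distal, rotation = R), "femur")
  fit2 <- fit_partial(m, po2)
  back <- tri_mesh(fit2$reconstructed$vertices %*% R, fit2$reconstructed$faces)
  d <- sqrt(mean((back$vertices - fit1$reconstructed$vertices)^2))
  expect_lt(d, 1e-3)
})

test_that("trimming makes the fit robust to osteophytes", {
  m <- coarse_model("femur", P = 12)
  tp <- coarse_template("femur")
  deg <- sapply(1:5, function(s) {
    gt <- sample_population(tp, 2, 6, 2, seed = 200 + s)[[1]]
    # severity 0.7 puts every bump height inside the trimmable band (above
    # the trimming floor, below the hard match cap); at lower severities the
    # ridge prior and the cap already neutralize the osteophytes and
    # trimming is a no-op
    path <- add_osteophytes(gt, 0.7, seed = s)
    crp <- crop_extremities(path$mesh, 0.3, 0.3)
    po <- partial_observation(crp$proximal, crp$distal, "femur")
    rob <- fit_partial(m, po, trim_frac = 0.10)
    naive <- fit_partial(m, po, trim_frac = 0)
    c(rob = surface_distance(rob$reconstructed, gt$mesh)$rmse,
      naive = surface_distance(naive$reconstructed, gt$mesh)$rmse)
  })
  expect_lt(mean(deg["rob", ]), mean(deg["naive", ]))
  # osteophytes cost less than 0.5 mm relative to the clean fit
  gt <- sample_population(tp, 2, 6, 2, seed = 300)[[1]]
  crc <- crop_extremities(gt$mesh, 0.3, 0.3)
  clean_fit <- fit_partial(m, partial_observation(crc$proximal, crc$distal, "femur"))
  path <- add_osteophytes(gt, 0.5, seed = 13)
  crp <- crop_extremities(path$mesh, 0.3, 0.3)
  rob_fit <- fit_partial(m, partial_observation(crp$proximal, crp$distal, "femur"))
  degr <- surface_distance(rob_fit$reconstructed, gt$mesh)$rmse -
    surface_distance(clean_fit$reconstructed, gt$mesh)$rmse
  expect_lt(degr, 0.5)
})
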