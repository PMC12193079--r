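test_that("the generalized Procrustes reference is a similarity-invariant fixed point", {
  tp <- coarse_template("femur")
  pts <- tp$mesh$vertices[seq(1, nrow(tp$mesh$vertices), by = 4), ]
  cs_id <- list(members = list(pts, pts, pts), V = nrow(pts), L = 0)
  ref <- build_reference(cs_id)
  tr <- procrustes_similarity(pts, ref)
  expect_lt(max(abs(apply_similarity(pts, tr) - ref)), 1e-8)

  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cs_rot <- list(members = list(pts, pts %*% t(R)), V = nrow(pts), L = 0)
  ref2 <- build_reference(cs_rot)
  tr2 <- procrustes_similarity(pts, ref2)
  expect_lt(sqrt(mean((apply_similarity(pts, tr2) - ref2)^2)), 1e-8)

  # converged mean is the coordinate-wise mean of the aligned members
  pop <- sample_population(tp, 10, 6, 2, seed = 2)
  cs <- corresponded_set(pop)
  ref3 <- build_reference(cs)
  aligned <- lapply(cs$members, function(X) {
    apply_similarity(X, procrustes_similarity(X, ref3))
  })
  mu <- Reduce(`+`, aligned) / length(aligned)
  mu <- sweep(mu, 2, colMeans(mu))
  mu <- mu * sqrt(sum(sweep(ref3, 2, colMeans(ref3))^2) / sum(mu^2))
  expect_lt(sqrt(mean((mu - ref3)^2)), 1e-6)

  cs_bad <- list(members = list(matrix(1, 10, 3), matrix(1, 10, 3)), V = 10, L = 0)
  expect_error(build_reference(cs_bad), "degenera")
})

test_that("non-rigid correspondence lands on targets in and out of the model class", {
  tp <- coarse_template("tibia")
  ref <- tp$mesh
  # identity target
  out <- correspond(ref, ref)
  expect_lt(max(abs(out$vertices - ref$vertices)), 1e-6)
  # pure similarity target
  sc <- mesh_transform(ref, scale = 1.1)
  out2 <- correspond(ref, sc)
  expect_lt(out2$residual, 0.01)
  # an off-template population member, treated as an arbitrary watertight mesh
  mem <- sample_population(tp, 2, 6, 2, seed = 31)[[1]]
  out3 <- correspond(ref, mem$mesh)
  expect_lt(out3$residual, 0.5)
})

test_that("PCA recovers the generator's latent dimension and training set exactly", {
  tp <- coarse_template("femur")
  # zero-variance population: all variances vanish
  p0 <- sample_population(tp, 3, 6, sd = 0, seed = 1, scale_jitter = FALSE)
  m0 <- build_model(corresponded_set(p0))
  expect_lt(max(m0$variances), 1e-10)
  # rank recovery at the 99.9% level (no scale jitter: exact latent rank)
  pop <- sample_population(tp, 30, 6, 2, seed = 3, scale_jitter = FALSE)
  m <- build_model(corresponded_set(pop))
  cf <- cumsum(m$variances) / sum(m$variances)
  expect_gte(cf[6], 0.999)
  # alignment is nonlinear in the coefficients, so a little variance leaks
  # past the latent rank; it stays orders of magnitude below the true modes
  expect_lt(m$variances[7] / m$variances[1], 5e-3)
  # with jitter the effective rank stays within k_latent + 1
  popj <- sample_population(tp, 30, 6, 2, seed = 3, scale_jitter = TRUE)
  mj <- build_model(corresponded_set(popj))
  cfj <- cumsum(mj$variances) / sum(mj$variances)
  expect_gte(cfj[7], 0.999)
  # training members are reproduced by the full model
  b <- project_coefficients(m, m$training[4, ])
  rec <- synthesize(m, b)
  expect_lt(max(abs(as.vector(t(rec$mesh$vertices)) -
                      m$training[4, seq_len(3 * m$V)])), 1e-6)
  expect_error(build_model(corresponded_set(p0[1:2])))
})

test_that("truncation keeps the smallest mode count reaching the threshold", {
  tm <- toy_model(c(3, 1, 0, 0))
  expect_length(truncate_model(tm, 0.99)$variances, 2L)
  # threshold 1 keeps every mode that still carries variance
  expect_length(truncate_model(toy_model(c(3, 1, 0.5, 0.25)), 1)$variances, 4L)
  m <- coarse_model("femur", P = 10, truncated = FALSE)
  for (thr in c(0.5, 0.9, 0.99, 0.999)) {
    mt <- truncate_model(m, thr)
    expect_gte(sum(mt$variances) / sum(m$variances), thr - 1e-12)
  }
})

test_that("synthesis is linear in sd-unit coefficients and invertible", {
  m <- coarse_model("tibia", P = 8, truncated = FALSE)
  mean_mesh <- synthesize(m)$mesh
  expect_equal(as.vector(t(mean_mesh$vertices)), m$mean[seq_len(3 * m$V)],
               tolerance = 1e-12)
  k <- 4
  e2 <- rep(0, k); e2[2] <- 1.7
  expect_equal(project_coefficients(m, c(as.vector(t(synthesize(m, e2)$mesh$vertices)),
                                         as.vector(t(synthesize(m, e2)$landmarks$points)) *
                                           m$landmark_weight))[2],
               1.7, tolerance = 1e-8)
  a <- c(0.5, -1, 0.3, 0); b <- c(-0.2, 0.4, 1, -1)
  va <- synthesize(m, a)$mesh$vertices - mean_mesh$vertices
  vb <- synthesize(m, b)$mesh$vertices - mean_mesh$vertices
  vab <- synthesize(m, a + b)$mesh$vertices - mean_mesh$vertices
  expect_equal(vab, va + vb, tolerance = 1e-9)
  expect_error(synthesize(m, rep(0, length(m$variances) + 1)))
})

test_that("compactness is a monotone variance fraction reaching 100 at full rank", {
  expect_equal(compactness(toy_model(c(2, 1, 1)), 1), 50)
  m <- coarse_model("femur", P = 10, truncated = FALSE)
  M <- length(m$variances)
  vals <- vapply(0:M, function(N) compactness(m, N), numeric(1))
  expect_equal(vals[1], 0)
  expect_equal(vals[M + 1], 100)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("generality vanishes inside the model subspace and decreases with modes", {
  m <- coarse_model("femur", P = 12, seed = 7, truncated = FALSE)
  tp <- coarse_template("femur")
  # the mean itself fits perfectly at any N
  mean_member <- vec_to_mem(m)
  g0 <- generality(m, list(members = list(mean_member), V = m$V, L = m$L), 0)
  expect_lt(g0[["mean"]], 1e-8)
  # held-out members: per-member error non-increasing in N
  ho <- sample_population(tp, 5, 6, 2, seed = 41)
  hs <- corresponded_set(ho)
  errs <- sapply(c(1, 3, 5, length(m$variances)), function(N) {
    attr(generality(m, hs, N), "per_member")
  })
  expect_true(all(diff(t(errs)) <= 1e-6))
  # in-subspace member is explained at N = M
  expect_lt(max(errs[, ncol(errs)]), 0.35)
  expect_error(generality(m, list(members = list(), V = m$V, L = m$L), 2))
})

test_that("specificity is deterministic and zero for a degenerate model", {
  tp <- coarse_template("tibia")
  p0 <- sample_population(tp, 3, 6, sd = 0, seed = 1, scale_jitter = FALSE)
  m0 <- build_model(corresponded_set(p0))
  s0 <- specificity(m0, N = 1, n_samples = 2, seed = 5)
  expect_lt(s0[["mean"]], 1e-6)
  m <- coarse_model("tibia", P = 8, truncated = FALSE)
  s1 <- specificity(m, N = 3, n_samples = 4, seed = 9)
  s2 <- specificity(m, N = 3, n_samples = 4, seed = 9)
  expect_identical(s1, s2)
  # brute-force recomputation with the same draws
  old <- kneeforge:::local_seed(9)
  draws <- replicate(4, stats::rnorm(3), simplify = FALSE)
  kneeforge:::restore_seed(old)
  brute <- sapply(draws, function(b) {
    mesh_s <- synthesize(m, b)$mesh
    min(sapply(seq_len(nrow(m$training)), function(i) {
      tm <- tri_mesh(matrix(m$training[i, seq_len(3 * m$V)], ncol = 3, byrow = TRUE),
                     m$faces)
      surface_distance(mesh_s, tm)$rmse
    }))
  })
  expect_equal(as.numeric(attr(s1, "per_sample")), as.numeric(brute), tolerance = 1e-12)
  expect_error(specificity(m, N = 2, n_samples = 0))
})
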