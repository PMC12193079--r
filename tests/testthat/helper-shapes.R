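# Shared fixtures, all generated in code: coarse templates keep the unit
# tests fast; full-resolution objects are reserved for the acceptance suite.

coarse_template <- function(bone_kind = "femur") {
  make_template(bone_kind, n_theta = 24L, n_z = 29L)
}

merge2 <- function(a, b) {
  tri_mesh(rbind(a$vertices, b$vertices),
           rbind(a$faces, b$faces + nrow(a$vertices)))
}

crop_to_partial <- function(bone, pf = 0.3, df = 0.3) {
  cr <- crop_extremities(bone$mesh, pf, df)
  partial_observation(cr$proximal, cr$distal, bone$bone_kind)
}

coarse_model <- function(bone_kind = "femur", P = 12, seed = 7, sd = 2,
                         truncated = TRUE) {
  pop <- sample_population(coarse_template(bone_kind), P, 6, sd, seed = seed)
  m <- build_model(corresponded_set(pop), bone_kind = bone_kind)
  if (truncated) truncate_model(m, 0.99) else m
}

rnorm_fixed <- function(n, seed) {
  old <- kneeforge:::local_seed(seed)
  on.exit(kneeforge:::restore_seed(old))
  stats::rnorm(n)
}

circle_contour <- function(r = 30, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  planar_contour(cbind(r * cos(th), r * sin(th)))
}

# the model mean as a corresponded member matrix (vertices then landmarks)
vec_to_mem <- function(m) {
  rbind(matrix(m$mean[seq_len(3 * m$V)], ncol = 3, byrow = TRUE),
        matrix(m$mean[3 * m$V + seq_len(3 * m$L)], ncol = 3, byrow = TRUE) /
          m$landmark_weight)
}

# minimal hand-built model for truncation/compactness arithmetic checks
toy_model <- function(variances) {
  M <- length(variances)
  structure(list(
    mean = rep(0, 3 * M), modes = diag(3 * M)[, seq_len(M), drop = FALSE],
    variances = variances, V = M, L = 0,
    faces = matrix(c(1L, 2L, 3L), 1, 3), landmark_names = character(0),
    landmark_weight = 1
  ), class = "ShapeModel")
}
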