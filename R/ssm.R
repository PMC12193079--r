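# Augmented statistical shape models: generalized Procrustes reference,
# non-rigid correspondence, PCA with landmark channels, truncation, synthesis
# and the Davies quality triad (compactness / generality / specificity).

#' Similarity Procrustes alignment (Umeyama)
#'
#' Least-squares similarity transform x -> s R x + t mapping `X` onto `Y`
#' (rows in correspondence).
#' @param X,Y n x 3 matrices
#' @param scale estimate an isotropic scale (default TRUE)
#' @return list with `s`, `R` (proper rotation), `t`
#' @export
procrustes_similarity <- function(X, Y, scale = TRUE) {
  n <- nrow(X)
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / n
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varX <- sum(Xc^2) / n
  if (varX < 1e-18) stop("numerical degeneracy: all points coincident")
  s <- if (scale) sum(diag(D) * sv$d) / varX else 1
  t <- my - s * as.vector(R %*% mx)
  list(s = s, R = R, t = t)
}

apply_similarity <- function(P, tr) {
  sweep(tr$s * P %*% t(tr$R), 2, tr$t, "+")
}

#' Assemble a corresponded set from a generator population
#'
#' Exploits the generator's exact correspondence: every member shares the
#' template topology, so vertex k is the same anatomical location everywhere.
#' @param bones list of `GroundTruthBone` sharing one template
#' @return a `CorrespondedSet`: members (vertex+landmark point matrices),
#'   shared faces, landmark names, V, L
#' @export
corresponded_set <- function(bones) {
  faces <- bones[[1]]$mesh$faces
  nms <- bones[[1]]$landmarks$names
  V <- nrow(bones[[1]]$mesh$vertices)
  members <- lapply(bones, function(b) {
    stopifnot(nrow(b$mesh$vertices) == V)
    rbind(b$mesh$vertices, b$landmarks$points)
  })
  structure(list(members = members, faces = faces, landmark_names = nms,
                 V = V, L = length(nms)), class = "CorrespondedSet")
}

#' @export
print.CorrespondedSet <- function(x, ...) {
  cat(sprintf("CorrespondedSet: %d members, %d vertices + %d landmarks\n",
              length(x$members), x$V, x$L))
  invisible(x)
}

#' Generalized Procrustes reference shape
#'
#' Iterated similarity alignment to the evolving mean until the mean moves by
#' less than `tol` mm (RMS) or `max_iter` iterations. The mean's centroid size
#' is held at the average centroid size of the input shapes, so millimetre
#' scale is preserved.
#'
#' @param cset a `CorrespondedSet` (P >= 2 members)
#' @param tol convergence tolerance on mean displacement (mm)
#' @param max_iter iteration cap
#' @return the converged mean point matrix (one row per vertex/landmark)
#' @export
build_reference <- function(cset, tol = 1e-6, max_iter = 50L) {
  shapes <- cset$members
  P <- length(shapes)
  if (P < 2) stop("need at least 2 members")
  csize <- function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    sqrt(sum(Xc^2))
  }
  sizes <- vapply(shapes, csize, numeric(1))
  if (any(sizes < 1e-12)) stop("numerical degeneracy: all points coincident")
  target_size <- mean(sizes)
  ref <- sweep(shapes[[1]], 2, colMeans(shapes[[1]]))
  ref <- ref * (target_size / csize(ref))
  for (it in seq_len(max_iter)) {
    aligned <- lapply(shapes, function(X) apply_similarity(X, procrustes_similarity(X, ref)))
    newref <- Reduce(`+`, aligned) / P
    newref <- sweep(newref, 2, colMeans(newref))
    newref <- newref * (target_size / csize(newref))
    shift <- sqrt(mean((newref - ref)^2))
    ref <- newref
    if (shift < tol) break
  }
  ref
}

#' Non-rigid correspondence by regularized ICP
#'
#' Deforms the reference topology onto an arbitrary watertight target:
#' similarity initialization, then `outer` iterations of closest-point
#' matching followed by a Laplacian-regularized displacement solve with
#' stiffness annealed geometrically from `stiff_hi` to `stiff_lo`.
#'
#' @param reference_mesh,target_mesh watertight `TriMesh` objects
#' @param outer outer iterations (default 10)
#' @param stiff_hi,stiff_lo stiffness annealing range
#' @param fail_mm residual (mm) above which correspondence is declared failed
#' @return list with `vertices` (reference topology on the target), `faces`,
#'   `residual` (mean distance to the target surface, mm)
#' @export
correspond <- function(reference_mesh, target_mesh, outer = 10L,
                       stiff_hi = 10, stiff_lo = 0.1, fail_mm = 5) {
  V <- reference_mesh$vertices
  Ft <- reference_mesh$faces
  # similarity initialization: centroid + z-extent scale, then a few
  # similarity ICP rounds
  tv <- target_mesh$vertices
  sc <- diff(range(tv[, 3])) / max(diff(range(V[, 3])), 1e-9)
  V <- sweep(sweep(V, 2, colMeans(V)) * sc, 2, colMeans(tv), "+")
  for (it in 1:8) {
    m <- point_mesh_distance(V, target_mesh)
    tr <- procrustes_similarity(V, m$closest)
    V <- apply_similarity(V, tr)
  }
  # uniform graph Laplacian of the reference topology
  E <- rbind(Ft[, c(1, 2)], Ft[, c(2, 3)], Ft[, c(3, 1)])
  E <- unique(t(apply(E, 1, sort)))
  n <- nrow(V)
  A <- Matrix::sparseMatrix(i = c(E[, 1], E[, 2]), j = c(E[, 2], E[, 1]),
                            x = 1, dims = c(n, n))
  Lp <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  ratio <- (stiff_lo / stiff_hi)^(1 / max(outer - 1, 1))
  for (k in seq_len(outer)) {
    alpha <- stiff_hi * ratio^(k - 1)
    m <- point_mesh_distance(V, target_mesh)
    rhs <- m$closest - V
    Msys <- Matrix::Diagonal(n) + alpha * Lp
    D <- as.matrix(Matrix::solve(Msys, rhs))
    V <- V + D
  }
  res <- mean(point_mesh_distance(V, target_mesh)$dist)
  if (res > fail_mm) {
    stop(sprintf("correspondence failure: residual %.2f mm > %.2f mm", res, fail_mm))
  }
  list(vertices = V, faces = Ft, residual = res)
}

shape_to_vec <- function(X) as.vector(t(X))
vec_to_shape <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Build an augmented statistical shape model
#'
#' Members are Procrustes-aligned (similarity, vertex block only) to the
#' generalized Procrustes reference; each member's 3V vertex coordinates and
#' 3L landmark coordinates (scaled by `landmark_weight`) are stacked into one
#' vector; PCA by singular value decomposition of the centered data matrix.
#' All M = min(P-1, 3(V+L)) modes are stored.
#'
#' @param cset a `CorrespondedSet` with P >= 3 members
#' @param landmark_weight weight of the landmark channel (default 1)
#' @param bone_kind optional label stored with the model
#' @param seed optional provenance seed recorded in the container
#' @return a `ShapeModel`
#' @export
build_model <- function(cset, landmark_weight = 1, bone_kind = NULL, seed = NULL) {
  P <- length(cset$members)
  if (P < 3) stop("need at least 3 members")
  V <- cset$V
  L <- cset$L
  vref <- build_reference(cset)[seq_len(V), , drop = FALSE]
  X <- matrix(0, P, 3 * (V + L))
  for (i in seq_len(P)) {
    mem <- cset$members[[i]]
    tr <- procrustes_similarity(mem[seq_len(V), , drop = FALSE], vref)
    al <- apply_similarity(mem, tr)
    lm <- al[V + seq_len(L), , drop = FALSE] * landmark_weight
    X[i, ] <- c(shape_to_vec(al[seq_len(V), , drop = FALSE]), shape_to_vec(lm))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(P - 1, ncol(Xc)))
  M <- min(P - 1, ncol(Xc))
  variances <- (sv$d[seq_len(M)]^2) / (P - 1)
  structure(list(
    mean = mu, modes = sv$v[, seq_len(M), drop = FALSE], variances = variances,
    V = V, L = L, faces = cset$faces, landmark_names = cset$landmark_names,
    landmark_weight = landmark_weight, bone_kind = bone_kind,
    training = X,
    provenance = list(seed = seed, P = P, built = format(Sys.Date()))
  ), class = "ShapeModel")
}

#' @export
print.ShapeModel <- function(x, ...) {
  cat(sprintf("ShapeModel (%s): %d vertices + %d landmarks, %d modes (w_L = %g)\n",
              x$bone_kind %||% "?", x$V, x$L, length(x$variances), x$landmark_weight))
  invisible(x)
}

#' Truncate a model to the smallest mode count retaining a variance fraction
#' @param model a `ShapeModel`
#' @param var_threshold fraction in (0, 1]
#' @return the truncated `ShapeModel`
#' @export
truncate_model <- function(model, var_threshold = 0.99) {
  if (var_threshold <= 0 || var_threshold > 1) stop("var_threshold must be in (0, 1]")
  frac <- cumsum(model$variances) / sum(model$variances)
  N <- which(frac >= var_threshold - 1e-12)[1]
  model$modes <- model$modes[, seq_len(N), drop = FALSE]
  model$variances <- model$variances[seq_len(N)]
  model
}

#' Synthesize a shape from mode coefficients
#'
#' Shape vector = mean + sum_i b_i sqrt(lambda_i) mode_i; coefficients are in
#' standard-deviation units. The landmark block is un-scaled by the landmark
#' weight on output.
#'
#' @param model a `ShapeModel`
#' @param b coefficient vector, length <= number of model modes
#' @return list with `mesh` (`TriMesh`) and `landmarks` (`LandmarkSet`)
#' @export
synthesize <- function(model, b = numeric(0)) {
  M <- length(model$variances)
  if (length(b) > M) stop("b longer than the model's mode count")
  vec <- model$mean
  if (length(b) > 0) {
    k <- length(b)
    vec <- vec + as.vector(model$modes[, seq_len(k), drop = FALSE] %*%
                             (b * sqrt(model$variances[seq_len(k)])))
  }
  nV <- 3 * model$V
  verts <- vec_to_shape(vec[seq_len(nV)])
  lms <- vec_to_shape(vec[nV + seq_len(3 * model$L)]) / model$landmark_weight
  list(
    mesh = tri_mesh(verts, model$faces),
    landmarks = landmark_set(model$landmark_names, lms,
                             default_risk_weights(model$landmark_names))
  )
}

#' Project a corresponded shape onto the model (full coefficients)
#' @param model a `ShapeModel`
#' @param vec stacked shape vector in model alignment
#' @return coefficients in sd units, length = mode count
#' @export
project_coefficients <- function(model, vec) {
  as.vector(crossprod(model$modes, vec - model$mean)) / sqrt(model$variances)
}

#' Compactness of a model at N modes (percent)
#' @param model a `ShapeModel`
#' @param N mode count (0..M)
#' @export
compactness <- function(model, N) {
  M <- length(model$variances)
  if (N < 0 || N > M) stop("N out of range")
  if (N == 0) return(0)
  100 * sum(model$variances[seq_len(N)]) / sum(model$variances)
}

align_member_to_model <- function(model, member) {
  V <- model$V
  L <- model$L
  mu_v <- vec_to_shape(model$mean[seq_len(3 * V)])
  tr <- procrustes_similarity(member[seq_len(V), , drop = FALSE], mu_v)
  al <- apply_similarity(member, tr)
  lm <- al[V + seq_len(L), , drop = FALSE] * model$landmark_weight
  c(shape_to_vec(al[seq_len(V), , drop = FALSE]), shape_to_vec(lm))
}

#' Generality: fit error on unseen corresponded shapes (mm)
#'
#' Each test member is similarity-aligned to the model mean, orthogonally
#' projected onto the first N modes, and scored by symmetric surface RMSE
#' between projection and member.
#'
#' @param model a `ShapeModel`
#' @param test_set a `CorrespondedSet` with the model topology
#' @param N number of modes used
#' @return c(mean, sd) in mm; per-member errors in attribute `per_member`
#' @export
generality <- function(model, test_set, N) {
  if (length(test_set$members) == 0) stop("empty test set")
  errs <- vapply(test_set$members, function(mem) {
    vec <- align_member_to_model(model, mem)
    r <- vec - model$mean
    k <- min(N, ncol(model$modes))
    proj <- model$mean
    if (k > 0) {
      B <- model$modes[, seq_len(k), drop = FALSE]
      proj <- proj + as.vector(B %*% crossprod(B, r))
    }
    mesh_p <- tri_mesh(vec_to_shape(proj[seq_len(3 * model$V)]), model$faces)
    mesh_m <- tri_mesh(vec_to_shape(vec[seq_len(3 * model$V)]), model$faces)
    surface_distance(mesh_p, mesh_m)$rmse
  }, numeric(1))
  out <- c(mean = mean(errs), sd = stats::sd(errs))
  attr(out, "per_member") <- errs
  out
}

#' Specificity: realism of randomly generated shapes (mm)
#'
#' Draw b ~ normal(0, I_N) in sd units, synthesize, and score each sample by
#' the minimum symmetric surface RMSE to any training member.
#'
#' @param model a `ShapeModel` (with stored training set)
#' @param N number of modes sampled
#' @param n_samples number of random samples (>= 1)
#' @param seed integer seed
#' @return c(mean, sd) in mm; per-sample errors in attribute `per_sample`
#' @export
specificity <- function(model, N, n_samples = 50L, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (is.null(model$training)) stop("model carries no training shapes")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  train_meshes <- apply(model$training, 1, function(row) {
    tri_mesh(vec_to_shape(row[seq_len(3 * model$V)]), model$faces)
  })
  errs <- vapply(seq_len(n_samples), function(s) {
    b <- stats::rnorm(N)
    mesh_s <- synthesize(model, b)$mesh
    min(vapply(train_meshes, function(tm) surface_distance(mesh_s, tm)$rmse,
               numeric(1)))
  }, numeric(1))
  out <- c(mean = mean(errs), sd = stats::sd(errs))
  attr(out, "per_sample") <- errs
  out
}
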