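#' Write a mesh to STL (binary or ASCII)
#'
#' @param mesh a `TriMesh`
#' @param path output file
#' @param binary write binary STL (default) or ASCII
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  fd <- mesh_face_data(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    tri <- matrix(0, nrow(F), 12)
    tri[, 1:3] <- fd$normals
    tri[, 4:6] <- V[F[, 1], , drop = FALSE]
    tri[, 7:9] <- V[F[, 2], , drop = FALSE]
    tri[, 10:12] <- V[F[, 3], , drop = FALSE]
    # interleave 12 floats + 2-byte attribute per facet
    for (f in seq_len(nrow(F))) {
      writeBin(as.numeric(tri[f, ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid kneeforge", con)
    for (f in seq_len(nrow(F))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g",
                         fd$normals[f, 1], fd$normals[f, 2], fd$normals[f, 3]), con)
      writeLines("outer loop", con)
      for (j in 1:3) {
        v <- V[F[f, j], ]
        writeLines(sprintf("vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
      }
      writeLines("endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid kneeforge", con)
  }
  invisible(path)
}

#' Read a mesh from STL (binary or ASCII), welding duplicate vertices
#' @param path STL file
#' @return a `TriMesh`
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !grepl("[^[:print:][:space:]]", suppressWarnings(rawToChar(head)))
  tri <- NULL
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    tri <- nums
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    tri <- matrix(0, nf * 3, 3)
    for (f in seq_len(nf)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(f - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  key <- paste(signif(tri[, 1], 10), signif(tri[, 2], 10), signif(tri[, 3], 10))
  ids <- match(key, unique(key))
  V <- tri[!duplicated(key), , drop = FALSE]
  F <- matrix(ids, ncol = 3, byrow = TRUE)
  tri_mesh(V, F)
}

#' Write a mesh to ASCII PLY
#' @param mesh a `TriMesh`
#' @param path output file
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices
  F <- mesh$faces
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(V)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(F)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path PLY file
#' @return a `TriMesh`
#' @export
read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  endh <- match("end_header", txt)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", txt, value = TRUE)[1]))
  vl <- txt[endh + seq_len(nv)]
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[1:3])))
  fl <- txt[endh + nv + seq_len(nf)]
  F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) as.integer(x[2:4]) + 1L))
  tri_mesh(V, F)
}

#' Write a landmark set to JSON
#'
#' Format: one object per landmark name with fields `point` ([x, y, z] in mm)
#' and `weight` (osteophyte-risk weight in [0, 1]).
#' @param landmarks a `LandmarkSet`
#' @param path output file
#' @export
write_landmarks_json <- function(landmarks, path) {
  obj <- lapply(seq_along(landmarks$names), function(i) {
    list(point = as.numeric(landmarks$points[i, ]),
         weight = as.numeric(landmarks$weights[i]))
  })
  names(obj) <- landmarks$names
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landmark set from JSON
#' @param path JSON file written by [write_landmarks_json()]
#' @return a `LandmarkSet`
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nms <- names(obj)
  pts <- do.call(rbind, lapply(obj, function(o) as.numeric(o$point)))
  w <- vapply(obj, function(o) as.numeric(o$weight), numeric(1))
  landmark_set(nms, pts, w)
}

#' Write a CT-like volume to NIfTI
#' @param volume a `CTVolume` or `LabelMask`
#' @param path output .nii or .nii.gz file
#' @export
write_volume_nifti <- function(volume, path) {
  arr <- if (!is.null(volume$intensities)) volume$intensities else volume$labels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  # origin goes in the affine (qform), RAS-style
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CT-like volume from NIfTI
#' @param path NIfTI file
#' @param as_labels interpret voxel data as integer labels
#' @return a `CTVolume` (or `LabelMask` if `as_labels`)
#' @export
read_volume_nifti <- function(path, as_labels = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  sp <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  orig <- aff[1:3, 4]
  if (as_labels) {
    label_mask(array(as.integer(round(arr)), dim = dim(arr)), sp, orig)
  } else {
    ct_volume(arr, sp, orig)
  }
}

#' Save a shape model container to JSON
#'
#' Named fields mirror the in-memory model: mean, modes, variances, topology,
#' landmark names, landmark weight, and provenance (seed, build date).
#' @param model a `ShapeModel`
#' @param path output .json file
#' @export
write_shape_model <- function(model, path) {
  obj <- list(
    container = "kneeforge-ssm",
    version = 1L,
    bone_kind = model$bone_kind %||% NA_character_,
    V = model$V, L = model$L,
    mean = as.numeric(model$mean),
    modes = list(dim = dim(model$modes), data = as.numeric(model$modes)),
    variances = as.numeric(model$variances),
    faces = list(dim = dim(model$faces), data = as.integer(model$faces)),
    landmark_names = model$landmark_names,
    landmark_weight = model$landmark_weight,
    provenance = model$provenance %||% list()
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a shape model container from JSON
#' @param path file written by [write_shape_model()]
#' @return a `ShapeModel`
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "kneeforge-ssm")) stop("not a kneeforge model container")
  structure(list(
    mean = as.numeric(obj$mean),
    modes = matrix(as.numeric(obj$modes$data), obj$modes$dim[1], obj$modes$dim[2]),
    variances = as.numeric(obj$variances),
    V = as.integer(obj$V), L = as.integer(obj$L),
    faces = matrix(as.integer(obj$faces$data), obj$faces$dim[1], obj$faces$dim[2]),
    landmark_names = as.character(obj$landmark_names),
    landmark_weight = as.numeric(obj$landmark_weight),
    bone_kind = obj$bone_kind,
    provenance = obj$provenance
  ), class = "ShapeModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
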