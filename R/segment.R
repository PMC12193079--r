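# Slice-wise segmentation with a pluggable predictor contract, followed by
# morphological post-processing, watershed femur/tibia separation and
# isosurface meshing with Taubin smoothing. The slice predictor stands in for
# a learned 2D model: anything mapping an intensity slice to foreground
# probabilities in [0, 1] plugs in without touching the post-processing.

#' Default thresholding slice predictor
#'
#' Returns a predictor emitting probability 1 where intensity >= threshold
#' and 0 elsewhere. Adequate for pseudo-CT where bone is far brighter than
#' background; a learned model can replace it behind the same contract.
#'
#' @param threshold_hu intensity threshold (HU)
#' @return function(slice matrix) -> probability matrix of the same shape
#' @export
default_slice_predictor <- function(threshold_hu = 200) {
  if (!is.finite(threshold_hu)) stop("threshold must be finite")
  function(slice) {
    out <- (slice >= threshold_hu) * 1.0
    dim(out) <- dim(slice)
    out
  }
}

#' Post-process per-slice probabilities into a separated label mask
#'
#' Per transverse slice: binarize at `prob_threshold`, morphological opening
#' then closing with a 3x3 box, and drop 2D components smaller than
#' `min_area_mm2`. Slices are then stacked; in 3D the two largest
#' 6-connected components are kept. If a knee acquisition yields a single
#' fused component, it is split by marker-based watershed on the inverted
#' interior distance transform, markers being the two largest distance maxima
#' at least `marker_min_separation_mm` apart (ties: larger distance, then
#' lower voxel index). Label 1 goes to the more proximal (higher z) component
#' for knee volumes, else by acquisition (hip = femur, ankle = tibia).
#'
#' @param prob_slices 3D array of foreground probabilities (x, y, z)
#' @param spacing length-3 voxel spacing (mm)
#' @param acquisition `"hip"`, `"knee"` or `"ankle"`
#' @param origin grid origin (mm)
#' @param cfg segmentation configuration (see [default_config()])
#' @return a `LabelMask`; attribute `flags` carries per-volume notes
#'   (`empty`, `watershed_used`)
#' @export
postprocess_masks <- function(prob_slices, spacing, acquisition = c("knee", "hip", "ankle"),
                              origin = c(0, 0, 0), cfg = default_config()$segment) {
  acquisition <- match.arg(acquisition)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  dims <- dim(prob_slices)
  bin <- prob_slices >= cfg$prob_threshold
  flags <- character(0)
  if (!any(bin)) {
    out <- label_mask(array(0L, dims), spacing, origin)
    attr(out, "flags") <- "empty"
    return(out)
  }
  brush <- EBImage::makeBrush(3, shape = "box")
  min_px <- cfg$min_area_mm2 / (spacing[1] * spacing[2])
  clean <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    sl <- bin[, , k]
    if (!any(sl)) next
    sl <- EBImage::closing(EBImage::opening(sl * 1, brush), brush) > 0.5
    if (any(sl)) {
      lab <- EBImage::bwlabel(sl * 1)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_px)
      sl <- array(lab %in% keep & lab > 0, dim(sl))
    }
    clean[, , k] <- sl
  }
  if (!any(clean)) {
    out <- label_mask(array(0L, dims), spacing, origin)
    attr(out, "flags") <- "empty"
    return(out)
  }
  cc <- cpp_connected_components(as.integer(clean), as.integer(dims))
  sizes <- cc$sizes
  ord <- order(sizes, decreasing = TRUE)
  comp <- array(cc$labels, dims)

  two_components <- length(sizes) >= 2 && sizes[ord[2]] >= 0.1 * sizes[ord[1]]
  labels <- array(0L, dims)
  if (acquisition == "knee" && !two_components) {
    # fused femur+tibia: split the largest component by watershed
    fg <- (comp == ord[1]) * 1L
    dt <- cpp_distance_transform(as.integer(fg), as.integer(dims), spacing)
    markers <- watershed_markers(dt, fg, dims, spacing, cfg$marker_min_separation_mm)
    if (is.null(markers)) {
      labels[fg == 1L] <- 1L
      flags <- c(flags, "watershed_no_markers")
    } else {
      ws <- cpp_watershed(as.numeric(dt), markers, as.integer(fg), as.integer(dims))
      labels <- array(as.integer(ws), dims)
      flags <- c(flags, "watershed_used")
    }
  } else if (acquisition == "knee") {
    labels[comp == ord[1]] <- 1L
    labels[comp == ord[2]] <- 2L
  } else {
    labels[comp == ord[1]] <- 1L
    if (two_components) labels[comp == ord[2]] <- 2L
  }

  labels <- assign_bone_labels(labels, acquisition, dims)
  out <- label_mask(labels, spacing, origin)
  attr(out, "flags") <- flags
  out
}

# two largest interior-distance maxima separated by >= min_sep mm
watershed_markers <- function(dt, fg, dims, spacing, min_sep) {
  d <- array(dt, dims)
  cand <- which(fg == 1L & d > max(d) * 0.2)
  if (length(cand) == 0) return(NULL)
  ij <- arrayInd(cand, dims)
  vals <- d[cand]
  # local maxima within the 26-neighbourhood, found on a coarse ordering
  ord <- order(vals, -cand, decreasing = TRUE)
  xyz <- sweep(ij[ord, , drop = FALSE], 2, spacing[1:3], "*")
  first <- 1
  second <- NA
  for (i in 2:length(ord)) {
    if (sqrt(sum((xyz[i, ] - xyz[first, ])^2)) >= min_sep) {
      second <- i
      break
    }
  }
  if (is.na(second)) return(NULL)
  markers <- integer(prod(dims))
  pick <- cand[ord[c(first, second)]]
  # label 1 = more proximal (higher z) marker
  zpos <- ij[ord[c(first, second)], 3]
  if (zpos[1] >= zpos[2]) {
    markers[pick[1]] <- 1L
    markers[pick[2]] <- 2L
  } else {
    markers[pick[1]] <- 2L
    markers[pick[2]] <- 1L
  }
  markers
}

# ensure label 1 = femur, 2 = tibia given the acquisition type
assign_bone_labels <- function(labels, acquisition, dims) {
  present <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(present) == 0) return(labels)
  if (length(present) == 1) {
    val <- if (acquisition == "ankle") 2L else 1L
    out <- labels
    out[labels == present] <- val
    return(out)
  }
  zc <- vapply(present, function(l) {
    mean(arrayInd(which(labels == l), dims)[, 3])
  }, numeric(1))
  out <- array(0L, dims)
  if (acquisition == "ankle") {
    # distal tibia dominates; keep both as tibia fragments is wrong - the
    # larger is the tibia, the other (fibula-like) is dropped
    big <- present[which.max(tabulate(labels[labels > 0])[present])]
    out[labels == big] <- 2L
  } else if (acquisition == "hip") {
    big <- present[which.max(tabulate(labels[labels > 0])[present])]
    out[labels == big] <- 1L
  } else {
    femur <- present[which.max(zc)]
    tibia <- present[which.min(zc)]
    out[labels == femur] <- 1L
    out[labels == tibia] <- 2L
  }
  out
}

#' Extract a smoothed triangle mesh from a label mask
#'
#' Isosurface at level 0.5 of the binary indicator via a tetrahedral
#' decomposition of the voxel grid (a watertight variant of marching cubes),
#' scaled by the voxel spacing and offset by the grid origin, then Taubin
#' lambda/mu smoothing (shrink-free) for `smoothing_iters` iterations.
#'
#' @param mask a `LabelMask`
#' @param label label to mesh (must be present)
#' @param smoothing_iters Taubin iterations (default 10)
#' @param cfg segmentation configuration
#' @return a watertight `TriMesh` in patient coordinates (mm)
#' @export
mask_to_mesh <- function(mask, label = 1L, smoothing_iters = 10L,
                         cfg = default_config()$segment) {
  ind <- mask$labels == label
  if (!any(ind)) stop(sprintf("label %d not found in mask", label))
  dims <- dim(mask$labels)
  # pad one background layer so the isosurface closes at the grid boundary
  pd <- dims + 2L
  field <- array(0, pd)
  field[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- ind * 1
  orig <- mask$origin - mask$spacing
  mt <- cpp_marching_tets(as.numeric(field), as.integer(pd), 0.5,
                          as.numeric(orig), as.numeric(mask$spacing))
  V <- mt$vertices
  F <- mt$faces
  if (smoothing_iters > 0) {
    V <- cpp_taubin_smooth(V, F, as.integer(smoothing_iters),
                           cfg$taubin_lambda, cfg$taubin_mu)
  }
  tri_mesh(V, F)
}

#' Segment a CT-like volume into per-bone meshes
#'
#' Applies the slice predictor to every transverse (fixed-z) slice, stacks
#' the probabilities, post-processes them into a separated label mask, and
#' meshes every present label.
#'
#' @param volume a `CTVolume`
#' @param predictor a slice predictor (see [default_slice_predictor()])
#' @param acquisition `"hip"`, `"knee"` or `"ankle"`
#' @param smoothing_iters Taubin iterations for meshing
#' @param cfg segmentation configuration
#' @return a `SegmentationResult`: list with `mask` (`LabelMask`), `meshes`
#'   (named by bone kind), `flags`
#' @export
segment_volume <- function(volume, predictor = default_slice_predictor(),
                           acquisition = c("knee", "hip", "ankle"),
                           smoothing_iters = 10L, cfg = default_config()$segment) {
  acquisition <- match.arg(acquisition)
  dims <- dim(volume$intensities)
  prob <- array(0, dims)
  for (k in seq_len(dims[3])) {
    p <- predictor(volume$intensities[, , k])
    if (!identical(dim(p), dims[1:2]) || min(p) < 0 || max(p) > 1) {
      stop("predictor output must match the slice shape with values in [0, 1]")
    }
    prob[, , k] <- p
  }
  mask <- postprocess_masks(prob, volume$spacing, acquisition,
                            origin = volume$origin, cfg = cfg)
  flags <- attr(mask, "flags")
  meshes <- list()
  for (lab in sort(setdiff(unique(as.vector(mask$labels)), 0L))) {
    kind <- if (lab == 1L) "femur" else "tibia"
    meshes[[kind]] <- mask_to_mesh(mask, lab, smoothing_iters, cfg)
  }
  structure(list(mask = mask, meshes = meshes, flags = flags),
            class = "SegmentationResult")
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat(sprintf("SegmentationResult: labels {%s}, meshes: %s%s\n",
              paste(sort(unique(as.vector(x$mask$labels))), collapse = ","),
              paste(names(x$meshes), collapse = ", "),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}
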