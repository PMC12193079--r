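#' Named 3D landmark set with osteophyte-risk weights
#'
#' @param names character vector of unique landmark names
#' @param points n x 3 matrix (mm)
#' @param weights per-landmark risk weights in [0, 1]; weight 0 means the
#'   landmark is never adjusted toward a segmented surface (osteophyte-prone
#'   zone), weight 1 means full adjustment
#' @return a `LandmarkSet`
#' @export
landmark_set <- function(names, points, weights = rep(0.8, length(names))) {
  points <- matrix(as.double(points), ncol = 3)
  names <- as.character(names)
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (nrow(points) != length(names)) stop("points/names length mismatch")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  rownames(points) <- names
  structure(list(names = names, points = points, weights = as.numeric(weights)),
            class = "LandmarkSet")
}

#' @export
print.LandmarkSet <- function(x, ...) {
  cat(sprintf("LandmarkSet: %d landmarks (%s)\n", length(x$names),
              paste(utils::head(x$names, 4), collapse = ", ")))
  invisible(x)
}

#' CT-like intensity volume
#' @param intensities 3D numeric array (HU-like)
#' @param spacing length-3 positive voxel spacing (mm)
#' @param origin length-3 position of voxel (1,1,1) center (mm)
#' @return a `CTVolume`
#' @export
ct_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L) stop("intensities must be a 3D array")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)), class = "CTVolume")
}

#' Integer label mask paired with a CT grid
#'
#' Labels: 0 = background, 1 = femur, 2 = tibia.
#' @param labels 3D integer array
#' @param spacing length-3 positive voxel spacing (mm)
#' @param origin length-3 position of voxel (1,1,1) center (mm)
#' @return a `LabelMask`
#' @export
label_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (!all(labels %in% c(0L, 1L, 2L))) stop("label values must be in {0, 1, 2}")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(labels = labels, spacing = spacing, origin = as.numeric(origin)),
            class = "LabelMask")
}

#' Voxel-center coordinates of a volume grid
#' @param vol a `CTVolume` or `LabelMask`
#' @return list of coordinate vectors x, y, z (mm)
#' @export
grid_coords <- function(vol) {
  d <- dim(vol$intensities %||% vol$labels)
  list(
    x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
    y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
    z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  )
}
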