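# End-to-end orchestration: segment -> fit -> landmarks -> design, with a
# machine-readable workflow report (statuses, metrics, timings, config hash).

#' Run the full planning workflow
#'
#' Inputs are either CT-like volumes for all three acquisitions
#' (`volumes$hip`, `$knee`, `$ankle` - both joint ends of each bone are needed
#' to make the reconstruction well-posed) or pre-segmented partial meshes
#' (`meshes$femur`, `meshes$tibia` as `PartialObservation`s). Both shape
#' models must be supplied up front; a missing model is a configuration error
#' and nothing executes. Each stage failure is recorded and downstream stages
#' are skipped.
#'
#' @param inputs list with `volumes` or `meshes` (see above)
#' @param models list with `femur` and `tibia` `ShapeModel`s (or file paths)
#' @param config full configuration (see [default_config()])
#' @param out_dir optional directory for artifacts (meshes, landmarks, report)
#' @return a `WorkflowReport` list
#' @export
run_workflow <- function(inputs, models, config = default_config(), out_dir = NULL) {
  for (bk in c("femur", "tibia")) {
    m <- models[[bk]]
    if (is.null(m)) stop(sprintf("configuration error: missing %s model", bk))
    if (is.character(m)) {
      if (!file.exists(m)) stop(sprintf("configuration error: missing %s model file: %s", bk, m))
      models[[bk]] <- read_shape_model(m)
    }
  }
  report <- list(stages = list(), config_hash = config_hash(config))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE, value = conditionMessage(e)))
    report$stages[[name]] <<- list(
      status = if (out$ok) "ok" else "failed",
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      reason = if (out$ok) NULL else out$value
    )
    if (!out$ok) return(NULL)
    out$value
  }

  partials <- NULL
  seg_meshes <- list(femur = NULL, tibia = NULL)
  seg_masks <- NULL
  if (!is.null(inputs$meshes)) {
    partials <- inputs$meshes
    seg_meshes$femur <- merge_meshes(partials$femur$proximal, partials$femur$distal)
    seg_meshes$tibia <- merge_meshes(partials$tibia$proximal, partials$tibia$distal)
    report$stages$segment <- list(status = "skipped (meshes supplied)", seconds = 0)
  } else {
    seg <- t_stage("segment", {
      pred <- default_slice_predictor(config$segment$threshold_hu)
      res <- lapply(names(inputs$volumes), function(acq) {
        segment_volume(inputs$volumes[[acq]], pred, acq,
                       smoothing_iters = config$segment$smoothing_iters,
                       cfg = config$segment)
      })
      names(res) <- names(inputs$volumes)
      res
    })
    if (is.null(seg)) return(finish_report(report, out_dir))
    knee <- seg$knee
    ok <- !is.null(knee) && !is.null(knee$meshes$femur) && !is.null(knee$meshes$tibia) &&
      !is.null(seg$hip) && !is.null(seg$hip$meshes$femur) &&
      !is.null(seg$ankle) && !is.null(seg$ankle$meshes$tibia)
    if (!ok) {
      report$stages$assemble <- list(
        status = "failed",
        reason = "full-bone reconstruction needs hip, knee and ankle segmentations (both joint ends of each bone)")
      return(finish_report(report, out_dir))
    }
    partials <- list(
      femur = partial_observation(
        proximal = seg$hip$meshes$femur,
        distal = knee$meshes$femur, bone_kind = "femur"),
      tibia = partial_observation(
        proximal = knee$meshes$tibia,
        distal = seg$ankle$meshes$tibia, bone_kind = "tibia")
    )
    seg_meshes$femur <- knee$meshes$femur
    seg_meshes$tibia <- knee$meshes$tibia
    seg_masks <- lapply(seg, function(s) s$mask)
    report$segmentation <- lapply(seg, function(s) s$flags)
  }

  fits <- t_stage("fit", {
    list(
      femur = fit_partial(models$femur, partials$femur,
                          ridge = config$fitting$ridge,
                          trim_frac = config$fitting$trim_frac,
                          iters = config$fitting$iters, cfg = config$fitting),
      tibia = fit_partial(models$tibia, partials$tibia,
                          ridge = config$fitting$ridge,
                          trim_frac = config$fitting$trim_frac,
                          iters = config$fitting$iters, cfg = config$fitting)
    )
  })
  if (is.null(fits)) return(finish_report(report, out_dir))
  report$fit <- lapply(fits, function(f)
    list(residual_rmse = f$residual_rmse, inlier_fraction = f$inlier_fraction,
         n_modes = length(f$b)))

  lms <- t_stage("landmarks", {
    lapply(fits, function(f) {
      prop <- propagate_landmarks(f, config$morpho)
      seg_m <- seg_meshes[[f$bone_kind]]
      if (!is.null(seg_m)) {
        refine_landmarks(prop, seg_m, config$morpho$max_shift_mm)
      } else prop
    })
  })
  if (is.null(lms)) return(finish_report(report, out_dir))

  design <- t_stage("design", {
    design_knee_implants(lms$femur, lms$tibia,
                         fits$femur$reconstructed, fits$tibia$reconstructed,
                         cfg = config$implant)
  })
  if (!is.null(design)) {
    report$design <- list(
      status = design$status,
      coverage = lapply(design$coverage, function(cv)
        list(rmse = cv$rmse, hausdorff = cv$hausdorff))
    )
  }
  report$results <- list(fits = fits, landmarks = lms, design = design,
                         partials = partials, seg_meshes = seg_meshes,
                         seg_masks = seg_masks)
  finish_report(report, out_dir)
}

finish_report <- function(report, out_dir) {
  class(report) <- "WorkflowReport"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res <- report$results
    if (!is.null(res)) {
      for (bk in names(res$fits)) {
        write_stl(res$fits[[bk]]$reconstructed,
                  file.path(out_dir, sprintf("%s_reconstructed.stl", bk)))
        write_landmarks_json(res$landmarks[[bk]],
                             file.path(out_dir, sprintf("%s_landmarks.json", bk)))
      }
    }
    slim <- report
    slim$results <- NULL
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.WorkflowReport <- function(x, ...) {
  cat("WorkflowReport\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s %s (%.1fs)%s\n", nm, st$status, st$seconds %||% 0,
                if (!is.null(st$reason)) paste0(" - ", st$reason) else ""))
  }
  invisible(x)
}

#' Score a workflow report against generator ground truth
#'
#' Appends Dice (when masks are supplied), reconstruction surface RMSE/HD,
#' and mean landmark error per bone to the report.
#'
#' @param report a `WorkflowReport` with in-memory results
#' @param truth list with `femur`, `tibia` (`GroundTruthBone`s in the same
#'   patient frame) and optionally `mask` (generator `LabelMask`)
#' @return the augmented `WorkflowReport`
#' @export
evaluate_against_truth <- function(report, truth) {
  res <- report$results
  if (is.null(res)) stop("report carries no results to evaluate")
  miss <- setdiff(c("femur", "tibia"), names(truth))
  if (length(miss)) stop(sprintf("missing truth entries: %s", paste(miss, collapse = ", ")))
  ev <- list()
  for (bk in c("femur", "tibia")) {
    sd_ <- surface_distance(res$fits[[bk]]$reconstructed, truth[[bk]]$mesh)
    lerr <- landmark_error(res$landmarks[[bk]], truth[[bk]]$landmarks)
    ev[[bk]] <- list(reconstruction_rmse = sd_$rmse,
                     reconstruction_hd = sd_$hausdorff,
                     landmark_mean_error = as.numeric(lerr))
  }
  if (!is.null(truth$mask) && !is.null(res$seg_masks$knee)) {
    ev$dice <- list(femur = dice(res$seg_masks$knee, truth$mask, 1L),
                    tibia = dice(res$seg_masks$knee, truth$mask, 2L))
  }
  report$evaluation <- ev
  report
}
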