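#' Default workflow configuration
#'
#' Every tunable named by the design modules lives here, grouped per module.
#' Units are mm and degrees unless noted.
#'
#' @return nested list of configuration values
#' @export
default_config <- function() {
  list(
    synth = list(
      n_theta = 44L, n_z = 57L,
      femur_length = 380, tibia_length = 360,
      scale_jitter = c(0.92, 1.08),
      shell_hu = 700, interior_hu = 300, background_hu = 40,
      shell_voxels = 2L, pad_mm = 10
    ),
    segment = list(
      threshold_hu = 200,
      prob_threshold = 0.5,
      min_area_mm2 = 30,
      marker_min_separation_mm = 10,
      smoothing_iters = 10L,
      taubin_lambda = 0.5, taubin_mu = -0.53
    ),
    ssm = list(
      landmark_weight = 1.0,
      var_threshold = 0.99,
      gpa_tol = 1e-6, gpa_max_iter = 50L,
      nricp_outer = 10L, nricp_stiff_hi = 10, nricp_stiff_lo = 0.1,
      nricp_fail_mm = 5
    ),
    fitting = list(
      ridge = 1.0, trim_frac = 0.10, iters = 40L,
      match_cap_mm = 5, dB_tol = 1e-6,
      icp_max_iter = 50L, icp_tol = 1e-6,
      register_fail_mm = 20, min_matches = 100L,
      crop_margin_mm = 3
    ),
    morpho = list(
      max_shift_mm = 5,
      risk_weights = list(
        MedialEpicondyle = 0.2, LateralEpicondyle = 0.2,
        MedialWearPoint = 0.2, LateralWearPoint = 0.2
      ),
      default_risk_weight = 0.8
    ),
    implant = list(
      distal_cut_mm = 9, posterior_cut_mm = 8, tibial_cut_mm = 8,
      tibial_slope_deg = 3,
      pivot_ratio = 0.33,
      rim_offset_mm = 0.5, posterior_retreat_mm = 3,
      femoral_rim_offset_mm = 0.25,
      fillet_radius_mm = 2,
      stem_scale = 0.35,
      rollback_angle_deg = 25,
      clearance_mm = 0.5, congruence_factor = 2.0, anterior_frac = 0.85,
      insert_margin_mm = 1.0,
      zones = list(
        tibial_posterior = c(0.35, 0.65),
        femoral_notch_halfwidth = 0.08,
        femoral_anterior_halfwidth = 0.06
      ),
      contour_step_mm = 0.5
    )
  )
}

#' Load a configuration YAML, merged over the defaults
#' @param path YAML file; `NULL` returns the defaults
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Stable hash of a configuration
#'
#' FNV-1a over the canonical (name-sorted) JSON serialization; changes iff
#' any configuration value changes.
#' @param cfg configuration list
#' @return hex string
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && any(nzchar(names(x)))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  s <- jsonlite::toJSON(canon(cfg), auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(as.character(s))
  h1 <- 17
  h2 <- 5381
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 33 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
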