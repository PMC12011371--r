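# Analysis configuration: one nested list of documented defaults per module,
# serializable to/from YAML.

#' Default analysis configuration
#'
#' Returns the full set of tunable parameters, grouped by module. Every
#' downstream operation is a pure function of (data, config, seed).
#'
#' Units: pixels for image-space parameters, micrometres/minutes for physical
#' ones. See the methods vignette for the rationale behind each default.
#'
#' @return A named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    invasion = list(
      smoothing_sigma   = 2,    # px, gelatin pre-smoothing before thresholding
      min_patch_area_px = 25,   # ~ area of one nucleus blob; removes speckle
      min_contrast      = 4,    # min (bright-dark)/within-sd to accept a mask
      detection_sigma   = 2,    # px, DAPI blob scale
      min_separation_px = 5,    # exclusion radius between detected nuclei
      rel_threshold     = 0.15, # fraction of max accepted as a blob
      match_radius_px   = 4     # viability dead/total point matching
    ),
    localization = list(
      edge_fraction  = 0.1,     # fraction of line ends used for background
      smooth_samples = 5,       # moving-average width for peak finding
      min_peak_sep_frac = 0.1   # min membrane peak separation, fraction of line
    ),
    calcium = list(
      response_window_min = 5,  # extremum search window after treatment
      direction = "auto",       # dip | spike | auto
      smooth_frames = 1,        # 1 = single-frame extremum (no smoothing)
      detrend = FALSE           # optional linear photobleaching detrend
    ),
    motility = list(
      max_disp_um      = 15,    # max frame-to-frame link length
      max_gap_frames   = 1,     # tolerated missed detections per track
      max_lag_fraction = 0.25,  # MSD lags used for fitting
      min_track_len    = 10
    ),
    mechanics = list(
      poisson       = 0.5,      # incompressible cell
      max_indent_um = 0.5,      # elastic regime: 10% of 5 um tip radius
      min_object_voxels = 50    # volume: discard components below this
    ),
    stats = list(
      fold_threshold = 5,       # strict > threshold retained
      equivocal = "exclude",    # exclude | as_negative
      ci_method = "wald",       # wald | wilson
      ci_level = 0.95
    )
  )
}

#' Write a configuration to a YAML file
#'
#' @param config nested list as returned by [default_config()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Values round-trip losslessly through [write_config()]. Missing groups are
#' filled from [default_config()] so partial configs stay valid.
#'
#' @param path path to a YAML config.
#' @return A named nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else user[[nm]]
  }
  base
}
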