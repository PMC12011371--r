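# Desk-scale study orchestration: simulate every modality for a set of
# labelled conditions, run each quantification, assemble the cross-assay
# study table and fit the scaling relations among its metrics.

#' Default study design
#'
#' Five conditions mimicking a crowding/pharmacology sweep (control at
#' normal density, two doses of a channel inhibitor, hyperosmotic medium,
#' overconfluent crowding): plasma-membrane channel fraction and motility
#' rise across the sweep while cell volume falls, so the cross-metric
#' scaling relations have known signs. Conditions are plain parameter sets,
#' not hard-coded biology; edit or replace them freely.
#'
#' @return Data frame of per-condition generator parameters.
#' @export
default_study_design <- function() {
  data.frame(
    condition = c("ND_control", "GSK219_low", "PEG300_2pct", "GSK219_high",
                  "OC_crowded"),
    pm_frac = c(0.15, 0.53, 0.55, 0.62, 0.78),
    nuc_frac = c(0.30, 0.17, 0.16, 0.14, 0.08),
    invasive_fraction = c(0.24, 0.38, 0.40, 0.48, 0.59),
    axis_a_um = c(10, 9.2, 9.0, 8.6, 8.0),
    axis_b_um = c(8, 7.4, 7.2, 6.9, 6.5),
    axis_c_um = c(6, 5.5, 5.4, 5.1, 4.5),
    D_um2_min = c(0.20, 0.33, 0.35, 0.42, 0.55),
    v_um_min = c(0.05, 0.09, 0.10, 0.12, 0.15),
    delta_ca = c(-49, -39, 324, -30, 2348),
    stringsAsFactors = FALSE
  )
}

#' Run the full synthetic study
#'
#' For each condition: simulate an invasion field, a line profile, an
#' ellipsoidal z-stack, a set of trajectories and a calcium trace with the
#' condition's parameters, quantify each with the corresponding analysis
#' operation, and collect one row per condition. Scaling relations are then
#' fitted between the plasma-membrane fraction, cell volume, invasive
#' fraction and diffusivity. Deterministic given (design, config, seed).
#'
#' @param design data frame as from [default_study_design()].
#' @param config analysis configuration ([default_config()]).
#' @param seed integer seed; each condition/assay derives a child seed.
#' @param n_cells_invasion cells per invasion field.
#' @param n_cells_motility trajectories per condition.
#' @param n_frames_motility frames per trajectory.
#' @param out_dir optional directory for CSV report files.
#' @return A `study_result` list: `table` (the per-condition study table),
#'   `scaling` (data frame of pairwise fits), `seed`.
#' @export
run_study <- function(design = default_study_design(),
                      config = default_config(), seed = config$seed,
                      n_cells_invasion = 100, n_cells_motility = 30,
                      n_frames_motility = 120, out_dir = NULL) {
  stopifnot(is.data.frame(design), nrow(design) >= 1)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    cond <- design[i, ]
    cseed <- child_seed(seed, paste0("study_", cond$condition))
    inv <- gen_invasion_field(n_cells = n_cells_invasion,
                              invasive_fraction = cond$invasive_fraction,
                              seed = cseed)
    mask <- segment_degradation(inv$gelatin,
                                config$invasion$min_patch_area_px,
                                config$invasion$smoothing_sigma,
                                config$invasion$min_contrast)
    pts <- detect_nuclei(inv$dapi, config$invasion$min_separation_px,
                         config$invasion$detection_sigma,
                         config$invasion$rel_threshold)
    inv_res <- invasive_fraction(mask, pts)
    cyto <- 1 - cond$pm_frac - cond$nuc_frac
    loc <- analyze_line_profile(
      gen_line_profile(cond$pm_frac, cyto, cond$nuc_frac,
                       seed = cseed)$profile,
      config$localization$edge_fraction,
      config$localization$smooth_samples,
      config$localization$min_peak_sep_frac
    )
    vol <- cell_volume(
      gen_ellipsoid_stack(c(cond$axis_a_um, cond$axis_b_um, cond$axis_c_um),
                          seed = cseed)$stack,
      config$mechanics$min_object_voxels
    )
    sim <- gen_trajectories(n_cells_motility, cond$D_um2_min, cond$v_um_min,
                            n_frames = n_frames_motility, seed = cseed)
    tracks <- link_trajectories(sim$frames, sim$dt,
                                config$motility$max_disp_um,
                                config$motility$max_gap_frames)
    mot <- vapply(tracks[vapply(tracks, function(tr)
      length(tr$time_min), numeric(1)) >= config$motility$min_track_len],
      function(tr) {
        a <- analyze_motility(tr, config$motility$max_lag_fraction)
        c(a$D_um2_min, a$v_um_min)
      }, numeric(2))
    ca <- delta_ca(
      gen_calcium_trace(delta_ca = cond$delta_ca, seed = cseed)$trace,
      config$calcium$response_window_min, config$calcium$direction,
      config$calcium$smooth_frames, config$calcium$detrend
    )
    data.frame(condition = cond$condition,
               pm_pct = loc$pm_pct,
               volume_um3 = vol$volume_um3,
               invasive_fraction = inv_res$invasive_fraction,
               D_um2_min = median(mot[1, ]),
               v_um_min = median(mot[2, ]),
               delta_ca = ca$delta_ca,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  scaling <- NULL
  if (nrow(tab) >= 3) {
    pairs <- list(c("pm_pct", "invasive_fraction"),
                  c("volume_um3", "invasive_fraction"),
                  c("pm_pct", "D_um2_min"),
                  c("volume_um3", "D_um2_min"),
                  c("D_um2_min", "invasive_fraction"))
    scaling <- do.call(rbind, lapply(pairs, function(p) {
      fit <- scaling_relation(tab[[p[1]]], tab[[p[2]]])
      data.frame(x = p[1], y = p[2], slope = fit$slope,
                 intercept = fit$intercept, r_squared = fit$r_squared,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(tab, file.path(out_dir, "study_table.csv"))
    if (!is.null(scaling)) {
      write_table(scaling, file.path(out_dir, "scaling_relations.csv"))
    }
    summary_lines <- c(
      sprintf("crowdquant study, seed %d, %d condition(s)", seed, nrow(tab)),
      utils::capture.output(print(tab, row.names = FALSE)),
      if (!is.null(scaling)) utils::capture.output(print(scaling,
                                                         row.names = FALSE))
    )
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }
  structure(list(table = tab, scaling = scaling, seed = seed),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d condition(s), seed %d\n", nrow(x$table),
              x$seed))
  print(x$table, row.names = FALSE)
  if (!is.null(x$scaling)) {
    cat("scaling relations:\n")
    print(x$scaling, row.names = FALSE)
  }
  invisible(x)
}
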