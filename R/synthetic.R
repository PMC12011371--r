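# Synthetic-data generators. Each modality used by the pipeline can be
# simulated with known ground truth, so every analysis stage is testable
# without an external dataset. All generators are deterministic given
# (parameters, seed); each draws from a child RNG stream keyed by the
# generator name, so adding one generator never perturbs another's output.

# -- gelatin degradation field -------------------------------------------------

#' Simulate a gelatin-degradation invasion field
#'
#' Produces a bright gelatin-fluorescence image with dark circular degradation
#' patches under the designated invasive nuclei, and a matching nuclear-stain
#' image with point-like (Gaussian) nuclei, mimicking low-magnification
#' imaging of a 2D matrix-degradation invasion assay.
#'
#' @param n_cells number of nuclei (>= 1).
#' @param invasive_fraction true fraction of invasive cells in `[0, 1]`.
#' @param field_px side length of the square field, pixels.
#' @param degraded_patch_radius_px radius of each dark degradation patch.
#' @param noise_sd additive Gaussian noise sd on the gelatin channel
#'   (background level is 1); the nuclear channel gets `noise_sd / 5`.
#' @param seed integer seed.
#' @return A list with `gelatin` and `dapi` ([fluorescence_image]s) and
#'   `truth` (data frame `row`, `col`, `invasive`, plus attributes
#'   `invasive_fraction`, `patch_area_px`).
#' @export
gen_invasion_field <- function(n_cells = 100, invasive_fraction = 0.4,
                               field_px = 384, degraded_patch_radius_px = 8,
                               noise_sd = 0.05, seed = 1) {
  stopifnot(n_cells >= 1, invasive_fraction >= 0, invasive_fraction <= 1)
  r <- degraded_patch_radius_px
  n_inv <- round(n_cells * invasive_fraction)
  withr::with_seed(child_seed(seed, "invasion_field"), {
    margin <- r + 4
    if (2 * margin >= field_px) stop("patches do not fit in the field")
    # non-overlapping patch centres by rejection sampling
    centres <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(centres) < n_inv) {
      cand <- runif(2, margin + 1, field_px - margin)
      ok <- nrow(centres) == 0 ||
        min(sqrt(rowSums((centres - rep(cand, each = nrow(centres)))^2))) >
          2 * r + 4
      if (ok) centres <- rbind(centres, cand)
      tries <- tries + 1
      if (tries > 5000 * max(1, n_inv)) {
        stop("infeasible packing: too many non-overlapping patches requested")
      }
    }
    # invasive nuclei near their patch centre (well inside the patch)
    nuc <- matrix(NA_real_, n_cells, 2)
    if (n_inv > 0) {
      jitter <- matrix(runif(2 * n_inv, -1, 1), ncol = 2)
      nuc[seq_len(n_inv), ] <- centres + jitter
    }
    # non-invasive nuclei outside every patch, not too close to each other
    k <- n_inv
    tries <- 0
    while (k < n_cells) {
      cand <- runif(2, 5, field_px - 4)
      far_patch <- n_inv == 0 ||
        min(sqrt(rowSums((centres - rep(cand, each = n_inv))^2))) > r + 5
      placed <- nuc[seq_len(k), , drop = FALSE]
      # nuclei kept resolvable: separation well above the blob FWHM
      far_nuc <- k == 0 ||
        min(sqrt(rowSums((placed - rep(cand, each = k))^2))) > 12
      if (far_patch && far_nuc) {
        k <- k + 1
        nuc[k, ] <- cand
      }
      tries <- tries + 1
      if (tries > 20000 * n_cells) stop("infeasible packing of nuclei")
    }
    gelatin <- matrix(1, field_px, field_px)
    if (n_inv > 0) {
      for (i in seq_len(n_inv)) {
        gelatin <- draw_disk(gelatin, centres[i, 1], centres[i, 2], r, 0.2)
      }
    }
    gelatin <- as.matrix(EBImage::gblur(gelatin, sigma = 1))
    gelatin <- pmax(gelatin + rnorm(length(gelatin), 0, noise_sd), 0)
    dapi <- matrix(0, field_px, field_px)
    for (i in seq_len(n_cells)) {
      dapi <- add_gaussian_blob(dapi, nuc[i, 1], nuc[i, 2], sigma = 2, amp = 1)
    }
    dapi <- pmax(dapi + rnorm(length(dapi), 0, noise_sd / 5), 0)
    truth <- data.frame(row = nuc[, 1], col = nuc[, 2],
                        invasive = seq_len(n_cells) <= n_inv)
    attr(truth, "invasive_fraction") <- n_inv / n_cells
    attr(truth, "patch_area_px") <- n_inv * pi * r^2
    list(gelatin = fluorescence_image(gelatin, channel = "Gelatin488"),
         dapi = fluorescence_image(dapi, channel = "DAPI"),
         truth = truth)
  })
}

draw_disk <- function(img, row, col, r, value) {
  rows <- max(1, floor(row - r)):min(nrow(img), ceiling(row + r))
  cols <- max(1, floor(col - r)):min(ncol(img), ceiling(col + r))
  d2 <- outer((rows - row)^2, (cols - col)^2, "+")
  img[rows, cols][d2 <= r^2] <- value
  img
}

add_gaussian_blob <- function(img, row, col, sigma, amp) {
  ext <- ceiling(4 * sigma)
  rows <- max(1, floor(row - ext)):min(nrow(img), ceiling(row + ext))
  cols <- max(1, floor(col - ext)):min(ncol(img), ceiling(col + ext))
  g <- amp * exp(-outer((rows - row)^2, (cols - col)^2, "+") / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + g
  img
}

# -- three-channel line profile ------------------------------------------------

#' Simulate a three-channel line profile across one cell
#'
#' The membrane-dye channel has two Gaussian peaks where the line crosses the
#' plasma membrane; the nuclear-dye channel has a flat-topped plateau in the
#' middle; the channel of interest is piecewise constant so that its mean
#' inside each true compartment window is proportional to the requested
#' compartment fraction.
#'
#' @param pm_frac,cyto_frac,nuc_frac true compartment fractions; must sum
#'   to 1 within 1e-9.
#' @param n_samples samples along the line (>= 20).
#' @param length_um physical line length.
#' @param noise_sd additive Gaussian noise sd on every channel (intensity
#'   scale: compartment levels are `100 * fraction`, dye peaks are 100).
#' @param geometry list with `pm_pos_frac` (two membrane-crossing positions as
#'   fractions of the line), `pm_sigma_um`, `nuc_center_frac`,
#'   `nuc_halfwidth_um`.
#' @param seed integer seed.
#' @return list with `profile` (a [line_profile]) and `truth` (window index
#'   vectors and the true fractions).
#' @export
gen_line_profile <- function(pm_frac, cyto_frac, nuc_frac,
                             n_samples = 200, length_um = 40, noise_sd = 2,
                             geometry = list(pm_pos_frac = c(0.15, 0.85),
                                             pm_sigma_um = 1.2,
                                             nuc_center_frac = 0.5,
                                             nuc_halfwidth_um = 6),
                             seed = 1) {
  fr <- c(pm_frac, cyto_frac, nuc_frac)
  if (any(fr < 0)) stop("fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1")
  x <- seq(0, length_um, length.out = n_samples)
  p <- geometry$pm_pos_frac * length_um
  nc <- geometry$nuc_center_frac * length_um
  if (!(p[1] < nc && nc < p[2])) stop("membrane peaks must flank the nucleus")
  membrane <- 100 * (exp(-(x - p[1])^2 / (2 * geometry$pm_sigma_um^2)) +
                     exp(-(x - p[2])^2 / (2 * geometry$pm_sigma_um^2)))
  nuclear <- 100 * exp(-((x - nc) / geometry$nuc_halfwidth_um)^8)
  # true half-maximum windows from the noise-free dye channels
  pm1 <- contiguous_above(membrane, which.min(abs(x - p[1])), 50)
  pm2 <- contiguous_above(membrane, which.min(abs(x - p[2])), 50)
  nw <- contiguous_above(nuclear, which.max(nuclear), 50)
  if (max(pm1) >= min(nw) || min(pm2) <= max(nw)) {
    stop("overlapping PM/nucleus windows")
  }
  cy1 <- (max(pm1) + 1):(min(nw) - 1)
  cy2 <- (max(nw) + 1):(min(pm2) - 1)
  target <- numeric(n_samples)
  target[c(pm1, pm2)] <- 100 * pm_frac
  target[c(cy1, cy2)] <- 100 * cyto_frac
  target[nw] <- 100 * nuc_frac
  withr::with_seed(child_seed(seed, "line_profile"), {
    profile <- line_profile(
      position_um = x,
      target = pmax(target + rnorm(n_samples, 0, noise_sd), 0),
      membrane_dye = pmax(membrane + rnorm(n_samples, 0, noise_sd), 0),
      nuclear_dye = pmax(nuclear + rnorm(n_samples, 0, noise_sd), 0)
    )
    truth <- list(pm_windows = list(pm1, pm2), nucleus_window = nw,
                  cytosol_windows = list(cy1, cy2),
                  pm_frac = pm_frac, cyto_frac = cyto_frac,
                  nuc_frac = nuc_frac)
    list(profile = profile, truth = truth)
  })
}

contiguous_above <- function(y, peak_idx, level) {
  lo <- peak_idx
  while (lo > 1 && y[lo - 1] >= level) lo <- lo - 1
  hi <- peak_idx
  while (hi < length(y) && y[hi + 1] >= level) hi <- hi + 1
  lo:hi
}

# -- trajectories --------------------------------------------------------------

#' Simulate 2D cell trajectories with diffusion and drift
#'
#' Each cell moves with a constant drift of speed `v` in a random direction
#' plus isotropic Gaussian steps with per-axis variance `2 * D * dt`, the
#' standard diffusion-with-drift model whose ensemble MSD is
#' `4 D tau + (v tau)^2`.
#'
#' @param n_cells number of cells.
#' @param D diffusivity, um^2/min (>= 0).
#' @param v drift (directional) speed, um/min (>= 0).
#' @param dt frame interval, min.
#' @param n_frames frames per trajectory (n_frames - 1 steps).
#' @param spacing_um starting-grid spacing between cells.
#' @param seed integer seed.
#' @return list with `frames` (per-frame matrices of `(x, y)` positions, rows
#'   in a fixed cell order), `dt`, and `truth` (per-cell `D`, `v`, drift
#'   angles, full true tracks).
#' @export
gen_trajectories <- function(n_cells, D, v, dt = 1, n_frames = 180,
                             spacing_um = 60, seed = 1) {
  stopifnot(D >= 0, v >= 0, n_frames >= 2)
  withr::with_seed(child_seed(seed, "trajectories"), {
    side <- ceiling(sqrt(n_cells))
    gx <- ((seq_len(n_cells) - 1) %% side) * spacing_um
    gy <- ((seq_len(n_cells) - 1) %/% side) * spacing_um
    ang <- runif(n_cells, 0, 2 * pi)
    sd_step <- sqrt(2 * D * dt)
    tracks <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      dx <- v * dt * cos(ang[i]) + rnorm(n_frames - 1, 0, sd_step)
      dy <- v * dt * sin(ang[i]) + rnorm(n_frames - 1, 0, sd_step)
      tracks[[i]] <- cbind(x = gx[i] + c(0, cumsum(dx)),
                           y = gy[i] + c(0, cumsum(dy)))
    }
    frames <- lapply(seq_len(n_frames), function(f) {
      t(vapply(tracks, function(tr) tr[f, ], numeric(2)))
    })
    list(frames = frames, dt = dt,
         truth = list(D = D, v = v, angles = ang, tracks = tracks))
  })
}

# -- calcium trace -------------------------------------------------------------

#' Simulate a Fluo-4 calcium trace with a treatment-locked transient
#'
#' Flat baseline, then an instantaneous step of signed amplitude `delta_ca`
#' at the first post-treatment frame, relaxing back exponentially with time
#' constant `recovery_tau` (use `Inf` for no recovery), plus additive
#' Gaussian noise. The transient shape is a modelling choice; amplitude
#' extraction must not depend on it.
#'
#' @param baseline baseline intensity (a.u.).
#' @param delta_ca signed transient amplitude (negative = dip).
#' @param treatment_frame last pre-treatment frame index; the response starts
#'   at `treatment_frame + 1`.
#' @param recovery_tau recovery time constant, min.
#' @param noise_sd additive Gaussian noise sd.
#' @param n_frames total frames (>= treatment_frame + 10).
#' @param dt_min frame interval, min.
#' @param seed integer seed.
#' @return list with `trace` (a [calcium_trace]) and `truth`.
#' @export
gen_calcium_trace <- function(baseline = 500, delta_ca = -49,
                              treatment_frame = 11, recovery_tau = 5,
                              noise_sd = 0.5, n_frames = 70, dt_min = 0.5,
                              seed = 1) {
  stopifnot(treatment_frame >= 1, treatment_frame < n_frames)
  if (n_frames < treatment_frame + 10) {
    stop("n_frames must be at least treatment_frame + 10")
  }
  tm <- (seq_len(n_frames) - 1) * dt_min
  y <- rep(baseline, n_frames)
  post <- (treatment_frame + 1):n_frames
  y[post] <- baseline +
    delta_ca * exp(-(tm[post] - tm[treatment_frame + 1]) / recovery_tau)
  withr::with_seed(child_seed(seed, "calcium_trace"), {
    y <- y + rnorm(n_frames, 0, noise_sd)
  })
  trace <- calcium_trace(time_min = tm, intensity = y,
                         treatment_time = tm[treatment_frame] + dt_min / 2)
  list(trace = trace,
       truth = list(baseline = baseline, delta_ca = delta_ca,
                    extremum_frame = treatment_frame + 1))
}

# -- force curve ---------------------------------------------------------------

#' Simulate a nanoindentation force curve
#'
#' Generates an instrument-like approach curve: indenter position, cantilever
#' deflection. Before the contact point the deflection is zero (plus noise);
#' beyond it the tip indents the sample following the Hertz spherical contact
#' law `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)`, with the cantilever
#' equilibrium `k d = F(z - z0 - d)` solved self-consistently.
#'
#' @param E_kPa true Young's modulus, kPa.
#' @param tip_radius_um spherical tip radius, um.
#' @param poisson Poisson ratio (0.5 = incompressible).
#' @param spring_constant_N_per_m cantilever spring constant, N/m.
#' @param contact_point_um contact point along the position axis, um.
#' @param max_indent_um maximum indentation depth generated, um.
#' @param noise_sd force-equivalent noise sd, nN (applied to the deflection).
#' @param n_samples samples along the approach.
#' @param seed integer seed.
#' @return list with `curve` (a [force_curve]) and `truth`.
#' @export
gen_force_curve <- function(E_kPa, tip_radius_um = 5, poisson = 0.5,
                            spring_constant_N_per_m = 0.24,
                            contact_point_um = 2, max_indent_um = 1,
                            noise_sd = 0.05, n_samples = 200, seed = 1) {
  stopifnot(E_kPa > 0, tip_radius_um > 0, max_indent_um > 0,
            poisson >= 0, poisson <= 0.5)
  k_nN_um <- spring_constant_N_per_m * 1000  # nN per um of deflection
  hertz <- function(delta) {
    (4 / 3) * (E_kPa / (1 - poisson^2)) * sqrt(tip_radius_um) *
      pmax(delta, 0)^1.5
  }
  z_max <- contact_point_um + max_indent_um * 1.3
  z <- seq(0, z_max, length.out = n_samples)
  d <- numeric(n_samples)
  for (i in which(z > contact_point_um)) {
    di <- 0
    for (it in 1:80) {  # contraction: |H'|/k << 1 for cell-scale moduli
      dn <- hertz(z[i] - contact_point_um - di) / k_nN_um
      if (abs(dn - di) < 1e-12) break
      di <- dn
    }
    d[i] <- di
  }
  withr::with_seed(child_seed(seed, "force_curve"), {
    d_noisy <- d + rnorm(n_samples, 0, noise_sd / k_nN_um)
  })
  curve <- force_curve(indenter_position_um = z, deflection_um = d_noisy,
                       spring_constant_N_per_m = spring_constant_N_per_m,
                       tip_radius_um = tip_radius_um)
  list(curve = curve,
       truth = list(E_kPa = E_kPa, contact_point_um = contact_point_um,
                    poisson = poisson, force_nN = d * k_nN_um))
}

# -- ellipsoid z-stack ---------------------------------------------------------

#' Simulate an ellipsoidal cell as a confocal z-stack
#'
#' Voxels whose centres fall inside the ellipsoid are bright, the exterior is
#' dim, and Gaussian noise is added. The true volume is
#' `4/3 * pi * a * b * c`.
#'
#' @param semi_axes_um semi-axes `(a, b, c)` in um, all > 0.
#' @param pixel_size_um lateral voxel size.
#' @param z_step_um axial voxel size.
#' @param noise_sd additive Gaussian noise sd (interior level 1, exterior 0.1).
#' @param pad_um padding around the ellipsoid.
#' @param seed integer seed.
#' @return list with `stack` (a [z_stack]) and `truth` (`volume_um3`).
#' @export
gen_ellipsoid_stack <- function(semi_axes_um = c(10, 8, 6),
                                pixel_size_um = 0.5, z_step_um = 0.5,
                                noise_sd = 0.05, pad_um = 3, seed = 1) {
  a <- semi_axes_um
  if (length(a) != 3 || any(a <= 0)) stop("semi-axes must be three positive values")
  nr <- ceiling(2 * (a[1] + pad_um) / pixel_size_um)
  nc <- ceiling(2 * (a[2] + pad_um) / pixel_size_um)
  nz <- ceiling(2 * (a[3] + pad_um) / z_step_um)
  rr <- ((seq_len(nr) - 0.5) - nr / 2) * pixel_size_um
  cc <- ((seq_len(nc) - 0.5) - nc / 2) * pixel_size_um
  zz <- ((seq_len(nz) - 0.5) - nz / 2) * z_step_um
  q <- outer(outer((rr / a[1])^2, (cc / a[2])^2, "+"), (zz / a[3])^2, "+")
  vox <- ifelse(q <= 1, 1, 0.1)
  withr::with_seed(child_seed(seed, "ellipsoid_stack"), {
    vox <- pmax(vox + array(rnorm(length(vox), 0, noise_sd), dim(vox)), 0)
  })
  list(stack = z_stack(vox, pixel_size_um, z_step_um),
       truth = list(volume_um3 = 4 / 3 * pi * prod(a)))
}

# -- concordance table ---------------------------------------------------------

#' Simulate a two-rater diagnostic concordance table
#'
#' Per-ROI rows with a pathology grade and a merged two-rater call
#' (`Y` = both raters saw plasma-membrane channel, `N` = both did not,
#' `E` = the raters disagreed), drawn Bernoulli from a requested operating
#' point.
#'
#' @param n_high_grade number of high-grade DCIS ROIs (the positive class).
#' @param n_lower_risk number of lower-risk ROIs (normal through
#'   intermediate-grade DCIS), cycled across the lower-risk grades.
#' @param sensitivity P(Y | high grade) among non-equivocal calls.
#' @param specificity P(N | lower risk) among non-equivocal calls.
#' @param equivocal_rate P(E) for any ROI.
#' @param n_idc optional invasive-carcinoma ROIs (excluded from specificity
#'   by the analysis).
#' @param idc_positive_rate P(Y | IDC) among non-equivocal calls.
#' @param seed integer seed.
#' @return list with `table` (data frame `roi_id`, `grade`, `call`) and
#'   `truth`.
#' @export
gen_concordance_table <- function(n_high_grade = 20, n_lower_risk = 62,
                                  sensitivity = 0.75, specificity = 61 / 62,
                                  equivocal_rate = 0, n_idc = 0,
                                  idc_positive_rate = 0.73, seed = 1) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, equivocal_rate >= 0, equivocal_rate <= 1)
  lower <- c("normal", "benign", "ADH", "DCIS_low", "DCIS_intermediate")
  withr::with_seed(child_seed(seed, "concordance_table"), {
    draw <- function(n, p_pos) {
      eq <- runif(n) < equivocal_rate
      pos <- runif(n) < p_pos
      ifelse(eq, "E", ifelse(pos, "Y", "N"))
    }
    grade <- c(rep("DCIS_high", n_high_grade),
               rep(lower, length.out = n_lower_risk),
               rep("IDC", n_idc))
    call <- c(draw(n_high_grade, sensitivity),
              draw(n_lower_risk, 1 - specificity),  # Y w.p. 1 - specificity
              if (n_idc > 0) draw(n_idc, idc_positive_rate))
    tab <- data.frame(roi_id = seq_along(grade), grade = grade, call = call,
                      stringsAsFactors = FALSE)
    list(table = tab,
         truth = list(sensitivity = sensitivity, specificity = specificity,
                      equivocal_rate = equivocal_rate))
  })
}
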