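# Cortical stiffness from nanoindentation (Hertz spherical contact model)
# and cell volume from confocal z-stacks.

#' Nanoindentation force curve
#'
#' Exactly one of `deflection_um` / `force_nN` must be supplied (instruments
#' export either cantilever deflection or calibrated force).
#'
#' @param indenter_position_um probe positions along the approach, um,
#'   monotone increasing.
#' @param deflection_um cantilever deflection, um (optional).
#' @param force_nN force, nN (optional).
#' @param spring_constant_N_per_m cantilever spring constant, N/m (> 0).
#' @param tip_radius_um spherical tip radius, um (> 0).
#' @return A `force_curve` object.
#' @export
force_curve <- function(indenter_position_um, deflection_um = NULL,
                        force_nN = NULL, spring_constant_N_per_m,
                        tip_radius_um) {
  n <- length(indenter_position_um)
  if (n < 50) stop("a force curve needs at least 50 samples")
  if (any(diff(indenter_position_um) <= 0)) {
    stop("indenter positions must be monotone increasing")
  }
  if (is.null(deflection_um) == is.null(force_nN)) {
    stop("supply exactly one of deflection_um or force_nN")
  }
  if (spring_constant_N_per_m <= 0 || tip_radius_um <= 0) {
    stop("spring constant and tip radius must be positive")
  }
  structure(list(indenter_position_um = as.numeric(indenter_position_um),
                 deflection_um = deflection_um, force_nN = force_nN,
                 spring_constant_N_per_m = spring_constant_N_per_m,
                 tip_radius_um = tip_radius_um),
            class = "force_curve")
}

#' Convert cantilever deflection to force
#'
#' Hooke's law: `F[nN] = k[N/m] * d[um] * 1000` (1 N/m * 1 um = 1000 nN).
#' The deflection is kept on the curve so the indentation depth can be
#' corrected for cantilever bending downstream.
#'
#' @param curve a [force_curve] carrying `deflection_um`.
#' @return The curve with `force_nN` filled in.
#' @export
force_from_deflection <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(curve$deflection_um)) stop("curve has no deflection data")
  if (!is.null(curve$force_nN)) stop("curve already has force data")
  curve$force_nN <- curve$spring_constant_N_per_m * 1000 * curve$deflection_um
  curve
}

#' Fit the Hertz spherical contact model
#'
#' Fits `F(delta) = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` jointly over
#' Young's modulus `E`, the contact point and a constant force offset, by
#' nonlinear least squares on the approach segment. When the curve carries
#' deflection data the indentation depth is corrected for cantilever
#' bending, `delta = (z - z0) - (F - F_offset) / k`. After an initial fit
#' the data are restricted to `delta <= max_indent_um` (the elastic regime)
#' and the fit is repeated.
#'
#' @param curve a [force_curve].
#' @param poisson Poisson ratio (default 0.5, incompressible).
#' @param max_indent_um indentation depth used for the final fit, um.
#' @return A `hertz_fit` list: `E_kPa`, `contact_point_um`, `poisson`,
#'   `force_offset_nN`, `fit_rmse_nN`, `indent_range_used_um`.
#' @export
fit_hertz <- function(curve, poisson = 0.5, max_indent_um = 0.5) {
  stopifnot(inherits(curve, "force_curve"), max_indent_um > 0)
  if (is.null(curve$force_nN)) curve <- force_from_deflection(curve)
  z <- curve$indenter_position_um
  f <- curve$force_nN
  k_nN_um <- curve$spring_constant_N_per_m * 1000
  correct_bending <- !is.null(curve$deflection_um)
  pref <- (4 / 3) / (1 - poisson^2) * sqrt(curve$tip_radius_um)
  model_force <- function(E, z0, f0) {
    delta <- z - z0
    if (correct_bending) delta <- delta - (f - f0) / k_nN_um
    f0 + pref * E * pmax(delta, 0)^1.5
  }
  # initial guesses: offset from the low-force tail, contact where force
  # first exceeds the tail level by 3 sd, E from the endpoint force
  n <- length(z)
  tail_n <- max(10, floor(n * 0.2))
  f0_init <- mean(f[seq_len(tail_n)])
  f_sd <- stats::sd(f[seq_len(tail_n)])
  above <- which(f > f0_init + 3 * f_sd + 1e-12)
  if (length(above) == 0 || max(f) - f0_init <= max(1e-9, 5 * f_sd)) {
    stop("no contact detected in force curve")
  }
  z0_init <- z[above[1]]
  d_end <- max(z[n] - z0_init, 1e-3)
  E_init <- max((f[n] - f0_init) / (pref * d_end^1.5), 1e-3)
  hertz_pred <- function(zi, fi, E, z0, f0) {
    delta <- zi - z0
    if (correct_bending) delta <- delta - (fi - f0) / k_nN_um
    f0 + pref * E * pmax(delta, 0)^1.5
  }
  do_fit <- function(idx) {
    df <- data.frame(fi = f[idx], zi = z[idx])
    minpack.lm::nlsLM(
      fi ~ hertz_pred(zi, fi, E, z0, f0),
      data = df,
      start = list(E = E_init, z0 = z0_init, f0 = f0_init),
      lower = c(E = 1e-6, z0 = min(z), f0 = -Inf),
      upper = c(E = Inf, z0 = max(z), f0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  fit1 <- do_fit(seq_len(n))
  p <- coef(fit1)
  # restrict to the elastic regime delta <= max_indent_um and refit
  delta1 <- z - p[["z0"]]
  if (correct_bending) delta1 <- delta1 - (f - p[["f0"]]) / k_nN_um
  idx <- which(delta1 <= max_indent_um)
  if (sum(delta1[idx] > 0) < 5) {
    stop("no post-contact data within the elastic regime")
  }
  fit2 <- tryCatch(do_fit(idx), error = function(e) fit1)
  p <- coef(fit2)
  resid <- f[idx] - model_force(p[["E"]], p[["z0"]], p[["f0"]])[idx]
  if (p[["z0"]] < min(z) || p[["z0"]] > max(z)) {
    stop("fitted contact point outside the curve span")
  }
  structure(list(E_kPa = p[["E"]], contact_point_um = p[["z0"]],
                 poisson = poisson, force_offset_nN = p[["f0"]],
                 fit_rmse_nN = sqrt(mean(resid^2)),
                 indent_range_used_um = max_indent_um),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g kPa, contact at %.4g um (rmse %.3g nN)\n",
              x$E_kPa, x$contact_point_um, x$fit_rmse_nN))
  invisible(x)
}

#' Cell volume from a confocal z-stack
#'
#' Thresholds the stack globally (Otsu on the range-normalized 3D intensity
#' histogram, hence invariant to intensity rescaling), keeps the largest
#' 3D-connected component at least `min_object_voxels` large, and reports
#' voxel count times voxel volume.
#'
#' @param stack a [z_stack].
#' @param min_object_voxels smallest component accepted.
#' @return A `volume_result` list: `volume_um3`, `n_voxels`,
#'   `threshold_used` (normalized scale).
#' @export
cell_volume <- function(stack, min_object_voxels = 50) {
  stopifnot(inherits(stack, "z_stack"))
  v <- stack$voxels
  if (diff(range(v)) == 0) stop("no cell found: constant stack")
  nrm <- (v - min(v)) / (max(v) - min(v))
  thr <- EBImage::otsu(EBImage::Image(matrix(nrm, nrow = dim(v)[1])),
                       range = c(0, 1), levels = 256L)
  fg <- nrm > thr
  if (!any(fg)) stop("no cell found: no voxel above threshold")
  lab <- label_components_3d(fg)
  sizes <- tabulate(lab[lab > 0])
  sizes[sizes < min_object_voxels] <- 0
  if (all(sizes == 0)) stop("no cell found: all components below min size")
  n_vox <- max(sizes)
  structure(list(
    volume_um3 = n_vox * stack$pixel_size_um^2 * stack$z_step_um,
    n_voxels = n_vox, threshold_used = thr
  ), class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %.4g um3 (%d voxels)\n",
              x$volume_um3, x$n_voxels))
  invisible(x)
}

# 3D connected components (6-connectivity): label each z-plane in 2D, then
# merge labels of overlapping components in adjacent planes via union-find.
# No installed package offers 3D labeling, so this small primitive is local.
label_components_3d <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[3])) {
    lk <- EBImage::bwlabel(fg[, , k])
    lk <- matrix(as.integer(lk), d[1], d[2])
    nk <- max(lk, 0L)
    pos <- lk > 0L
    lk[pos] <- lk[pos] + offset
    lab[, , k] <- lk
    offset <- offset + nk
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(d[3] - 1)) {
    a <- lab[, , k]
    b <- lab[, , k + 1]
    both <- a > 0L & b > 0L
    if (any(both)) {
      pairs <- unique(cbind(a[both], b[both]))
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relabel <- match(roots, unique(roots))
  pos <- lab > 0L
  lab[pos] <- relabel[lab[pos]]
  lab
}
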