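# Single-cell motility: link per-frame detections into trajectories, compute
# time-averaged mean squared displacement (MSD), and fit the 2D
# diffusion-with-drift decomposition msd(tau) = 4 D tau + (v tau)^2.

#' Single-cell trajectory
#'
#' @param cell_id identifier.
#' @param time_min frame times, min (uniform, increasing).
#' @param x_um,y_um positions, um.
#' @param gaps number of interpolated (missed-detection) frames.
#' @return A `trajectory` object.
#' @export
trajectory <- function(cell_id, time_min, x_um, y_um, gaps = 0L) {
  n <- length(time_min)
  if (length(x_um) != n || length(y_um) != n) stop("unequal lengths")
  dt <- diff(time_min)
  if (n > 1 && (any(dt <= 0) || diff(range(dt)) > 1e-8 * max(dt))) {
    stop("times must be uniformly spaced and increasing")
  }
  structure(list(cell_id = cell_id, time_min = as.numeric(time_min),
                 x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 gaps = as.integer(gaps)),
            class = "trajectory")
}

#' Link per-frame detections into trajectories
#'
#' Greedy shortest-link-first frame-to-frame assignment: candidate links are
#' sorted by distance and accepted while each detection and each open track
#' is used at most once per frame. Links longer than `max_disp_um` (per
#' frame of elapsed time) are forbidden. Tracks tolerate up to
#' `max_gap_frames` missed detections; skipped positions are filled by
#' linear interpolation and counted in `gaps`. Unlinked detections start new
#' tracks. Frames are consumed strictly in time order.
#'
#' @param detections list of per-frame matrices/data frames with columns
#'   `x`, `y` (um); one element per frame, in time order.
#' @param dt_min frame interval, min.
#' @param max_disp_um maximum link length per frame of gap, um.
#' @param max_gap_frames tolerated missed detections.
#' @return List of [trajectory] objects (longest first).
#' @export
link_trajectories <- function(detections, dt_min = 1, max_disp_um = 15,
                              max_gap_frames = 1) {
  if (length(detections) < 2) stop("need at least 2 frames")
  detections <- lapply(detections, function(d) {
    d <- as.matrix(as.data.frame(d)[, 1:2])
    colnames(d) <- c("x", "y")
    d
  })
  # open tracks: list of (rows = frame index + position, last frame seen)
  tracks <- list()
  open <- integer(0)   # indices into tracks still eligible for linking
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    nd <- nrow(det)
    # drop tracks whose gap allowance is exhausted
    if (length(open)) {
      last <- vapply(tracks[open], function(tr) tr$last_frame, numeric(1))
      open <- open[f - last <= max_gap_frames + 1]
    }
    assigned_det <- logical(nd)
    if (length(open) && nd > 0) {
      lastpos <- t(vapply(tracks[open], function(tr) tr$last_pos, numeric(2)))
      last <- vapply(tracks[open], function(tr) tr$last_frame, numeric(1))
      d2 <- outer(lastpos[, 1], det[, 1], "-")^2 +
        outer(lastpos[, 2], det[, 2], "-")^2
      lim <- (max_disp_um * (f - last))^2  # per-row allowance grows with gap
      cand <- which(d2 <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d2[cand], cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        used_tr <- logical(length(open))
        for (i in seq_len(nrow(cand))) {
          a <- cand[i, 1]; b <- cand[i, 2]
          if (!used_tr[a] && !assigned_det[b]) {
            used_tr[a] <- TRUE
            assigned_det[b] <- TRUE
            ti <- open[a]
            tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
            tracks[[ti]]$xs <- c(tracks[[ti]]$xs, det[b, 1])
            tracks[[ti]]$ys <- c(tracks[[ti]]$ys, det[b, 2])
            tracks[[ti]]$last_frame <- f
            tracks[[ti]]$last_pos <- det[b, ]
          }
        }
      }
    }
    for (b in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(
        frames = f, xs = det[b, 1], ys = det[b, 2],
        last_frame = f, last_pos = det[b, ]
      )
      open <- c(open, length(tracks))
    }
  }
  out <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    full <- tr$frames[1]:tr$last_frame
    gaps <- length(full) - length(tr$frames)
    xs <- stats::approx(tr$frames, tr$xs, xout = full)$y
    ys <- stats::approx(tr$frames, tr$ys, xout = full)$y
    trajectory(i, (full - 1) * dt_min, xs, ys, gaps)
  })
  out[order(-vapply(out, function(tr) length(tr$time_min), numeric(1)))]
}

#' Time-averaged mean squared displacement
#'
#' MSD at lag `tau = k dt` is the mean over all ordered frame pairs
#' `(i, i + k)` of the squared displacement, computed for lags up to
#' `max_lag_fraction` of the track length.
#'
#' @param traj a [trajectory] with >= 10 points.
#' @param max_lag_fraction largest lag as a fraction of track length.
#' @return An `msd_curve` data frame: `lag_min`, `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$time_min)
  if (n < 10) stop("trajectory too short for MSD (need >= 10 points)")
  dt <- traj$time_min[2] - traj$time_min[1]
  max_lag <- max(4L, floor((n - 1) * max_lag_fraction))
  max_lag <- min(max_lag, n - 1)
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) {
    dx <- traj$x_um[(k + 1):n] - traj$x_um[1:(n - k)]
    dy <- traj$y_um[(k + 1):n] - traj$y_um[1:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  out <- data.frame(lag_min = lags * dt, msd_um2 = msd, n_pairs = n - lags)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit diffusivity and drift speed to an MSD curve
#'
#' Weighted least squares of `msd(tau) = 4 D tau + (v tau)^2` — linear in
#' `(D, v^2)` with basis `(4 tau, tau^2)` — using the pair counts as
#' weights. Negative estimates are clipped to zero (with the other
#' parameter refitted) and flagged.
#'
#' @param msd an `msd_curve` from [compute_msd] with >= 4 lags.
#' @return A `motility_result` list: `D_um2_min`, `v_um_min`, `fit_r2`,
#'   `n_lags_used`, `clipped`.
#' @export
fit_motility <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  if (nrow(msd) < 4) stop("need at least 4 usable lags")
  tau <- msd$lag_min
  if (diff(range(tau)) == 0) stop("degenerate design: all lags equal")
  y <- msd$msd_um2
  w <- msd$n_pairs
  X <- cbind(4 * tau, tau^2)
  beta <- coef(stats::lm(y ~ X - 1, weights = w))
  clipped <- FALSE
  if (beta[1] < 0) {  # pure drift: refit v^2 alone
    clipped <- TRUE
    beta <- c(0, max(0, coef(stats::lm(y ~ I(tau^2) - 1, weights = w))))
  } else if (beta[2] < 0) {  # pure diffusion: refit D alone
    clipped <- TRUE
    beta <- c(coef(stats::lm(y ~ I(4 * tau) - 1, weights = w)), 0)
    beta[1] <- max(0, beta[1])
  }
  pred <- X %*% beta
  ss_res <- sum(w * (y - pred)^2)
  ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  structure(list(D_um2_min = beta[[1]], v_um_min = sqrt(beta[[2]]),
                 fit_r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_lags_used = nrow(msd), clipped = clipped),
            class = "motility_result")
}

#' @export
print.motility_result <- function(x, ...) {
  cat(sprintf("<motility_result> D = %.4g um2/min, v = %.4g um/min (R2 %.3f)\n",
              x$D_um2_min, x$v_um_min, x$fit_r2))
  invisible(x)
}

#' Per-trajectory motility summary
#'
#' MSD fit (`D`, `v`) plus the net-displacement speed
#' `v_net = |r(T) - r(0)| / T` as a model-free comparison value.
#'
#' @param traj a [trajectory].
#' @param max_lag_fraction see [compute_msd].
#' @return list: `cell_id`, `D_um2_min`, `v_um_min`, `v_net_um_min`,
#'   `fit_r2`, `n_points`.
#' @export
analyze_motility <- function(traj, max_lag_fraction = 0.25) {
  fit <- fit_motility(compute_msd(traj, max_lag_fraction))
  n <- length(traj$time_min)
  total_t <- traj$time_min[n] - traj$time_min[1]
  vnet <- sqrt((traj$x_um[n] - traj$x_um[1])^2 +
                 (traj$y_um[n] - traj$y_um[1])^2) / total_t
  list(cell_id = traj$cell_id, D_um2_min = fit$D_um2_min,
       v_um_min = fit$v_um_min, v_net_um_min = vnet, fit_r2 = fit$fit_r2,
       n_points = n)
}
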