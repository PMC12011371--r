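# Line analysis: partition a protein channel into plasma-membrane, cytosol
# and nucleus compartments along a line crossing one cell, using the
# membrane-dye (DiI) half-maximum double peak and the nuclear-dye (DAPI)
# half-maximum plateau as compartment guides.

#' Three-channel line profile across one cell
#'
#' @param position_um positions along the line, um, strictly increasing.
#' @param target channel-of-interest intensities.
#' @param membrane_dye membrane-dye (DiI) intensities.
#' @param nuclear_dye nuclear-dye (DAPI) intensities.
#' @return A `line_profile` object.
#' @export
line_profile <- function(position_um, target, membrane_dye, nuclear_dye) {
  n <- length(position_um)
  if (n < 20) stop("a line profile needs at least 20 samples")
  if (length(target) != n || length(membrane_dye) != n ||
      length(nuclear_dye) != n) stop("channels must have equal length")
  if (any(diff(position_um) <= 0)) stop("positions must be strictly increasing")
  vals <- c(target, membrane_dye, nuclear_dye)
  if (!all(is.finite(vals))) stop("intensities must be finite")
  structure(list(position_um = as.numeric(position_um),
                 target = as.numeric(target),
                 membrane_dye = as.numeric(membrane_dye),
                 nuclear_dye = as.numeric(nuclear_dye)),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.3g um\n",
              length(x$position_um), diff(range(x$position_um))))
  invisible(x)
}

#' Subtract line-end background from every channel
#'
#' Estimates each channel's background as the mean of the outer
#' `edge_fraction` of samples at both ends of the line (assumed to lie
#' outside the cell), subtracts it and clips negatives to zero.
#'
#' @param profile a [line_profile].
#' @param edge_fraction fraction of samples per end used for the estimate,
#'   in `(0, 0.3]`.
#' @return A background-subtracted [line_profile].
#' @export
subtract_background <- function(profile, edge_fraction = 0.1) {
  stopifnot(inherits(profile, "line_profile"))
  if (edge_fraction <= 0 || edge_fraction > 0.3) {
    stop("edge_fraction must be in (0, 0.3]")
  }
  n <- length(profile$position_um)
  k <- floor(n * edge_fraction)
  if (k < 1) stop("line too short for an edge background estimate")
  idx <- c(seq_len(k), (n - k + 1):n)
  for (ch in c("target", "membrane_dye", "nuclear_dye")) {
    profile[[ch]] <- pmax(profile[[ch]] - mean(profile[[ch]][idx]), 0)
  }
  profile
}

#' Locate compartment windows from the dye channels
#'
#' The two dominant membrane-dye peaks (found on a lightly smoothed trace,
#' ties broken toward the outermost candidates) define the two
#' plasma-membrane windows as full-width-at-half-maximum intervals; the
#' nuclear-dye half-maximum interval defines the nucleus window; the two
#' gaps between them are the cytosol windows.
#'
#' @param profile a [line_profile] (background-subtracted).
#' @param smooth_samples moving-average width for peak finding (odd).
#' @param min_peak_sep_frac minimum separation between the two membrane
#'   peaks, as a fraction of the line length.
#' @return A `compartment_windows` list with integer index vectors
#'   `pm_windows` (two), `nucleus_window`, `cytosol_windows` (two).
#' @export
find_windows <- function(profile, smooth_samples = 5,
                         min_peak_sep_frac = 0.1) {
  stopifnot(inherits(profile, "line_profile"))
  n <- length(profile$position_um)
  mem <- moving_average(profile$membrane_dye, smooth_samples)
  peaks <- local_peaks(mem)
  min_sep <- max(2, floor(min_peak_sep_frac * n))
  pk <- pick_two_peaks(peaks, mem, min_sep, n)
  if (length(pk) < 2) stop("two membrane-dye peaks required")
  pk <- sort(pk)
  # FWHM windows on the raw (unsmoothed) channels, one per peak
  pm1 <- contiguous_above(profile$membrane_dye, pk[1],
                          profile$membrane_dye[pk[1]] / 2)
  pm2 <- contiguous_above(profile$membrane_dye, pk[2],
                          profile$membrane_dye[pk[2]] / 2)
  if (max(pm1) >= min(pm2)) stop("membrane-dye windows overlap")
  nuc_peak <- which.max(profile$nuclear_dye)
  if (nuc_peak <= max(pm1) || nuc_peak >= min(pm2)) {
    stop("nuclear-dye peak must lie between the membrane-dye peaks")
  }
  nw <- contiguous_above(profile$nuclear_dye, nuc_peak,
                         profile$nuclear_dye[nuc_peak] / 2)
  if (min(nw) <= max(pm1) || max(nw) >= min(pm2)) {
    stop("nucleus window overlaps a membrane window")
  }
  cy1 <- (max(pm1) + 1):(min(nw) - 1)
  cy2 <- (max(nw) + 1):(min(pm2) - 1)
  if (length(cy1) == 0 || length(cy2) == 0) stop("empty cytosol window")
  structure(list(pm_windows = list(pm1, pm2), nucleus_window = nw,
                 cytosol_windows = list(cy1, cy2)),
            class = "compartment_windows")
}

moving_average <- function(y, w) {
  if (w <= 1) return(y)
  if (w %% 2 == 0) w <- w + 1
  sm <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  sm
}

local_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Two highest local maxima separated by at least min_sep; ties broken toward
# the outermost candidates (a line crossing a cell meets the membrane at its
# two extremes).
pick_two_peaks <- function(peaks, y, min_sep, n) {
  if (length(peaks) < 2) return(peaks)
  mid <- (n + 1) / 2
  ord <- order(-y[peaks], -abs(peaks - mid))
  peaks <- peaks[ord]
  first <- peaks[1]
  rest <- peaks[abs(peaks - first) >= min_sep]
  if (length(rest) == 0) return(first)
  c(first, rest[1])
}

#' Compartment percentages of the target channel
#'
#' Pools the samples of the two plasma-membrane windows and of the two
#' cytosol windows, averages the target channel per compartment, and reports
#' each mean as a percentage of the sum of the three means, following the
#' intensity-partitioning definition of line analysis.
#'
#' @param profile a [line_profile] (background-subtracted).
#' @param windows a `compartment_windows` from [find_windows].
#' @return A `localization_result` list: `pm_pct`, `cyto_pct`, `nuc_pct`
#'   (summing to 100).
#' @export
compartment_fractions <- function(profile, windows) {
  stopifnot(inherits(profile, "line_profile"),
            inherits(windows, "compartment_windows"))
  n <- length(profile$target)
  idx_all <- c(unlist(windows$pm_windows), windows$nucleus_window,
               unlist(windows$cytosol_windows))
  if (any(idx_all < 1 | idx_all > n)) stop("windows outside profile")
  m_pm <- mean(profile$target[unlist(windows$pm_windows)])
  m_cy <- mean(profile$target[unlist(windows$cytosol_windows)])
  m_nu <- mean(profile$target[windows$nucleus_window])
  s <- m_pm + m_cy + m_nu
  if (s <= 0) stop("all compartment means are zero: fractions undefined")
  structure(list(pm_pct = 100 * m_pm / s, cyto_pct = 100 * m_cy / s,
                 nuc_pct = 100 * m_nu / s),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result> PM %.1f%% / cytosol %.1f%% / nucleus %.1f%%\n",
              x$pm_pct, x$cyto_pct, x$nuc_pct))
  invisible(x)
}

#' One-call line analysis
#'
#' Background subtraction, window finding and compartment partitioning in
#' sequence, with the package defaults.
#'
#' @param profile a [line_profile].
#' @param edge_fraction see [subtract_background].
#' @param smooth_samples,min_peak_sep_frac see [find_windows].
#' @return A `localization_result`.
#' @export
analyze_line_profile <- function(profile, edge_fraction = 0.1,
                                 smooth_samples = 5, min_peak_sep_frac = 0.1) {
  bg <- subtract_background(profile, edge_fraction)
  compartment_fractions(bg, find_windows(bg, smooth_samples,
                                         min_peak_sep_frac))
}
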