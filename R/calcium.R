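# Fluo-4 calcium trace analysis: ROI trace extraction from a time lapse,
# baseline and treatment-locked transient amplitude (delta-Ca) extraction,
# and group comparison of time-averaged intensities.

#' Calcium intensity trace
#'
#' @param time_min frame times in minutes, uniformly spaced, increasing.
#' @param intensity background-subtracted mean ROI intensity per frame.
#' @param treatment_time time the treatment was added (min), or `NULL`.
#' @return A `calcium_trace` object.
#' @export
calcium_trace <- function(time_min, intensity, treatment_time = NULL) {
  n <- length(time_min)
  if (n < 10) stop("a calcium trace needs at least 10 frames")
  if (length(intensity) != n) stop("time and intensity lengths differ")
  dt <- diff(time_min)
  if (any(dt <= 0) || diff(range(dt)) > 1e-8 * max(dt)) {
    stop("frame times must be uniformly spaced and increasing")
  }
  structure(list(time_min = as.numeric(time_min),
                 intensity = as.numeric(intensity),
                 treatment_time = treatment_time),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d frames, %.3g-%.3g min%s\n",
              length(x$time_min), min(x$time_min), max(x$time_min),
              if (is.null(x$treatment_time)) ""
              else sprintf(", treatment at %.3g min", x$treatment_time)))
  invisible(x)
}

#' Extract a background-subtracted ROI trace from a time lapse
#'
#' Per frame, the mean intensity over `roi` minus the mean over
#' `background_roi` (when given). `roi = NULL` uses the whole field.
#'
#' @param movie a [time_lapse].
#' @param roi logical matrix (same shape as a frame) or `NULL` for the whole
#'   field.
#' @param background_roi logical matrix of background pixels, or `NULL` for
#'   no background subtraction.
#' @param treatment_time treatment time (in the movie's time unit,
#'   converted to minutes if the unit is seconds).
#' @return A [calcium_trace].
#' @export
extract_trace <- function(movie, roi = NULL, background_roi = NULL,
                          treatment_time = NULL) {
  stopifnot(inherits(movie, "time_lapse"))
  shp <- dim(movie$frames[[1]]$pixels)
  if (is.null(roi)) roi <- matrix(TRUE, shp[1], shp[2])
  if (!any(roi)) stop("empty roi")
  if (!is.null(background_roi)) {
    if (!any(background_roi)) stop("empty background_roi")
    if (any(roi & background_roi)) stop("roi overlaps background_roi")
  }
  vals <- vapply(movie$frames, function(f) {
    v <- mean(f$pixels[roi])
    if (!is.null(background_roi)) v <- v - mean(f$pixels[background_roi])
    v
  }, numeric(1))
  step <- movie$frame_interval * if (movie$time_unit == "s") 1 / 60 else 1
  tt <- if (!is.null(treatment_time) && movie$time_unit == "s") {
    treatment_time / 60
  } else treatment_time
  calcium_trace((seq_along(vals) - 1) * step, vals, tt)
}

#' Baseline and treatment-locked transient amplitude (delta-Ca)
#'
#' The baseline is the mean of all pre-treatment frames; the extremum is the
#' minimum (dip), maximum (spike), or whichever deviates more from baseline
#' (`auto`) within `response_window_min` after treatment, on an optionally
#' smoothed trace (`smooth_frames = 1` means the raw single-frame extremum).
#' `delta_ca = extremum - baseline`, signed.
#'
#' @param trace a [calcium_trace] with `treatment_time` set.
#' @param response_window_min extremum search window after treatment, min.
#' @param direction `"dip"`, `"spike"` or `"auto"`.
#' @param smooth_frames odd moving-average width applied before the extremum
#'   search (1 = none).
#' @param detrend subtract a linear photobleaching trend fitted to the
#'   pre-treatment frames before analysis.
#' @return A `delta_ca_result` list: `baseline`, `extremum`, `delta_ca`,
#'   `extremum_time`.
#' @export
delta_ca <- function(trace, response_window_min = 5,
                     direction = c("auto", "dip", "spike"),
                     smooth_frames = 1, detrend = FALSE) {
  stopifnot(inherits(trace, "calcium_trace"))
  direction <- match.arg(direction)
  if (is.null(trace$treatment_time)) stop("treatment_time is not set")
  tm <- trace$time_min
  y <- trace$intensity
  pre <- tm < trace$treatment_time
  if (sum(pre) < 3) stop("need at least 3 pre-treatment frames")
  if (detrend) {
    fit <- lm(y[pre] ~ tm[pre])
    y <- y - (coef(fit)[1] + coef(fit)[2] * tm) + mean(y[pre])
  }
  baseline <- mean(y[pre])
  ys <- moving_average(y, smooth_frames)
  win <- which(!pre & tm <= trace$treatment_time + response_window_min)
  if (length(win) == 0) stop("no frames inside the response window")
  if (max(tm) < trace$treatment_time + response_window_min) {
    warning("response window extends past the trace end; truncated")
  }
  i_min <- win[which.min(ys[win])]
  i_max <- win[which.max(ys[win])]
  i_ext <- switch(direction,
    dip = i_min,
    spike = i_max,
    auto = if (abs(ys[i_min] - baseline) >= abs(ys[i_max] - baseline)) {
      i_min
    } else i_max
  )
  structure(list(baseline = baseline, extremum = ys[i_ext],
                 delta_ca = ys[i_ext] - baseline,
                 extremum_time = tm[i_ext]),
            class = "delta_ca_result")
}

#' @export
print.delta_ca_result <- function(x, ...) {
  cat(sprintf("<delta_ca_result> baseline %.4g, delta_ca %+.4g at %.3g min\n",
              x$baseline, x$delta_ca, x$extremum_time))
  invisible(x)
}

#' Compare time-averaged trace intensities between two groups
#'
#' Computes the per-trace mean intensity over the full duration and tests the
#' two groups with a two-sided Mann-Whitney U test.
#'
#' @param traces_a,traces_b lists of [calcium_trace] objects (>= 3 each).
#' @return list with `means_a`, `means_b`, `u`, `p_value`, `method`.
#' @export
compare_mean_levels <- function(traces_a, traces_b) {
  if (length(traces_a) < 3 || length(traces_b) < 3) {
    stop("each group needs at least 3 traces")
  }
  ma <- vapply(traces_a, function(tr) mean(tr$intensity), numeric(1))
  mb <- vapply(traces_b, function(tr) mean(tr$intensity), numeric(1))
  mw <- mann_whitney_u(ma, mb)
  list(means_a = ma, means_b = mb, u = mw$u, p_value = mw$p_value,
       method = mw$method)
}
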