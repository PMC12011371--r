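# Invasive-fraction quantification from paired gelatin-degradation and
# nuclear-stain images: threshold the gelatin field into a degradation mask,
# detect nuclei as intensity blobs, and count the nuclei lying on the mask.

#' Segment degraded (dark) gelatin regions
#'
#' Smooths the gelatin image, picks a threshold automatically by Otsu's
#' method on the range-normalized intensities (hence invariant to affine
#' intensity rescaling), and marks the dark class as degraded matrix.
#' Connected components smaller than `min_patch_area_px` are removed.
#'
#' When the two intensity classes are not separated by more than
#' `min_contrast` pooled within-class standard deviations the image is
#' treated as degradation-free (noise alone would otherwise be split in
#' half); a constant image yields an empty mask with a warning.
#'
#' @param gelatin a [fluorescence_image] of the gelatin channel.
#' @param min_patch_area_px minimum component area kept, px.
#' @param smoothing_sigma Gaussian pre-smoothing sigma, px.
#' @param min_contrast minimum between-class separation in pooled
#'   within-class sd units.
#' @return A `degradation_mask`: logical matrix (`TRUE` = degraded) with
#'   attributes `threshold` (on the normalized scale) and `method`.
#' @export
segment_degradation <- function(gelatin, min_patch_area_px = 25,
                                smoothing_sigma = 2, min_contrast = 4) {
  stopifnot(inherits(gelatin, "fluorescence_image"))
  px <- gelatin$pixels
  empty <- function(reason) {
    structure(matrix(FALSE, nrow(px), ncol(px)),
              threshold = NA_real_, method = reason,
              class = "degradation_mask")
  }
  if (diff(range(px)) == 0) {
    warning("constant image: returning empty degradation mask")
    return(empty("constant_image"))
  }
  sm <- as.matrix(EBImage::gblur(px, sigma = smoothing_sigma))
  nrm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(nrm), range = c(0, 1), levels = 256L)
  dark <- nrm <= thr
  if (!any(dark) || all(dark)) return(empty("degenerate_threshold"))
  m0 <- mean(nrm[dark]); m1 <- mean(nrm[!dark])
  s0 <- stats::sd(nrm[dark]); s1 <- stats::sd(nrm[!dark])
  pooled <- sqrt(((sum(dark) - 1) * s0^2 + (sum(!dark) - 1) * s1^2) /
                   (length(nrm) - 2))
  if (!is.finite(pooled) || pooled == 0 || (m1 - m0) / pooled < min_contrast) {
    return(empty("no_degradation_detected"))
  }
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_patch_area_px)
  mask <- matrix(lab %in% keep, nrow(px), ncol(px))
  structure(mask, threshold = thr, method = "otsu_dark_class",
            class = "degradation_mask")
}

#' Detect nuclei as intensity blobs
#'
#' Gaussian smoothing followed by local-maximum detection with an exclusion
#' radius: no two accepted points lie closer than `min_separation_px`.
#' Positions are refined to sub-pixel accuracy by an intensity-weighted
#' centroid in a 3x3 window. At low magnification nuclei are unresolved
#' points, so blob detection (not segmentation) is the right operation.
#'
#' @param dapi a [fluorescence_image] of the nuclear-stain channel.
#' @param min_separation_px exclusion radius between points.
#' @param detection_sigma Gaussian smoothing sigma, px.
#' @param rel_threshold minimum blob intensity as a fraction of the image
#'   maximum (after smoothing).
#' @return A `point_set`: data frame with sub-pixel `row`, `col` and a
#'   detection `score`.
#' @export
detect_nuclei <- function(dapi, min_separation_px = 5, detection_sigma = 2,
                          rel_threshold = 0.15) {
  stopifnot(inherits(dapi, "fluorescence_image"))
  px <- dapi$pixels
  empty <- data.frame(row = numeric(0), col = numeric(0), score = numeric(0))
  class(empty) <- c("point_set", "data.frame")
  if (max(px) <= 0 || diff(range(px)) == 0) return(empty)
  sm <- as.matrix(EBImage::gblur(px, sigma = detection_sigma))
  cand <- which(sm == local_max_filter(sm, ceiling(min_separation_px)) &
                  sm >= rel_threshold * max(sm), arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), ncol = 2)
  score <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0 ||
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >=
          min_separation_px^2) {
      kept <- rbind(kept, p)
      score <- c(score, sm[p[1], p[2]])
    }
  }
  refined <- t(apply(kept, 1, function(p) centroid3(sm, p[1], p[2])))
  out <- data.frame(row = refined[, 1], col = refined[, 2], score = score)
  class(out) <- c("point_set", "data.frame")
  out
}

# Maximum filter over a (2r+1)^2 neighbourhood via grayscale dilation.
local_max_filter <- function(mat, r) {
  kern <- matrix(1, 2 * r + 1, 2 * r + 1)
  as.matrix(EBImage::dilate(EBImage::Image(mat), kern))
}

centroid3 <- function(mat, r, c) {
  rows <- max(1, r - 1):min(nrow(mat), r + 1)
  cols <- max(1, c - 1):min(ncol(mat), c + 1)
  w <- mat[rows, cols, drop = FALSE]
  s <- sum(w)
  if (s <= 0) return(c(r, c))
  c(sum(rows * rowSums(w)) / s, sum(cols * colSums(w)) / s)
}

#' Invasive cell fraction from a mask and detected nuclei
#'
#' A cell counts as invaded when its rounded position falls on a `TRUE` mask
#' pixel (boundary pixels count as invaded). The fraction is monotone
#' non-decreasing under mask dilation.
#'
#' @param mask a `degradation_mask` from [segment_degradation].
#' @param points a `point_set` from [detect_nuclei] (same field).
#' @return An `invasion_result` list: `n_total`, `n_invaded`,
#'   `invasive_fraction`, `threshold_used`.
#' @export
invasive_fraction <- function(mask, points) {
  stopifnot(inherits(mask, "degradation_mask"))
  n_total <- nrow(points)
  if (n_total == 0) stop("no cells detected: invasive fraction undefined")
  ri <- pmin(pmax(round(points$row), 1), nrow(mask))
  ci <- pmin(pmax(round(points$col), 1), ncol(mask))
  n_invaded <- sum(mask[cbind(ri, ci)])
  structure(list(n_total = n_total, n_invaded = n_invaded,
                 invasive_fraction = n_invaded / n_total,
                 threshold_used = attr(mask, "threshold")),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("<invasion_result> %d / %d cells invaded (fraction %.3f)\n",
              x$n_invaded, x$n_total, x$invasive_fraction))
  invisible(x)
}

#' Fraction of dead cells from dual-stain point sets
#'
#' Matches each dead-marker point to at most one total-population point by
#' greedy nearest-neighbour assignment within `match_radius_px`, and returns
#' matched dead points / total points.
#'
#' @param dead_marker_points `point_set` from the death-marker channel.
#' @param all_cell_points `point_set` of the whole population
#'   (co-registered field).
#' @param match_radius_px maximum match distance, px.
#' @return Fraction of dead cells in `[0, 1]`.
#' @export
viability_fraction <- function(dead_marker_points, all_cell_points,
                               match_radius_px = 4) {
  if (nrow(all_cell_points) == 0) stop("empty total point set")
  nd <- nrow(dead_marker_points)
  if (nd == 0) return(0)
  d2 <- outer(dead_marker_points$row, all_cell_points$row, "-")^2 +
    outer(dead_marker_points$col, all_cell_points$col, "-")^2
  pairs <- which(d2 <= match_radius_px^2, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0)
  ord <- order(d2[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_dead <- logical(nd)
  used_tot <- logical(nrow(all_cell_points))
  matched <- 0
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!used_dead[a] && !used_tot[b]) {
      used_dead[a] <- TRUE
      used_tot[b] <- TRUE
      matched <- matched + 1
    }
  }
  matched / nrow(all_cell_points)
}
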