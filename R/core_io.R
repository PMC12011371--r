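# Calibrated containers and TIFF/CSV i/o shared by all assay modules.

#' Calibrated 2D fluorescence image
#'
#' @param pixels numeric matrix of non-negative intensities (arbitrary units),
#'   indexed `(row, col)`, row axis pointing down.
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @param channel optional channel label, e.g. `"Gelatin488"` or `"DAPI"`.
#' @return A `fluorescence_image` object.
#' @export
fluorescence_image <- function(pixels, pixel_size_um = 1, channel = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("intensities must be finite")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = as.character(channel)),
    class = "fluorescence_image"
  )
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("<fluorescence_image> %d x %d px, %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel))
  invisible(x)
}

#' Time-lapse stack of fluorescence images
#'
#' @param frames list of `fluorescence_image` objects (all the same shape),
#'   or a 3D array `(row, col, frame)`.
#' @param frame_interval time between consecutive frames.
#' @param time_unit `"min"` or `"s"`; recorded with the data.
#' @param pixel_size_um pixel size, used when `frames` is an array.
#' @return A `time_lapse` object.
#' @export
time_lapse <- function(frames, frame_interval, time_unit = c("min", "s"),
                       pixel_size_um = 1) {
  time_unit <- match.arg(time_unit)
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) {
      fluorescence_image(frames[, , k], pixel_size_um)
    })
  }
  if (length(frames) < 2) stop("a time lapse needs at least 2 frames")
  shp <- dim(frames[[1]]$pixels)
  same <- vapply(frames, function(f) identical(dim(f$pixels), shp), logical(1))
  if (!all(same)) stop("all frames must have the same shape")
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }
  structure(
    list(frames = frames, frame_interval = frame_interval,
         time_unit = time_unit),
    class = "time_lapse"
  )
}

#' @export
print.time_lapse <- function(x, ...) {
  cat(sprintf("<time_lapse> %d frames, interval %.4g %s\n",
              length(x$frames), x$frame_interval, x$time_unit))
  invisible(x)
}

#' Calibrated confocal z-stack
#'
#' @param voxels 3D numeric array `(row, col, z)`.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um axial step between planes in micrometres.
#' @return A `z_stack` object.
#' @export
z_stack <- function(voxels, pixel_size_um, z_step_um) {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "double"
  if (length(dim(voxels)) != 3 || dim(voxels)[3] < 3) {
    stop("a z-stack needs a 3D array with at least 3 planes")
  }
  if (!all(is.finite(voxels))) stop("intensities must be finite")
  if (pixel_size_um <= 0 || z_step_um <= 0) {
    stop("pixel_size_um and z_step_um must be positive")
  }
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um),
    class = "z_stack"
  )
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<z_stack> %d x %d x %d voxels, %.4g um/px, %.4g um z-step\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Read a single- or multi-page TIFF into a calibrated container
#'
#' Pages are read as grayscale float matrices. The returned container depends
#' on the calibration supplied: a 1-page file yields a [fluorescence_image];
#' a multi-page file yields a [time_lapse] when `frame_interval` is given, or
#' a [z_stack] when `z_step_um` is given.
#'
#' Stored intensities are 32-bit floats in `[0, 1]`; `intensity_scale` (as
#' returned by [write_image_stack]) restores the original relative scale.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um lateral pixel size in micrometres (> 0).
#' @param frame_interval frame spacing for time-lapse data.
#' @param time_unit time unit of `frame_interval`.
#' @param z_step_um axial step for z-stack data.
#' @param channel channel label attached to single images.
#' @param intensity_scale multiplicative intensity scale (power of two
#'   recorded at write time); default 1.
#' @return A `fluorescence_image`, `time_lapse` or `z_stack`.
#' @export
read_image_stack <- function(path, pixel_size_um = 1, frame_interval = NULL,
                             time_unit = "min", z_step_um = NULL,
                             channel = "", intensity_scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(frame_interval) && !is.null(z_step_um)) {
    stop("give either frame_interval or z_step_um, not both")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse grayscale-as-RGB
    as.matrix(p) * intensity_scale
  })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    stop("TIFF pages have mismatched shapes")
  }
  if (!is.null(z_step_um)) {
    vox <- array(unlist(pages), dim = c(shp, length(pages)))
    return(z_stack(vox, pixel_size_um, z_step_um))
  }
  if (!is.null(frame_interval)) {
    frames <- lapply(pages, fluorescence_image, pixel_size_um = pixel_size_um)
    return(time_lapse(frames, frame_interval, time_unit))
  }
  if (length(pages) > 1) {
    stop("multi-page TIFF: supply frame_interval (time lapse) or z_step_um (z-stack)")
  }
  fluorescence_image(pages[[1]], pixel_size_um, channel)
}

#' Write a container to a 32-bit float TIFF
#'
#' Intensities are divided by a power-of-two scale so they fit the `[0, 1]`
#' storage range exactly (binary-exact rescaling); the scale is returned so
#' the caller can pass it back to [read_image_stack] as `intensity_scale`.
#'
#' @param x a `fluorescence_image`, `time_lapse` or `z_stack`.
#' @param path output path.
#' @return Invisibly, the intensity scale (a power of two, >= 1).
#' @export
write_image_stack <- function(x, path) {
  pages <-
    if (inherits(x, "fluorescence_image")) list(x$pixels)
    else if (inherits(x, "time_lapse")) lapply(x$frames, function(f) f$pixels)
    else if (inherits(x, "z_stack")) {
      lapply(seq_len(dim(x$voxels)[3]), function(k) x$voxels[, , k])
    } else stop("unsupported container")
  mx <- max(1, vapply(pages, max, numeric(1)))
  scale <- 2^ceiling(log2(mx))
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L, compression = "none")
  invisible(scale)
}

#' Write a results table to CSV at full precision
#'
#' Numeric columns are serialized with 17 significant digits so re-reading
#' reproduces the values to double precision. An empty table produces a
#' header-only file.
#'
#' @param records a data frame with homogeneous column types.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
    }
  }
  tryCatch(
    write.csv(out, path, row.names = FALSE, quote = TRUE),
    error = function(e) stop("cannot write table to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a CSV results table
#'
#' @param path path to a CSV written by [write_table] (or compatible).
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

# Deterministic child seed for a named generator, so adding one generator
# never perturbs another's stream. Kept below 2^31 - 1.
child_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483629 + 1)
}
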