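#' Construct a scan image
#'
#' A `scan_image` holds one scanning-probe topograph (or constant-height
#' current map): a rectangular grid of Z values with physical axis
#' coordinates and free-form acquisition metadata. Row 1 of `z` corresponds
#' to the smallest Y coordinate and column 1 to the smallest X coordinate.
#'
#' @param z numeric matrix of Z values, `[row, col]` = `[y, x]`. Topographic
#'   Z is conventionally in picometres; constant-height maps carry current
#'   units instead.
#' @param x numeric vector of strictly increasing physical X positions
#'   (nanometres), one per column. Defaults to `0:(ncol(z) - 1)`.
#' @param y numeric vector of strictly increasing physical Y positions
#'   (nanometres), one per row. Defaults to `0:(nrow(z) - 1)`.
#' @param metadata named list of acquisition metadata (source file, scan
#'   mode, sample bias, tunnelling setpoint, electrode potential, ...).
#' @return An object of class `scan_image`.
#' @examples
#' img <- scan_image(matrix(rnorm(64), 8, 8))
#' dim(img)
#' @export
scan_image <- function(z, x = NULL, y = NULL, metadata = list()) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (is.null(x)) x <- as.double(seq_len(ncol(z)) - 1L)
  if (is.null(y)) y <- as.double(seq_len(nrow(z)) - 1L)
  img <- structure(
    list(z = z, x = as.double(x), y = as.double(y), metadata = metadata),
    class = "scan_image"
  )
  validate_scan_image(img)
  img
}

validate_scan_image <- function(img) {
  if (!is.matrix(img$z)) stop("z must be a matrix")
  if (length(img$x) != ncol(img$z))
    stop("length(x) [", length(img$x), "] != ncol(z) [", ncol(img$z), "]")
  if (length(img$y) != nrow(img$z))
    stop("length(y) [", length(img$y), "] != nrow(z) [", nrow(img$z), "]")
  if (length(img$x) > 1 && any(diff(img$x) <= 0))
    stop("x coordinates must be strictly increasing")
  if (length(img$y) > 1 && any(diff(img$y) <= 0))
    stop("y coordinates must be strictly increasing")
  if (any(!is.finite(img$z))) stop("all Z values must be finite")
  invisible(img)
}

#' @export
dim.scan_image <- function(x) dim(x$z)

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %d x %d pixels\n", nrow(x$z), ncol(x$z)))
  cat(sprintf("  X: [%g, %g] nm   Y: [%g, %g] nm\n",
              x$x[1], x$x[length(x$x)], x$y[1], x$y[length(x$y)]))
  cat(sprintf("  Z: [%g, %g]\n", min(x$z), max(x$z)))
  if (!is.null(x$metadata$file)) cat("  file:", x$metadata$file, "\n")
  invisible(x)
}

#' Display a scan image as a greyscale raster
#'
#' @param x a [scan_image()].
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.scan_image <- function(x, ...) {
  graphics::image(x$x, x$y, t(x$z), col = grDevices::grey.colors(256, 0, 1),
                  xlab = "X (nm)", ylab = "Y (nm)", useRaster = TRUE,
                  asp = 1, ...)
  invisible(x)
}

#' Construct an image series
#'
#' An ordered sequence of [scan_image()] frames from one experiment. All
#' frames must share the same grid dimensions; indices record acquisition
#' order (the "image number" axis of per-series plots).
#'
#' @param frames list of `scan_image` objects.
#' @param indices integer acquisition indices, strictly increasing, one per
#'   frame. Defaults to `0, 1, 2, ...`.
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, indices = NULL) {
  if (length(frames) == 0) stop("an image_series needs at least one frame")
  lapply(frames, validate_scan_image)
  if (is.null(indices)) indices <- seq_along(frames) - 1L
  indices <- as.integer(indices)
  if (length(indices) != length(frames))
    stop("one index per frame required")
  if (length(indices) > 1 && any(diff(indices) <= 0))
    stop("indices must be strictly increasing")
  d <- dim(frames[[1]]$z)
  same <- vapply(frames, function(f) identical(dim(f$z), d), logical(1))
  if (!all(same))
    stop("all frames must share identical grid dimensions; frame ",
         which(!same)[1], " differs")
  structure(list(frames = frames, indices = indices), class = "image_series")
}

#' @export
length.image_series <- function(x) length(x$frames)

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]]$z)
  cat(sprintf("<image_series> %d frames of %d x %d pixels (indices %d..%d)\n",
              length(x$frames), d[1], d[2],
              x$indices[1], x$indices[length(x$indices)]))
  invisible(x)
}

#' @export
`[.image_series` <- function(x, i) {
  image_series(x$frames[i], x$indices[i])
}

series_file_names <- function(series) {
  vapply(series$frames, function(f) {
    fn <- f$metadata$file
    if (is.null(fn)) NA_character_ else as.character(fn)
  }, character(1))
}
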