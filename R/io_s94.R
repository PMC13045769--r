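#' Read a raw binary scan file (s94 dialect)
#'
#' Decodes the minimal little-endian raw-scan container this toolkit
#' defines for `.s94`-style instrument files (see Details) and returns the
#' physical-unit image. Vendor files using other layouts are not supported.
#'
#' @details
#' Layout (little-endian): magic `"S94F"` (4 bytes), version `uint16 = 1`,
#' cols `uint16`, rows `uint16`, x scan size `float64` (nm), y scan size
#' `float64` (nm), z scale `float64` (physical units per count), then
#' `rows * cols` `int16` samples, row-major with X fastest. Z values are
#' `z_scale * count`; pixel pitch is scan size divided by the pixel count.
#'
#' @param path path to the binary file.
#' @return A [scan_image()].
#' @seealso [write_s94()] for the matching writer.
#' @export
read_s94 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "S94F"))
    stop("unsupported format: bad magic '", magic, "' (expected 'S94F')")
  hdr <- readBin(con, integer(), n = 3L, size = 2L, signed = FALSE,
                 endian = "little")
  if (length(hdr) < 3) stop("truncated header in ", path)
  version <- hdr[1]
  if (version != 1L)
    stop("unsupported format version ", version, " (expected 1)")
  cols <- hdr[2]
  rows <- hdr[3]
  sizes <- readBin(con, numeric(), n = 3L, size = 8L, endian = "little")
  if (length(sizes) < 3) stop("truncated header in ", path)
  x_size <- sizes[1]
  y_size <- sizes[2]
  z_scale <- sizes[3]
  n <- rows * cols
  samples <- readBin(con, integer(), n = n, size = 2L, signed = TRUE,
                     endian = "little")
  if (length(samples) < n) {
    expect <- 34L + 2L * n
    stop(sprintf(
      "truncated data block in %s: expected %d bytes, got %d",
      path, expect, file.size(path)))
  }
  z <- matrix(z_scale * samples, nrow = rows, ncol = cols, byrow = TRUE)
  scan_image(z,
             x = (seq_len(cols) - 1) * x_size / cols,
             y = (seq_len(rows) - 1) * y_size / rows,
             metadata = list(file = basename(path), z_scale = z_scale,
                             x_size_nm = x_size, y_size_nm = y_size))
}

#' Write a raw binary scan file (s94 dialect)
#'
#' Encodes a [scan_image()] in the toolkit's s94 dialect (see
#' [read_s94()]). Z values are stored as `int16` counts of `z_scale`
#' physical units; the default scale is chosen so the full Z range fits the
#' integer range.
#'
#' @param img a [scan_image()] with uniformly spaced axes.
#' @param path output path.
#' @param z_scale physical units per stored count; default
#'   `max(abs(Z)) / 32000` (1 for an all-zero image).
#' @return `path`, invisibly.
#' @export
write_s94 <- function(img, path, z_scale = NULL) {
  validate_scan_image(img)
  check_uniform_axes(img)
  if (is.null(z_scale)) {
    z_scale <- max(abs(img$z)) / 32000
    if (z_scale == 0) z_scale <- 1
  }
  counts <- round(as.vector(t(img$z)) / z_scale)
  if (any(abs(counts) > 32767))
    stop("z_scale too small: counts exceed int16 range")
  rows <- nrow(img$z)
  cols <- ncol(img$z)
  pitch_x <- if (cols > 1) img$x[2] - img$x[1] else 1
  pitch_y <- if (rows > 1) img$y[2] - img$y[1] else 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("S94F", con, nchars = 4L, eos = NULL)
  writeBin(as.integer(c(1L, cols, rows)), con, size = 2L, endian = "little")
  writeBin(as.double(c(pitch_x * cols, pitch_y * rows, z_scale)), con,
           size = 8L, endian = "little")
  writeBin(as.integer(counts), con, size = 2L, endian = "little")
  invisible(path)
}

check_uniform_axes <- function(img, tol = 1e-8) {
  for (ax in c("x", "y")) {
    v <- img[[ax]]
    if (length(v) > 2) {
      d <- diff(v)
      if (max(d) - min(d) > tol * max(abs(d)))
        stop("non-uniform ", ax, " axis spacing")
    }
  }
  invisible(img)
}

#' Export a scan image as an 8-bit greyscale PNG
#'
#' Intensities follow the linear greyscale convention of SPM display
#' software: `round(255 * (Z - Zmin) / (Zmax - Zmin))` per pixel
#' (round half up), normalised per image; a constant image maps to all
#' zeros. Row 1 of the grid (smallest Y) is drawn at the bottom of the
#' raster, i.e. the raster is vertically flipped relative to the grid.
#'
#' @param img a [scan_image()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  validate_scan_image(img)
  m <- png_intensities(img$z)
  png::writePNG(m[rev(seq_len(nrow(m))), , drop = FALSE] / 255, path)
  invisible(path)
}

png_intensities <- function(z) {
  rng <- max(z) - min(z)
  if (rng == 0) return(matrix(0L, nrow(z), ncol(z)))
  m <- floor(255 * (z - min(z)) / rng + 0.5)
  storage.mode(m) <- "integer"
  m
}

# shared helper: write a label grid (1..k) as a k-level greyscale PNG,
# lowest cluster black, highest white, intermediates evenly spaced
write_label_png <- function(labels, k, path) {
  grey <- if (k == 1) labels * 0 else round(255 * (labels - 1) / (k - 1))
  png::writePNG(grey[rev(seq_len(nrow(grey))), , drop = FALSE] / 255, path)
  invisible(path)
}
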