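#' Filter configuration
#'
#' Bundles the Boolean switches and percentile limits that drive
#' [filter_folder()], mirroring the flag-driven configuration of batch SPM
#' filtering scripts.
#'
#' @param apply_flatten apply [flatten_line_parabola()] first?
#' @param apply_equalize apply [equalize()] (always after flattening)?
#' @param lower_percentile lower clipping percentile in `[0, 100)`.
#' @param upper_percentile upper clipping percentile in `(0, 100]`.
#' @param emit_png also write a greyscale PNG per processed image?
#' @param emit_control_plots also write a before/after Z-histogram control
#'   plot per image?
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(apply_flatten = TRUE, apply_equalize = TRUE,
                          lower_percentile = 1, upper_percentile = 99,
                          emit_png = FALSE, emit_control_plots = FALSE) {
  check_percentiles(lower_percentile, upper_percentile)
  structure(list(apply_flatten = isTRUE(apply_flatten),
                 apply_equalize = isTRUE(apply_equalize),
                 lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile,
                 emit_png = isTRUE(emit_png),
                 emit_control_plots = isTRUE(emit_control_plots)),
            class = "filter_config")
}

check_percentiles <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) ||
      lo < 0 || lo >= 100 || hi <= 0 || hi > 100 || lo >= hi)
    stop("percentile limits must satisfy 0 <= lower < upper <= 100 (got ",
         lo, ", ", hi, ")")
  invisible(NULL)
}

#' Line-wise parabolic flattening
#'
#' Removes instrumental background (tilt, bow, piezo creep) from a
#' topograph by fitting each horizontal scan line independently with a
#' least-squares parabola in the physical X coordinate and subtracting the
#' fit. Residuals of every row are orthogonal to \{1, X, X^2\}; axes and
#' metadata are unchanged.
#'
#' @param img a [scan_image()] with at least 3 columns.
#' @return The flattened [scan_image()].
#' @export
flatten_line_parabola <- function(img) {
  validate_scan_image(img)
  if (ncol(img$z) < 3)
    stop("each scan line needs at least 3 points for a quadratic fit; ",
         "supply wider images or reduce the fit order upstream")
  X <- cbind(1, img$x, img$x^2)
  img$z <- t(stats::lm.fit(X, t(img$z))$residuals)
  dimnames(img$z) <- NULL
  img
}

#' Percentile equalisation with zero rebasing
#'
#' Contrast enhancement that clips Z outliers and rebases the scale: the Z
#' values at the `lower` and `upper` percentiles of the image's Z
#' distribution become hard limits (values beyond them are reassigned to
#' the nearest limit), then the whole image is shifted so its minimum is
#' exactly 0. Relative differences among unclipped points are preserved.
#' Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param img a [scan_image()].
#' @param lower,upper percentile limits, `0 <= lower < upper <= 100`.
#' @return The equalised [scan_image()]; a constant input yields all zeros.
#' @export
equalize <- function(img, lower = 1, upper = 99) {
  validate_scan_image(img)
  check_percentiles(lower, upper)
  q <- stats::quantile(img$z, c(lower, upper) / 100, names = FALSE, type = 7)
  z <- pmin(pmax(img$z, q[1]), q[2])
  img$z <- z - min(z)
  img
}

#' Batch-filter a folder of XYZ ASCII images
#'
#' Reads every matching file in `in_dir` in lexicographic order, applies
#' the enabled corrections (flattening always before equalisation, since
#' residual tilt distorts the Z distribution the outlier clip relies on)
#' and writes the result as an XYZ ASCII file of the same structure into
#' `out_dir`, optionally with a greyscale PNG and a histogram control plot.
#' Unparseable files are logged, skipped and counted.
#'
#' @param in_dir input directory.
#' @param out_dir output directory (created if needed).
#' @param config a [filter_config()].
#' @param pattern input file-name regexp.
#' @return A summary of class `filter_summary`: counts and names of
#'   processed and failed files.
#' @export
filter_folder <- function(in_dir, out_dir, config = filter_config(),
                          pattern = "\\.(txt|xyz)$") {
  stopifnot(inherits(config, "filter_config"))
  files <- sort(list.files(in_dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0)
    stop("no input files matching '", pattern, "' in ", in_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- character(0)
  failed <- character(0)
  for (f in files) {
    res <- tryCatch({
      img <- read_xyz_ascii(f)
      raw <- img
      if (config$apply_flatten) img <- flatten_line_parabola(img)
      if (config$apply_equalize)
        img <- equalize(img, config$lower_percentile, config$upper_percentile)
      base <- sub("\\.[^.]*$", "", basename(f))
      write_xyz_ascii(img, file.path(out_dir, paste0(base, ".txt")))
      if (config$emit_png)
        write_png(img, file.path(out_dir, paste0(base, ".png")))
      if (config$emit_control_plots)
        control_histogram(raw, img, file.path(out_dir, paste0(base, "_hist.png")))
      TRUE
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      FALSE
    })
    if (res) ok <- c(ok, basename(f)) else failed <- c(failed, basename(f))
  }
  structure(list(processed = length(ok), failed = length(failed),
                 files = ok, failures = failed, out_dir = out_dir),
            class = "filter_summary")
}

control_histogram <- function(raw, filtered, path) {
  grDevices::png(path, width = 800, height = 400)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old), add = TRUE)
  graphics::hist(raw$z, breaks = 64, main = "raw Z", xlab = "Z")
  graphics::hist(filtered$z, breaks = 64, main = "filtered Z", xlab = "Z")
  invisible(path)
}

#' @export
print.filter_summary <- function(x, ...) {
  cat(sprintf("<filter_summary> %d processed, %d failed -> %s\n",
              x$processed, x$failed, x$out_dir))
  if (x$failed > 0) cat("  failed:", paste(x$failures, collapse = ", "), "\n")
  invisible(x)
}
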