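#' Calibrate a fixed-threshold segmentation scheme
#'
#' The fast alternative to per-frame mixture fitting for long, highly
#' correlated series (video frames): the Z range ("maximum extension of
#' the Z distribution") of each of the first `n` frames — assumed to be
#' acquired at the equilibrium condition — is averaged, the average
#' extension is divided into `n_intervals` equal-width intervals anchored
#' at Z = 0 (the frames are expected to be equalised upstream, so their
#' minimum is rebased to 0), and the resulting interior boundaries are
#' frozen for the whole series.
#'
#' Frames with zero Z extension are excluded from the average with a
#' warning rather than poisoning the scheme.
#'
#' @param series an [image_series()] of equalised frames.
#' @param n number of leading calibration frames (`<= length(series)`).
#' @param n_intervals number of equal-width intervals, `>= 1`.
#' @return An object of class `threshold_scheme` with fields
#'   `n_intervals`, `reference_extension`, `boundaries` (the
#'   `n_intervals - 1` interior thresholds `i * extension / n_intervals`),
#'   `n_calibration` and `calibration_files`.
#' @export
calibrate_scheme <- function(series, n, n_intervals) {
  stopifnot(inherits(series, "image_series"))
  if (n < 1 || n > length(series$frames))
    stop("n must be between 1 and the series length (", length(series$frames),
         "); got ", n)
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  cal <- series$frames[seq_len(n)]
  ext <- vapply(cal, function(f) max(f$z) - min(f$z), numeric(1))
  zero <- ext <= 0
  if (any(zero))
    warning(sum(zero), " zero-extension calibration frame(s) excluded ",
            "from the average (frames ",
            paste(series$indices[seq_len(n)][zero], collapse = ", "), ")")
  if (all(zero)) stop("all calibration frames have zero Z extension")
  ref <- mean(ext[!zero])
  structure(list(
    n_intervals = as.integer(n_intervals),
    reference_extension = ref,
    boundaries = seq_len(n_intervals - 1L) * ref / n_intervals,
    n_calibration = as.integer(n),
    calibration_files = series_file_names(series)[seq_len(n)]
  ), class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf(
    "<threshold_scheme> %d intervals over average extension %.4g (from %d frames)\n",
    x$n_intervals, x$reference_extension, x$n_calibration))
  if (length(x$boundaries))
    cat("  boundaries:", paste(signif(x$boundaries, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a frozen threshold scheme to one image
#'
#' Labels every pixel with the index of the half-open interval
#' `[b[i-1], b[i])` containing its Z value; interval 1 extends below the
#' first boundary and the top interval is closed above at +Inf, so later
#' frames exceeding the calibrated extension are absorbed rather than
#' dropped. No optimisation is involved — runtime is linear in the pixel
#' count, which is the method's speed advantage over the mixture fit.
#'
#' @param img a [scan_image()].
#' @param scheme a [calibrate_scheme()] result.
#' @return A list with `labels` (integer matrix, values 1..n_intervals)
#'   and `fractions` (pixel fraction per interval, summing to 1).
#' @export
apply_scheme <- function(img, scheme) {
  validate_scan_image(img)
  stopifnot(inherits(scheme, "threshold_scheme"))
  lab <- findInterval(img$z, scheme$boundaries) + 1L
  lab <- matrix(lab, nrow(img$z), ncol(img$z))
  list(labels = lab,
       fractions = tabulate(lab, scheme$n_intervals) / length(lab))
}

#' Segment an image series with a frozen threshold scheme
#'
#' Applies the calibrated scheme to every frame (never recomputing the
#' boundaries), writes one segmented PNG per frame with the same grey-level
#' convention as the mixture segmenter, and collects a cumulative
#' tab-separated table with one row per (frame, interval): image index,
#' file name, interval id, lower/upper bound and pixel fraction.
#'
#' @param series an [image_series()].
#' @param scheme a [calibrate_scheme()] result (calibrated on this series
#'   or a statistically comparable one).
#' @param out_dir if non-`NULL`, per-frame PNGs `seg_thr_<index>.png` and
#'   the table `threshold_intervals.tsv` are written there.
#' @return The cumulative table as a data.frame.
#' @export
segment_series_threshold <- function(series, scheme, out_dir = NULL) {
  stopifnot(inherits(series, "image_series"),
            inherits(scheme, "threshold_scheme"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- scheme$n_intervals
  lower <- c(0, scheme$boundaries)
  upper <- c(scheme$boundaries, Inf)
  files <- series_file_names(series)
  rows <- vector("list", length(series$frames))
  for (i in seq_along(series$frames)) {
    idx <- series$indices[i]
    seg <- tryCatch(apply_scheme(series$frames[[i]], scheme),
                    error = function(e) e)
    if (inherits(seg, "error")) {
      message("frame ", idx, ": segmentation failed (",
              conditionMessage(seg), ")")
      next
    }
    rows[[i]] <- data.frame(image = idx, file = files[i],
                            interval = seq_len(k),
                            lower = lower, upper = upper,
                            pixel_fraction = seg$fractions)
    if (!is.null(out_dir))
      write_label_png(seg$labels, k,
                      file.path(out_dir, sprintf("seg_thr_%04d.png", idx)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out_dir))
    utils::write.table(tab, file.path(out_dir, "threshold_intervals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
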