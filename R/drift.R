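#' Expand an image with a zero border
#'
#' Embeds the topograph in a larger canvas of exact zeros ("a black empty
#' frame") so that later rigid translations stay inside the canvas and
#' leave a visible trace of the original position. Physical axes are
#' extended with the original (uniform) spacing.
#'
#' @param img a [scan_image()] with uniformly spaced axes.
#' @param pad border width in pixels, `>= 0`.
#' @return A `(rows + 2 pad) x (cols + 2 pad)` [scan_image()] with the
#'   original data centred.
#' @export
expand_grid <- function(img, pad) {
  validate_scan_image(img)
  pad <- as.integer(pad)
  if (pad < 0) stop("pad must be >= 0")
  if (pad == 0) return(img)
  check_uniform_axes(img)
  r <- nrow(img$z)
  co <- ncol(img$z)
  dx <- if (co > 1) img$x[2] - img$x[1] else 1
  dy <- if (r > 1) img$y[2] - img$y[1] else 1
  z <- matrix(0, r + 2L * pad, co + 2L * pad)
  z[pad + seq_len(r), pad + seq_len(co)] <- img$z
  out <- img
  out$z <- z
  out$x <- img$x[1] + (seq_len(co + 2L * pad) - 1L - pad) * dx
  out$y <- img$y[1] + (seq_len(r + 2L * pad) - 1L - pad) * dy
  out$metadata$pad <- pad
  out
}

#' Load an anchor track
#'
#' Reads the headless replacement for interactive anchor picking: a
#' tab/whitespace-separated text file with one line per sampled frame —
#' `file_name  x_centre  y_centre` — where the centres are 1-based pixel
#' coordinates of the tracked feature in the (expanded) image frame.
#' Lines starting with `#` are comments. File names are resolved against
#' the series' frame metadata; entries are sorted by frame index, so input
#' line order is irrelevant. The earliest sampled frame is the reference.
#'
#' @param path path to the track file.
#' @param series the [image_series()] the file names refer to.
#' @param box_size side of the tracking square in pixels (bookkeeping
#'   only; default 0).
#' @return An object of class `anchor_track`: data.frame `entries` with
#'   columns `frame`, `file`, `x`, `y`, plus `box_size`.
#' @export
load_anchor_track <- function(path, series, box_size = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no anchor entries in ", path)
  toks <- strsplit(lines, "[\\s]+", perl = TRUE)
  bad <- lengths(toks) < 3L
  if (any(bad)) stop("anchor entry with fewer than 3 fields: '",
                     lines[which(bad)[1]], "'")
  df <- data.frame(
    file = vapply(toks, `[`, character(1), 1L),
    x = as.numeric(vapply(toks, `[`, character(1), 2L)),
    y = as.numeric(vapply(toks, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$x) || anyNA(df$y))
    stop("non-numeric anchor coordinate in ", path)
  anchor_track(df, series, box_size = box_size)
}

#' Build an anchor track from in-memory entries
#'
#' @param entries data.frame with columns `file`, `x`, `y` (see
#'   [load_anchor_track()]).
#' @param series the [image_series()] the file names refer to.
#' @param box_size side of the tracking square in pixels.
#' @return An `anchor_track` object.
#' @export
anchor_track <- function(entries, series, box_size = 0L) {
  stopifnot(inherits(series, "image_series"))
  files <- series_file_names(series)
  pos <- match(entries$file, files)
  if (anyNA(pos))
    stop("anchor file name not found in the series: '",
         entries$file[which(is.na(pos))[1]], "'")
  frame <- series$indices[pos]
  if (anyDuplicated(frame))
    stop("duplicate anchor entry for frame ",
         frame[anyDuplicated(frame)])
  d <- dim(series$frames[[1]]$z)
  oob <- entries$x < 1 | entries$x > d[2] | entries$y < 1 | entries$y > d[1]
  if (any(oob))
    stop(sprintf(
      "anchor centre out of image bounds for '%s': (%g, %g) not in [1, %d] x [1, %d]",
      entries$file[which(oob)[1]], entries$x[which(oob)[1]],
      entries$y[which(oob)[1]], d[2], d[1]))
  o <- order(frame)
  structure(list(
    entries = data.frame(frame = frame[o], file = entries$file[o],
                         x = entries$x[o], y = entries$y[o],
                         stringsAsFactors = FALSE),
    box_size = as.integer(box_size)
  ), class = "anchor_track")
}

#' @export
print.anchor_track <- function(x, ...) {
  cat(sprintf("<anchor_track> %d anchors on frames %d..%d (box %d px)\n",
              nrow(x$entries), x$entries$frame[1],
              x$entries$frame[nrow(x$entries)], x$box_size))
  invisible(x)
}

#' Fit a translational drift model to an anchor track
#'
#' The first anchor is the reference; every later anchor's deviation
#' `(x_i - x_0, y_i - y_0)` is fitted per axis as a smooth function of the
#' frame index — a natural cubic spline through the anchors, or a
#' least-squares polynomial — and evaluated at every frame of the series.
#' Frames beyond the last anchor hold the last fitted deviation constant
#' (spline/polynomial extrapolation diverges); frames before the first
#' anchor hold the first. The reference-frame deviation is forced to
#' exactly (0, 0) (for the polynomial fit the whole curve is shifted by
#' its value at the reference).
#'
#' @param track an [anchor_track()].
#' @param n_frames number of frames to evaluate (frame indices
#'   `0..n_frames-1`).
#' @param fit_kind `"cubic_spline"` (default) or `"polynomial"`.
#' @param poly_degree polynomial degree when `fit_kind = "polynomial"`.
#' @return An object of class `drift_model`: data.frame `deviations` with
#'   columns `frame`, `dx`, `dy` (pixels), plus `fit_kind`, `poly_degree`
#'   and the source `anchors`.
#' @export
build_drift_model <- function(track, n_frames,
                              fit_kind = c("cubic_spline", "polynomial"),
                              poly_degree = 3L) {
  stopifnot(inherits(track, "anchor_track"))
  fit_kind <- match.arg(fit_kind)
  e <- track$entries
  n_anchor <- nrow(e)
  if (fit_kind == "cubic_spline" && n_anchor < 2)
    stop("the cubic spline fit needs at least 2 anchors; got ", n_anchor)
  if (fit_kind == "polynomial" && n_anchor < poly_degree + 1)
    stop("a degree-", poly_degree, " polynomial fit needs at least ",
         poly_degree + 1, " anchors; got ", n_anchor)
  t_anchor <- e$frame
  dev_anchor <- cbind(e$x - e$x[1], e$y - e$y[1])
  frames <- 0:(n_frames - 1L)
  t_eval <- pmin(pmax(frames, t_anchor[1]), t_anchor[n_anchor])
  dev <- matrix(0, n_frames, 2)
  for (ax in 1:2) {
    if (fit_kind == "cubic_spline") {
      f <- stats::splinefun(t_anchor, dev_anchor[, ax], method = "natural")
      dev[, ax] <- f(t_eval)
    } else {
      X <- outer(t_anchor, 0:poly_degree, "^")
      beta <- stats::lm.fit(X, dev_anchor[, ax])$coefficients
      beta[is.na(beta)] <- 0
      dev[, ax] <- outer(t_eval, 0:poly_degree, "^") %*% beta
      ref_val <- sum(beta * t_anchor[1]^(0:poly_degree))
      dev[, ax] <- dev[, ax] - ref_val
    }
  }
  ref_row <- match(t_anchor[1], frames)
  if (!is.na(ref_row)) dev[ref_row, ] <- 0
  structure(list(
    deviations = data.frame(frame = frames, dx = dev[, 1], dy = dev[, 2]),
    fit_kind = fit_kind,
    poly_degree = if (fit_kind == "polynomial") as.integer(poly_degree) else NA_integer_,
    anchors = track
  ), class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  d <- x$deviations
  cat(sprintf(
    "<drift_model> %s over %d frames, %d anchors; max |dx| %.2f px, max |dy| %.2f px\n",
    x$fit_kind, nrow(d), nrow(x$anchors$entries),
    max(abs(d$dx)), max(abs(d$dy))))
  invisible(x)
}

#' Plot fitted drift trajectories
#'
#' Control plot of the fitted per-frame deviations x(t) and y(t) with the
#' anchor deviations overlaid.
#'
#' @param x a [build_drift_model()] result.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.drift_model <- function(x, ...) {
  d <- x$deviations
  graphics::matplot(d$frame, cbind(d$dx, d$dy), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "frame", ylab = "deviation (px)", ...)
  e <- x$anchors$entries
  graphics::points(e$frame, e$x - e$x[1], col = "firebrick", pch = 19)
  graphics::points(e$frame, e$y - e$y[1], col = "steelblue", pch = 19)
  graphics::legend("topleft", c("dx", "dy"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Apply a drift model to an image series
#'
#' Rigidly translates every frame by the negated, whole-pixel-rounded
#' fitted deviation, cancelling the drift so the tracked feature stays at
#' the reference position. Translation is integer-pixel only (no
#' resampling), so the multiset of non-zero Z values of each frame is
#' preserved bit-exactly; vacated pixels are 0. Frames must already be
#' grid-expanded with enough padding — if a translation would push data
#' pixels off the canvas, an error names the frame and the minimum pad
#' needed.
#'
#' @param series a grid-expanded [image_series()].
#' @param model a [build_drift_model()] whose frame range covers the
#'   series indices.
#' @return The corrected [image_series()].
#' @export
apply_correction <- function(series, model) {
  stopifnot(inherits(series, "image_series"), inherits(model, "drift_model"))
  dev <- model$deviations
  pos <- match(series$indices, dev$frame)
  if (anyNA(pos))
    stop("drift model does not cover frame ",
         series$indices[which(is.na(pos))[1]])
  frames <- series$frames
  for (i in seq_along(frames)) {
    dc <- -round(dev$dx[pos[i]])
    dr <- -round(dev$dy[pos[i]])
    if (dc == 0 && dr == 0) next
    z <- frames[[i]]$z
    n_data <- sum(z != 0)
    shifted <- shift_matrix(z, dr, dc)
    if (sum(shifted != 0) != n_data) {
      lost <- n_data - sum(shifted != 0)
      stop(sprintf(
        "frame %d: translation (%d, %d) px pushes %d data pixel(s) off the canvas; re-expand with pad >= %d",
        series$indices[i], dc, dr, lost, max(abs(dc), abs(dr))))
    }
    frames[[i]]$z <- shifted
    frames[[i]]$metadata$drift_corrected <- c(dx = dc, dy = dr)
  }
  image_series(frames, series$indices)
}

# rigid integer translation: content moves by dr rows and dc columns,
# vacated pixels become 0
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr)[seq_len(nr) + dr >= 1 & seq_len(nr) + dr <= nr]
  src_c <- seq_len(nc)[seq_len(nc) + dc >= 1 & seq_len(nc) + dc <= nc]
  if (length(src_r) && length(src_c))
    out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

#' Correct a series end-to-end from an anchor track
#'
#' Convenience wrapper: expands every frame with `pad` zeros (default
#' `ceiling(1.5 * max anchor deviation)`), builds the drift model in the
#' expanded pixel frame and applies it. The anchor coordinates must refer
#' to the expanded frame when `pad` is supplied explicitly as 0.
#'
#' @param series an [image_series()] (not yet expanded; anchor coordinates
#'   refer to the unexpanded frames).
#' @param track an [anchor_track()] on the unexpanded frames.
#' @param pad zero-border width in pixels; `NULL` for the default.
#' @param fit_kind,poly_degree passed to [build_drift_model()].
#' @return A list with the corrected `series` (expanded frames) and the
#'   `model`.
#' @export
drift_correct_series <- function(series, track, pad = NULL,
                                 fit_kind = "cubic_spline", poly_degree = 3L) {
  e <- track$entries
  max_dev <- max(abs(c(e$x - e$x[1], e$y - e$y[1])), 1)
  if (is.null(pad)) pad <- ceiling(1.5 * max_dev)
  expanded <- image_series(lapply(series$frames, expand_grid, pad = pad),
                           series$indices)
  model <- build_drift_model(track, n_frames = max(series$indices) + 1L,
                             fit_kind = fit_kind, poly_degree = poly_degree)
  list(series = apply_correction(expanded, model), model = model, pad = pad)
}
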