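#' Specification for a synthetic monolayer topograph
#'
#' Describes a molecular-monolayer test image with known ground truth: a
#' periodic lattice of blob-shaped molecules drawn from a few discrete
#' height classes over a low background, per-scan-line smooth (up to
#' quadratic) background offsets, additive Gaussian noise and sparse
#' single-pixel Z spikes. The defaults emulate a porphyrin-like adlayer:
#' ~8 px lattice period, three height classes at 0 / +25 / +45 pm
#' (background, dark and bright molecules), 4 pm noise.
#'
#' Molecules are rendered by default as flat-top discs with a cosine edge
#' taper (`blob_shape = "disc"`): a molecule images as a compact object of
#' roughly uniform apparent height, which is exactly the discrete-height
#' structure the Z-distribution segmenters assume. A pure Gaussian bump
#' profile (`blob_shape = "gaussian"`) is available but spreads the blob's
#' pixels over all intermediate heights, so its Z histogram has no mode at
#' the class height.
#'
#' @param rows,cols image size in pixels.
#' @param lattice_spacing lattice period in pixels.
#' @param blob_sigma blob radius parameter in pixels: the flat-top radius
#'   for `"disc"`, the Gaussian sigma for `"gaussian"`.
#' @param edge_width half-width of the cosine edge taper (disc shape), px.
#' @param blob_shape `"disc"` or `"gaussian"`.
#' @param lattice `"square"` or `"triangular"`.
#' @param class_offsets Z offset of each molecule class (pm); class 1 is
#'   conventionally the background at 0.
#' @param class_probabilities probability of each class per lattice site;
#'   must sum to 1.
#' @param noise_sd additive Gaussian noise standard deviation (pm).
#' @param outlier_fraction fraction of pixels hit by a spike, in `[0, 1)`.
#' @param outlier_magnitude spike amplitude (pm); spikes are `+/-` this.
#' @param line_background list of length-2 ranges `a`, `b`, `c` for the
#'   per-row background `a + b*x + c*x^2` (x = column index starting at
#'   0); each row draws its coefficients uniformly from these ranges.
#' @param seed integer seed; one global seed drives independent
#'   per-purpose substreams (placement, backgrounds, noise, outliers).
#' @return An object of class `monolayer_spec`.
#' @export
monolayer_spec <- function(rows = 128L, cols = 128L,
                           lattice_spacing = 8,
                           blob_sigma = 3.3,
                           edge_width = 0.3,
                           blob_shape = c("disc", "gaussian"),
                           lattice = c("square", "triangular"),
                           class_offsets = c(0, 25, 45),
                           class_probabilities = c(0.5, 0.3, 0.2),
                           noise_sd = 4,
                           outlier_fraction = 0.002,
                           outlier_magnitude = 200,
                           line_background = list(a = c(-10, 10),
                                                  b = c(-0.08, 0.08),
                                                  c = c(-5e-4, 5e-4)),
                           seed = 1L) {
  blob_shape <- match.arg(blob_shape)
  lattice <- match.arg(lattice)
  if (abs(sum(class_probabilities) - 1) > 1e-9)
    stop("class_probabilities must sum to 1")
  if (length(class_probabilities) != length(class_offsets))
    stop("one probability per class offset required")
  if (lattice_spacing <= 0 || blob_sigma <= 0)
    stop("lattice_spacing and blob_sigma must be positive")
  if (blob_shape == "disc" && lattice_spacing < 2 * (blob_sigma + edge_width))
    stop("lattice too dense for the blob size: spacing ", lattice_spacing,
         " < 2 * (radius + edge) = ", 2 * (blob_sigma + edge_width))
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  structure(as.list(environment()), class = "monolayer_spec")
}

#' Specification for a drifting synthetic series
#'
#' Describes an image sequence built from one monolayer scene that is
#' rigidly translated along a smooth trajectory with fresh noise per
#' frame, emulating the slow translational drift that makes a long series
#' lose its initial position. An optional dim schedule reduces one class's
#' height offset from a given frame onward, emulating the contrast drop of
#' a potential-step experiment.
#'
#' @param n_frames number of frames.
#' @param trajectory function of the 0-based frame index returning
#'   `c(dx, dy)` in pixels; must satisfy `trajectory(0) == c(0, 0)`. The
#'   default is a smooth nonlinear excursion reaching ~12 px.
#' @param dim_schedule `NULL`, or a list with `frame` (first affected
#'   0-based frame), `class` (class index in `class_offsets`), `factor`
#'   (multiplier applied to the affected molecules' offset from `frame`
#'   on) and optionally `fraction` (share of that class's molecules that
#'   dim, default 1). A fractional schedule emulates the chronoamperometric
#'   response, where part of the molecular population goes dark: mass moves
#'   from the middle mode of the Z distribution into the low one, which is
#'   what makes the lowest-cluster pixel fraction rise under both
#'   segmenters.
#' @param seed integer seed for the per-frame noise substreams.
#' @return An object of class `drift_spec`.
#' @export
drift_spec <- function(n_frames = 60L,
                       trajectory = NULL,
                       dim_schedule = NULL,
                       seed = 1L) {
  if (is.null(trajectory)) {
    n <- n_frames
    trajectory <- function(t) c(12 * sin(pi * t / (1.6 * n))^2,
                                8 * (1 - cos(2 * pi * t / (1.9 * n))) / 2)
  }
  t0 <- trajectory(0)
  if (length(t0) != 2 || any(abs(t0) > 1e-12))
    stop("trajectory(0) must be c(0, 0)")
  if (!is.null(dim_schedule)) {
    stopifnot(is.list(dim_schedule),
              all(c("frame", "class", "factor") %in% names(dim_schedule)))
    if (is.null(dim_schedule$fraction)) dim_schedule$fraction <- 1
  }
  structure(list(n_frames = as.integer(n_frames), trajectory = trajectory,
                 dim_schedule = dim_schedule, seed = as.integer(seed)),
            class = "drift_spec")
}

# independent substream seeds derived from one global seed (kept < 2^31)
substream_seed <- function(seed, purpose) {
  offs <- c(placement = 101L, background = 211L, noise = 307L,
            outliers = 401L, frame = 503L)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[purpose]]
}

#' Generate a synthetic monolayer topograph with ground truth
#'
#' Renders the scene described by a [monolayer_spec()]: molecules on the
#' lattice (composited by pointwise maximum, so with zero noise and zero
#' backgrounds the Z at a molecule centre equals its class offset
#' exactly), then per-row backgrounds, noise and outlier spikes. Output is
#' deterministic for a fixed seed.
#'
#' @param spec a [monolayer_spec()].
#' @param shift_px optional `c(dx, dy)` integer pixel translation applied
#'   to all molecule centres (used by [make_drift_series()]).
#' @param offsets_override optional replacement for `spec$class_offsets`.
#' @param molecule_scale optional per-molecule amplitude multiplier
#'   (recycled over lattice sites; used by the dim schedule).
#' @param noise_seed optional replacement for the noise/outlier substream
#'   seed (used for per-frame fresh noise).
#' @return A list with `image` (a [scan_image()]) and `truth`: molecule
#'   centres (1-based pixel coordinates), classes and offsets, the per-row
#'   background coefficients and the spec itself.
#' @export
make_monolayer_image <- function(spec, shift_px = c(0, 0),
                                 offsets_override = NULL,
                                 molecule_scale = NULL,
                                 noise_seed = NULL) {
  stopifnot(inherits(spec, "monolayer_spec"))
  rng <- save_rng_state()
  on.exit(restore_rng_state(rng))
  offsets <- if (is.null(offsets_override)) spec$class_offsets else offsets_override

  # placement + class assignment substream (scene identity)
  set.seed(substream_seed(spec$seed, "placement"))
  centres <- lattice_centres(spec)
  classes <- sample.int(length(offsets), nrow(centres), replace = TRUE,
                        prob = spec$class_probabilities)
  cx <- centres[, 1] + shift_px[1]
  cy <- centres[, 2] + shift_px[2]

  z <- matrix(0, spec$rows, spec$cols)
  amp <- offsets[classes]
  if (!is.null(molecule_scale))
    amp <- amp * rep_len(molecule_scale, length(amp))
  for (m in seq_along(amp)) {
    if (amp[m] == 0) next
    z <- composite_blob(z, cx[m], cy[m], amp[m], spec)
  }

  set.seed(substream_seed(spec$seed, "background"))
  coef <- cbind(a = stats::runif(spec$rows, spec$line_background$a[1],
                                 spec$line_background$a[2]),
                b = stats::runif(spec$rows, spec$line_background$b[1],
                                 spec$line_background$b[2]),
                c = stats::runif(spec$rows, spec$line_background$c[1],
                                 spec$line_background$c[2]))
  xs <- seq_len(spec$cols) - 1
  z <- z + coef[, "a"] %*% t(rep(1, spec$cols)) +
    coef[, "b"] %*% t(xs) + coef[, "c"] %*% t(xs^2)

  set.seed(if (is.null(noise_seed)) substream_seed(spec$seed, "noise")
           else noise_seed)
  if (spec$noise_sd > 0)
    z <- z + matrix(stats::rnorm(length(z), 0, spec$noise_sd),
                    spec$rows, spec$cols)
  if (spec$outlier_fraction > 0) {
    n_out <- round(spec$outlier_fraction * length(z))
    if (n_out > 0) {
      pix <- sample.int(length(z), n_out)
      z[pix] <- z[pix] + sample(c(-1, 1), n_out, replace = TRUE) *
        spec$outlier_magnitude
    }
  }

  list(image = scan_image(z, metadata = list(file = "synthetic.xyz",
                                             synthetic = TRUE)),
       truth = list(molecules = data.frame(x = cx, y = cy, class = classes,
                                           offset = amp),
                    row_coefficients = as.data.frame(coef),
                    class_offsets = offsets,
                    spec = spec))
}

lattice_centres <- function(spec) {
  s <- spec$lattice_spacing
  if (spec$lattice == "square") {
    gx <- seq(s / 2, spec$cols, by = s)
    gy <- seq(s / 2, spec$rows, by = s)
    as.matrix(expand.grid(x = gx, y = gy))
  } else {
    ry <- s * sqrt(3) / 2
    gy <- seq(s / 2, spec$rows, by = ry)
    out <- lapply(seq_along(gy), function(i) {
      off <- if (i %% 2 == 0) s / 2 else 0
      gx <- seq(s / 2 + off, spec$cols, by = s)
      cbind(x = gx, y = rep(gy[i], length(gx)))
    })
    do.call(rbind, out)
  }
}

# composite one molecule into the height map by pointwise maximum
composite_blob <- function(z, cx, cy, amp, spec) {
  r_max <- if (spec$blob_shape == "disc") spec$blob_sigma + spec$edge_width
           else 4 * spec$blob_sigma
  c_lo <- max(1L, floor(cx - r_max))
  c_hi <- min(ncol(z), ceiling(cx + r_max))
  r_lo <- max(1L, floor(cy - r_max))
  r_hi <- min(nrow(z), ceiling(cy + r_max))
  if (c_lo > c_hi || r_lo > r_hi) return(z)
  cc <- c_lo:c_hi
  rr <- r_lo:r_hi
  d <- sqrt(outer((rr - cy)^2, (cc - cx)^2, "+"))
  p <- if (spec$blob_shape == "disc") {
    r0 <- spec$blob_sigma
    e <- spec$edge_width
    ifelse(d <= r0 - e, 1,
           ifelse(d >= r0 + e, 0,
                  0.5 * (1 + cos(pi * (d - r0 + e) / (2 * e)))))
  } else {
    exp(-d^2 / (2 * spec$blob_sigma^2))
  }
  z[rr, cc] <- pmax(z[rr, cc], amp * p)
  z
}

#' Generate a drifting synthetic series with ground truth
#'
#' Builds `n_frames` frames of the same monolayer scene (same molecule
#' placement and classes), each rigidly translated by the whole-pixel-
#' rounded trajectory with fresh per-frame noise and outliers, then
#' embedded in a zero border of `pad` pixels. The returned ground-truth
#' anchor track records the true centre of a reference molecule (the
#' brightest molecule nearest the scene centre) per frame, in the
#' expanded-image pixel frame — exactly what a user would click on.
#'
#' @param mono a [monolayer_spec()].
#' @param drift a [drift_spec()].
#' @param pad zero-border width in pixels; must exceed the maximum
#'   trajectory excursion.
#' @return A list with `series` (an [image_series()] of expanded frames),
#'   `track` (the full per-frame ground-truth [anchor_track()]) and
#'   `truth` (per-frame shifts and the base scene ground truth).
#' @export
make_drift_series <- function(mono, drift, pad = 16L) {
  stopifnot(inherits(mono, "monolayer_spec"), inherits(drift, "drift_spec"))
  rng <- save_rng_state()
  on.exit(restore_rng_state(rng))
  pad <- as.integer(pad)
  shifts <- t(vapply(0:(drift$n_frames - 1L), drift$trajectory, numeric(2)))
  shifts <- round(shifts)
  if (max(abs(shifts)) > 0 && max(abs(shifts)) >= pad)
    stop("trajectory excursion (", max(abs(shifts)),
         " px) must stay below pad (", pad, " px)")

  base <- make_monolayer_image(mono)  # scene identity (placement substream)
  mol <- base$truth$molecules
  bright <- which(mol$offset == max(mol$offset))
  ctr <- c(mono$cols, mono$rows) / 2
  ref_mol <- bright[which.min((mol$x[bright] - ctr[1])^2 +
                                (mol$y[bright] - ctr[2])^2)]

  frames <- vector("list", drift$n_frames)
  files <- sprintf("frame_%04d.xyz", 0:(drift$n_frames - 1L))
  ds <- drift$dim_schedule
  dim_scale <- rep(1, nrow(mol))
  if (!is.null(ds)) {
    affected <- which(mol$class == ds$class)
    if (ds$fraction < 1) {
      set.seed(substream_seed(drift$seed, "placement") + 7L)
      affected <- sample(affected, round(ds$fraction * length(affected)))
    }
    dim_scale[affected] <- ds$factor
  }
  for (t in seq_len(drift$n_frames)) {
    scale_t <- if (!is.null(ds) && (t - 1L) >= ds$frame) dim_scale else NULL
    fr <- make_monolayer_image(
      mono, shift_px = shifts[t, ], molecule_scale = scale_t,
      noise_seed = substream_seed(drift$seed, "frame") + t)
    img <- expand_grid(fr$image, pad)
    img$metadata$file <- files[t]
    frames[[t]] <- img
  }
  series <- image_series(frames, 0:(drift$n_frames - 1L))
  track <- anchor_track(
    data.frame(file = files,
               x = mol$x[ref_mol] + shifts[, 1] + pad,
               y = mol$y[ref_mol] + shifts[, 2] + pad,
               stringsAsFactors = FALSE),
    series)
  list(series = series, track = track,
       truth = list(shifts = shifts, base = base$truth,
                    reference_molecule = mol[ref_mol, , drop = FALSE],
                    dim_scale = dim_scale, pad = pad))
}

#' Write an anchor track to a tab-separated file
#'
#' @param track an [anchor_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anchor_track <- function(track, path) {
  stopifnot(inherits(track, "anchor_track"))
  e <- track$entries
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# file\tx_centre\ty_centre",
               sprintf("%s\t%.6g\t%.6g", e$file, e$x, e$y)), con)
  invisible(path)
}
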