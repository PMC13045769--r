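#' Read an XYZ ASCII topograph
#'
#' Parses the plain-text export dialect common to SPM analysis software:
#' three whitespace-separated columns holding the X, Y and Z position of one
#' image point per line, optionally preceded by a text header. Points are
#' placed on the grid by their (X, Y) coordinates, so any line order that
#' covers a complete rectangular grid parses to the same image.
#'
#' @param path path to the file.
#' @param header either `"auto"` (leading lines whose first token is not
#'   numeric are skipped and their count reported) or an integer number of
#'   header lines to skip.
#' @return A [scan_image()] with `metadata$file` set to the file name and
#'   `metadata$header_lines` to the number of header lines skipped.
#' @seealso [write_xyz_ascii()]
#' @export
read_xyz_ascii <- function(path, header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  orig <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  orig <- orig[keep]
  if (length(lines) == 0) stop("no data lines in ", path)

  if (identical(header, "auto")) {
    first_tok <- sub("^\\s*(\\S+).*$", "\\1", lines)
    is_num <- !is.na(suppressWarnings(as.numeric(first_tok)))
    n_skip <- match(TRUE, is_num, nomatch = length(lines) + 1L) - 1L
    if (n_skip > 0)
      message(n_skip, " header line(s) auto-detected and skipped in ",
              basename(path))
  } else {
    n_skip <- as.integer(header)
  }
  if (n_skip >= length(lines)) stop("no data lines after header in ", path)
  if (n_skip > 0) {
    lines <- lines[-seq_len(n_skip)]
    orig <- orig[-seq_len(n_skip)]
  }

  toks <- strsplit(trimws(lines), "[\\s,]+", perl = TRUE)
  short <- lengths(toks) < 3L
  if (any(short))
    stop("parse error at line ", orig[which(short)[1]],
         ": fewer than 3 fields")
  m <- vapply(toks, function(t) suppressWarnings(as.numeric(t[1:3])),
              numeric(3))
  if (anyNA(m)) {
    bad <- which(colSums(is.na(m)) > 0)[1]
    stop("parse error at line ", orig[bad], ": non-numeric field in '",
         lines[bad], "'")
  }
  xs <- sort(unique(m[1, ]))
  ys <- sort(unique(m[2, ]))
  n_expect <- length(xs) * length(ys)
  grid <- matrix(NA_real_, length(ys), length(xs))
  ind <- cbind(match(m[2, ], ys), match(m[1, ], xs))
  dup <- anyDuplicated(ind)
  if (dup > 0)
    stop("duplicate grid point (X=", m[1, dup], ", Y=", m[2, dup], ")")
  grid[ind] <- m[3, ]
  if (anyNA(grid)) {
    miss <- which(is.na(grid), arr.ind = TRUE)
    miss <- miss[order(miss[, 1], miss[, 2]), , drop = FALSE]
    stop(sprintf(
      "incomplete rectangular grid: first missing point (X=%g, Y=%g); %d of %d points present",
      xs[miss[1, 2]], ys[miss[1, 1]], ncol(m), n_expect))
  }
  scan_image(grid, xs, ys,
             metadata = list(file = basename(path), header_lines = n_skip))
}

#' Write an XYZ ASCII topograph
#'
#' Emits one "X Y Z" line per image point, X varying fastest (inner loop
#' over columns) and Y slowest, matching line-by-line acquisition order.
#' Values are printed with `digits` significant digits, so a read-back
#' reproduces the image to that precision.
#'
#' @param img a [scan_image()].
#' @param path output file path.
#' @param digits significant digits for all three columns (default 10).
#' @return `path`, invisibly.
#' @export
write_xyz_ascii <- function(img, path, digits = 10) {
  validate_scan_image(img)
  fmt <- sprintf("%%.%dg %%.%dg %%.%dg", digits, digits, digits)
  x_col <- rep(img$x, times = length(img$y))
  y_col <- rep(img$y, each = length(img$x))
  z_col <- as.vector(t(img$z))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(fmt, x_col, y_col, z_col), con)
  invisible(path)
}

#' Read a folder of XYZ ASCII files as an image series
#'
#' Files are read in lexicographic order and indexed 0, 1, 2, ...
#'
#' @param dir directory containing XYZ ASCII files.
#' @param pattern file-name regexp (default `"\\.(txt|xyz)$"`).
#' @param header passed to [read_xyz_ascii()].
#' @return An [image_series()].
#' @export
read_xyz_series <- function(dir, pattern = "\\.(txt|xyz)$", header = "auto") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) stop("no XYZ files matching '", pattern, "' in ", dir)
  image_series(lapply(files, read_xyz_ascii, header = header))
}
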