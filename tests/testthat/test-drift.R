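test_that("grid expansion centres the data in exact zeros", {
  img <- scan_image(matrix(1:16 + 0.5, 4, 4))
  big <- expand_grid(img, 2)
  expect_identical(dim(big$z), c(8L, 8L))
  expect_equal(big$z[3:6, 3:6], img$z)
  expect_equal(sum(big$z), sum(img$z))
  border <- big$z
  border[3:6, 3:6] <- 0
  expect_true(all(border == 0))
  # axes keep the original spacing
  expect_equal(diff(big$x), rep(1, 7))
  expect_identical(expand_grid(img, 0), img)
  expect_error(expand_grid(scan_image(matrix(1, 2, 2), x = c(0, 1), y = c(0, 1)), -1),
               "pad")
  irr <- scan_image(matrix(1:9, 3, 3), x = c(0, 1, 5))
  expect_error(expand_grid(irr, 1), "non-uniform")
})

make_named_series <- function(n, nr = 6, nc = 6) {
  frames <- lapply(seq_len(n), function(i) {
    img <- scan_image(matrix(runif(nr * nc), nr, nc))
    img$metadata$file <- sprintf("frame_%04d.xyz", i - 1)
    img
  })
  image_series(frames)
}

test_that("anchor tracks resolve file names, sort, and validate", {
  set.seed(41)
  ser <- make_named_series(21)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# file x y",
               "frame_0010.xyz\t4\t5",
               "frame_0000.xyz\t3\t3",
               "frame_0020.xyz\t5.5\t2"), f)
  trk <- load_anchor_track(f, ser)
  expect_equal(trk$entries$frame, c(0L, 10L, 20L))
  expect_equal(trk$entries$x, c(3, 4, 5.5))

  # shuffled lines parse to the identical track
  writeLines(c("frame_0020.xyz\t5.5\t2",
               "frame_0010.xyz\t4\t5",
               "frame_0000.xyz\t3\t3"), f)
  expect_identical(load_anchor_track(f, ser), trk)

  writeLines(c("frame_0000.xyz\t3\t3", "frame_0000.xyz\t4\t4"), f)
  expect_error(load_anchor_track(f, ser), "duplicate")
  writeLines("no_such.xyz\t3\t3", f)
  expect_error(load_anchor_track(f, ser), "not found in the series")
  writeLines("frame_0000.xyz\t99\t3", f)
  expect_error(load_anchor_track(f, ser), "out of image bounds")
})

test_that("two anchors interpolate linearly and the reference is pinned", {
  set.seed(42)
  ser <- make_named_series(11)
  trk <- anchor_track(data.frame(file = c("frame_0000.xyz", "frame_0010.xyz"),
                                 x = c(5, 6), y = c(5, 5.5)), ser)
  for (kind in c("cubic_spline", "polynomial")) {
    mod <- build_drift_model(trk, 11, fit_kind = kind, poly_degree = 1)
    expect_equal(unlist(mod$deviations[1, c("dx", "dy")]),
                 c(dx = 0, dy = 0))
    expect_equal(mod$deviations$dx[6], 0.5, tolerance = 1e-9)
    expect_equal(mod$deviations$dy[6], 0.25, tolerance = 1e-9)
  }
})

test_that("fits reproduce the anchor deviations at the knots", {
  set.seed(43)
  ser <- make_named_series(31, 40, 40)
  files <- sprintf("frame_%04d.xyz", c(0, 8, 15, 23, 30))
  dx <- c(0, 2.5, 7, 9, 10.5)
  dy <- c(0, -1, -3, -2, 1)
  trk <- anchor_track(data.frame(file = files, x = 20 + dx, y = 20 + dy), ser)
  sp <- build_drift_model(trk, 31, "cubic_spline")
  expect_equal(sp$deviations$dx[c(0, 8, 15, 23, 30) + 1], dx, tolerance = 1e-9)
  expect_equal(sp$deviations$dy[c(0, 8, 15, 23, 30) + 1], dy, tolerance = 1e-9)
  # degree = n_anchors - 1 polynomial also interpolates
  po <- build_drift_model(trk, 31, "polynomial", poly_degree = 4)
  expect_equal(po$deviations$dx[c(0, 8, 15, 23, 30) + 1], dx, tolerance = 1e-6)
  # beyond the last anchor the deviation holds constant
  sp2 <- build_drift_model(trk, 40, "cubic_spline")
  expect_equal(sp2$deviations$dx[32:40], rep(10.5, 9))
  expect_error(build_drift_model(trk, 31, "polynomial", poly_degree = 5),
               "at least 6 anchors")
})

test_that("spline and polynomial agree on a low-order trajectory", {
  set.seed(44)
  ser <- make_named_series(61, 50, 50)
  tt <- seq(0, 60, by = 10)
  files <- sprintf("frame_%04d.xyz", tt)
  dx <- 0.003 * tt^2
  dy <- 0.1 * tt - 0.001 * tt^2
  trk <- anchor_track(data.frame(file = files, x = 25 + dx, y = 25 + dy), ser)
  sp <- build_drift_model(trk, 61, "cubic_spline")
  po <- build_drift_model(trk, 61, "polynomial", poly_degree = 3)
  expect_lt(max(abs(sp$deviations$dx - po$deviations$dx)), 1)
  expect_lt(max(abs(sp$deviations$dy - po$deviations$dy)), 1)
})

test_that("correction translates by the negated rounded deviation", {
  # feature at (60, 55); fitted deviation (10, 5) -> corrected (50, 50)
  z <- matrix(0, 80, 80)
  z[55, 60] <- 7  # [row=y, col=x]
  img <- scan_image(z)
  img$metadata$file <- "frame_0000.xyz"
  img2 <- img
  img2$metadata$file <- "frame_0001.xyz"
  ser <- image_series(list(img, img2))
  trk <- anchor_track(data.frame(file = c("frame_0000.xyz", "frame_0001.xyz"),
                                 x = c(50, 60), y = c(50, 55)), ser)
  mod <- build_drift_model(trk, 2, "cubic_spline")
  out <- apply_correction(ser, mod)
  # reference frame untouched
  expect_identical(out$frames[[1]]$z, img$z)
  expect_equal(out$frames[[2]]$z[50, 50], 7)
  expect_equal(sum(out$frames[[2]]$z != 0), 1L)
})

test_that("rigid translation preserves the non-zero multiset exactly", {
  set.seed(45)
  m <- matrix(0, 30, 30)
  m[10:20, 12:22] <- rnorm(121)
  shifted <- spmkit:::shift_matrix(m, -4, 6)
  expect_identical(sort(shifted[shifted != 0]), sort(m[m != 0]))
  # a shift that would lose data is caught with the minimum pad named
  img <- scan_image(m)
  img$metadata$file <- "frame_0000.xyz"
  img2 <- img
  img2$metadata$file <- "frame_0001.xyz"
  ser <- image_series(list(img, img2))
  trk <- anchor_track(data.frame(file = c("frame_0000.xyz", "frame_0001.xyz"),
                                 x = c(5, 25), y = c(5, 5)), ser)
  mod <- build_drift_model(trk, 2, "cubic_spline")
  expect_error(apply_correction(ser, mod), "re-expand with pad")
})

test_that("drift is recovered on a programmed synthetic trajectory", {
  sp <- clean_spec(seed = 46, rows = 64, cols = 64)
  dsp <- drift_spec(n_frames = 30, seed = 46)
  gen <- make_drift_series(sp, dsp, pad = 16)
  trk <- anchor_track(gen$track$entries[seq(1, 30, by = 5), ], gen$series)
  mod <- build_drift_model(trk, 30, "cubic_spline")
  corr <- apply_correction(gen$series, mod)
  # true centre after correction stays put within a pixel
  pos_x <- gen$track$entries$x - round(mod$deviations$dx)
  pos_y <- gen$track$entries$y - round(mod$deviations$dy)
  expect_lte(stats::sd(pos_x), 1)
  expect_lte(stats::sd(pos_y), 1)
  # multiset preservation frame by frame
  for (i in c(5, 20)) {
    a <- gen$series$frames[[i]]$z
    b <- corr$frames[[i]]$z
    expect_identical(sort(b[b != 0]), sort(a[a != 0]))
  }
  # re-correcting with a model rebuilt from the corrected anchors is identity
  corr_entries <- gen$track$entries
  corr_entries$x <- corr_entries$x - round(mod$deviations$dx)
  corr_entries$y <- corr_entries$y - round(mod$deviations$dy)
  trk2 <- anchor_track(corr_entries[seq(1, 30, by = 5), ], corr)
  mod2 <- build_drift_model(trk2, 30, "cubic_spline")
  corr2 <- apply_correction(corr, mod2)
  expect_equal(max(abs(round(mod2$deviations$dx))), 0)
  expect_identical(corr2$frames[[15]]$z, corr$frames[[15]]$z)
})

test_that("the end-to-end wrapper picks a sufficient pad", {
  sp <- clean_spec(seed = 47, rows = 48, cols = 48)
  dsp <- drift_spec(n_frames = 12,
                    trajectory = function(t) c(0.5 * t, 0.25 * t), seed = 47)
  gen <- make_drift_series(sp, dsp, pad = 8)
  # anchors in the unexpanded frame
  ent <- gen$track$entries
  ent$x <- ent$x - 8
  ent$y <- ent$y - 8
  base <- image_series(lapply(gen$series$frames, function(f) {
    img <- scan_image(f$z[9:56, 9:56])
    img$metadata$file <- f$metadata$file
    img
  }), gen$series$indices)
  out <- drift_correct_series(base, anchor_track(ent[c(1, 6, 12), ], base))
  expect_s3_class(out$series, "image_series")
  expect_gte(out$pad, ceiling(1.5 * max(abs(ent$x - ent$x[1]))) - 1)
})
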