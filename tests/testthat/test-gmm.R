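test_that("two well-separated groups are recovered almost exactly", {
  set.seed(2)
  z <- c(rnorm(500, 0, 0.01), rnorm(500, 10, 0.01))
  fit <- fit_gmm(z, 2, seed = 1)
  expect_equal(fit$means, c(0, 10), tolerance = 0.01)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.01)
  expect_true(all(diff(fit$means) > 0))
})

test_that("k = 1 reduces to the sample mean and biased variance", {
  set.seed(3)
  z <- rnorm(400, 5, 2)
  fit <- fit_gmm(z, 1, seed = 0)
  expect_equal(fit$means, mean(z), tolerance = 1e-9)
  expect_equal(fit$variances, mean((z - mean(z))^2), tolerance = 1e-8)
  expect_identical(fit$weights, 1)
  expect_true(all(fit$labels == 1L))
})

test_that("mixture parameters are recovered from generated ground truth", {
  set.seed(4)
  z <- c(rnorm(6000, 0, 5), rnorm(3600, 25, 5), rnorm(2400, 45, 5))
  fit <- fit_gmm(z, 3, seed = 4)
  expect_equal(fit$means, c(0, 25, 45), tolerance = 1.5)
  expect_equal(fit$weights, c(0.5, 0.3, 0.2), tolerance = 0.02)
})

test_that("fit invariants hold: sorted means, unit weights, full labelling", {
  set.seed(5)
  z <- c(rnorm(900, 0, 2), rnorm(600, 12, 2), rnorm(500, 30, 3))
  for (k in 1:4) {
    fit <- fit_gmm(z, k, seed = 5)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_true(all(diff(fit$means) >= 0))
    expect_equal(sum(tabulate(fit$labels, k)), length(z))
    expect_true(all(fit$variances > 0))
  }
})

test_that("labels follow the arg-max posterior rule", {
  set.seed(6)
  z <- c(rnorm(500, 0, 2), rnorm(500, 9, 2))
  fit <- fit_gmm(z, 2, seed = 6)
  # brute-force posterior per point from the reported parameters
  post <- sapply(1:2, function(j)
    fit$weights[j] * dnorm(z, fit$means[j], sqrt(fit$variances[j])))
  expect_identical(as.vector(fit$labels), max.col(post, ties.method = "first"))
})

test_that("a fixed seed reproduces the fit bit for bit", {
  set.seed(7)
  z <- c(rnorm(800, 0, 3), rnorm(800, 15, 3))
  expect_identical(fit_gmm(z, 2, seed = 11), fit_gmm(z, 2, seed = 11))
})

test_that("invalid inputs are rejected", {
  expect_error(fit_gmm(c(1, 2, 3), 5, seed = 0), "exceeds the number")
  expect_error(fit_gmm(c(1, NA, 3), 1, seed = 0), "non-finite")
})

test_that("the component sweep covers 2..k_max with non-decreasing fit", {
  set.seed(8)
  z <- c(rnorm(2000, 0, 4), rnorm(1200, 25, 4), rnorm(800, 45, 4))
  fits <- gmm_sweep(z, 4, seed = 8)
  expect_named(fits, c("k2", "k3", "k4"))
  ll <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  expect_true(all(diff(ll) >= -1e-3 * abs(ll[-length(ll)])))
  for (f in fits) {
    expect_equal(sum(f$weights), 1, tolerance = 1e-9)
    expect_true(all(diff(f$means) >= 0))
  }
  expect_error(gmm_sweep(z, 1, seed = 0), "k_max")
})

test_that("fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(9)
  z <- c(rnorm(3000, 0, 5), rnorm(2000, 25, 5), rnorm(1000, 45, 5))
  fit <- fit_gmm(z, 3, seed = 9)
  ref <- mclust::Mclust(z, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means, as.vector(sort(ref$parameters$mean)),
               tolerance = 0.2)
  expect_equal(fit$weights,
               ref$parameters$pro[order(ref$parameters$mean)],
               tolerance = 0.01)
})

test_that("cluster heights reference every cluster to the lowest", {
  fake <- structure(list(n_clusters = 3L, means = c(10, 35, 55),
                         variances = c(1, 1, 1), weights = c(.4, .4, .2),
                         labels = c(1L, 2L, 3L)), class = "spm_gmm")
  expect_equal(cluster_heights(fake), c(25, 45))
  fake$means <- c(5, 5, 5)
  expect_equal(cluster_heights(fake), c(0, 0))
  fake$n_clusters <- 1L
  expect_identical(cluster_heights(fake), numeric(0))
})

test_that("pixel fractions match brute-force counting and sum to 1", {
  set.seed(10)
  for (i in 1:5) {
    k <- sample(2:5, 1)
    labs <- matrix(sample.int(k, 100, replace = TRUE), 10, 10)
    fake <- structure(list(n_clusters = k, labels = labs), class = "spm_gmm")
    fr <- pixel_fractions(fake)
    expect_equal(fr, vapply(1:k, function(j) sum(labs == j), 0) / 100)
    expect_equal(sum(fr), 1)
  }
})

test_that("an image input yields a label grid aligned with the pixels", {
  sp <- clean_spec(seed = 12, rows = 48, cols = 48)
  img <- make_monolayer_image(sp)$image
  fit <- fit_gmm(img, 3, seed = 0)
  expect_identical(dim(fit$labels), dim(img$z))
  # pixels labelled highest cluster sit higher on average than lowest
  expect_gt(mean(img$z[fit$labels == 3]), mean(img$z[fit$labels == 1]))
})

test_that("series segmentation produces the cumulative table and images", {
  sp <- clean_spec(seed = 13, rows = 48, cols = 48)
  dsp <- drift_spec(n_frames = 5, trajectory = function(t) c(0, 0), seed = 13)
  ser <- make_drift_series(sp, dsp, pad = 0)$series
  d <- withr::local_tempdir()
  tab <- segment_series_gmm(ser, 3, seed = 0, out_dir = d)
  expect_equal(nrow(tab), 15L)
  expect_equal(unique(tab$status), "ok")
  expect_length(list.files(d, "^seg_gmm_.*png$"), 5L)
  expect_true(file.exists(file.path(d, "gmm_clusters.tsv")))
  # per-frame fractions sum to 1, heights referenced to lowest cluster
  by_frame <- split(tab, tab$image)
  for (b in by_frame) {
    expect_equal(sum(b$pixel_fraction), 1)
    expect_equal(b$height, b$mean - b$mean[1])
  }
})
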