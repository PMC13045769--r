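#' Fit a univariate Gaussian mixture to Z values
#'
#' Segments the Z-value distribution of an image by expectation-
#' maximisation of a k-component univariate Gaussian mixture. The height
#' distribution of an ordered molecular monolayer is multi-modal — one mode
#' per molecular region (substrate/ligand background, dark molecules,
#' bright molecules) — and each mixture component captures one such region.
#'
#' Initialisation is k-means++-style seeding driven by `seed`, so a fixed
#' seed gives bit-identical results on identical input. EM stops when the
#' relative log-likelihood change drops below `tol` or after `max_iter`
#' iterations; component variances are floored at 1e-12 to prevent
#' collapse. Components are reported sorted by ascending mean and each
#' point is labelled with the component of maximal posterior probability.
#'
#' @param z numeric vector of Z values (a [scan_image()] is accepted and
#'   its pixels are used).
#' @param k number of mixture components, `1 <= k <= length(z)`.
#' @param seed integer seed for the initialisation.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return An object of class `spm_gmm` with elements `n_clusters`,
#'   `means`, `variances`, `weights` (the mixture proportions, the fraction
#'   of the distribution each component accounts for), `labels` (1-based
#'   hard assignments, a matrix when the input was an image),
#'   `log_likelihood`, `n_iter`, `converged` and `seed`.
#' @examples
#' z <- c(rnorm(300, 0, 1), rnorm(300, 10, 1))
#' fit <- fit_gmm(z, k = 2, seed = 1)
#' fit$means
#' @export
fit_gmm <- function(z, k, seed = 0L, tol = 1e-6, max_iter = 500L) {
  grid_dim <- NULL
  if (inherits(z, "scan_image")) {
    grid_dim <- dim(z$z)
    z <- as.vector(z$z)
  }
  z <- as.double(z)
  if (any(!is.finite(z))) stop("non-finite Z values in input")
  n <- length(z)
  if (k < 1) stop("k must be >= 1")
  if (n < k) stop("k (", k, ") exceeds the number of data points (", n, ")")

  rng <- save_rng_state()
  on.exit(restore_rng_state(rng))
  set.seed(seed)
  mu <- kmeanspp_centres(z, k)
  lab0 <- lloyd_refine(z, mu)
  w <- numeric(k)
  v <- numeric(k)
  v_all <- max(stats::var(z) * (n - 1) / n, 1e-12)
  if (!is.finite(v_all)) v_all <- 1e-12
  for (j in seq_len(k)) {
    sel <- lab0 == j
    w[j] <- max(sum(sel) / n, 1e-6)
    if (any(sel)) {
      mu[j] <- mean(z[sel])
      v[j] <- sum((z[sel] - mu[j])^2) / sum(sel)
    }
    if (!any(sel) || v[j] <= 0) v[j] <- v_all
  }
  w <- w / sum(w)

  ll_old <- -Inf
  ll <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    lp <- log_comp_density(z, mu, v, w)
    m <- lp[, 1]
    if (k > 1) for (j in 2:k) m <- pmax(m, lp[, j])
    rs <- rowSums(exp(lp - m))
    ll <- sum(m + log(rs))
    r <- exp(lp - m) / rs
    nk <- pmax(colSums(r), 1e-10)
    w <- nk / sum(nk)
    mu <- colSums(r * z) / nk
    v <- pmax(colSums(r * outer(z, mu, "-")^2) / nk, 1e-12)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  lp <- log_comp_density(z, mu, v, w)
  labels <- max.col(lp, ties.method = "first")
  o <- order(mu)
  perm <- integer(k)
  perm[o] <- seq_len(k)
  labels <- perm[labels]
  if (!is.null(grid_dim)) labels <- matrix(labels, grid_dim[1], grid_dim[2])
  structure(list(n_clusters = as.integer(k),
                 means = mu[o], variances = v[o], weights = w[o],
                 labels = labels, log_likelihood = ll,
                 n_iter = it, converged = converged,
                 seed = as.integer(seed)),
            class = "spm_gmm")
}

log_comp_density <- function(z, mu, v, w) {
  k <- length(mu)
  lp <- matrix(0, length(z), k)
  for (j in seq_len(k))
    lp[, j] <- log(w[j]) + stats::dnorm(z, mu[j], sqrt(v[j]), log = TRUE)
  lp
}

# Lloyd iterations from the seeded centres (standard k-means refinement
# before EM); returns the converged hard assignment
lloyd_refine <- function(z, mu, max_iter = 50L) {
  k <- length(mu)
  lab <- max.col(-outer(z, mu, "-")^2, ties.method = "first")
  if (k == 1) return(lab)
  for (i in seq_len(max_iter)) {
    mu_new <- vapply(seq_len(k), function(j)
      if (any(lab == j)) mean(z[lab == j]) else mu[j], numeric(1))
    lab_new <- max.col(-outer(z, mu_new, "-")^2, ties.method = "first")
    if (identical(lab_new, lab)) break
    lab <- lab_new
    mu <- mu_new
  }
  lab
}

kmeanspp_centres <- function(z, k) {
  n <- length(z)
  mu <- numeric(k)
  mu[1] <- z[sample.int(n, 1L)]
  if (k > 1) {
    d2 <- (z - mu[1])^2
    for (j in 2:k) {
      tot <- sum(d2)
      mu[j] <- if (tot <= 0) z[sample.int(n, 1L)]
               else z[sample.int(n, 1L, prob = d2 / tot)]
      d2 <- pmin(d2, (z - mu[j])^2)
    }
  }
  mu
}

# save/restore the caller's RNG state so seeded fits do not perturb it
save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
  invisible(NULL)
}

#' @export
print.spm_gmm <- function(x, ...) {
  cat(sprintf("<spm_gmm> %d components, logLik %.4g (%s in %d iter, seed %d)\n",
              x$n_clusters, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$seed))
  print(data.frame(mean = x$means, sd = sqrt(x$variances),
                   weight = x$weights,
                   pixel_fraction = pixel_fractions(x)))
  invisible(x)
}

#' @export
summary.spm_gmm <- function(object, ...) {
  data.frame(cluster = seq_len(object$n_clusters),
             mean = object$means,
             variance = object$variances,
             weight = object$weights,
             pixel_fraction = pixel_fractions(object),
             height_vs_lowest = object$means - object$means[1])
}

#' Sweep the number of mixture components
#'
#' Fits the mixture for every k from 2 to `k_max` with the same seed
#' policy, so the user can inspect the segmented images and choose the
#' minimum component count that separates the molecular regions of
#' interest. Model choice is deliberately manual (visual inspection);
#' log-likelihoods are reported but no information criterion is applied.
#'
#' @param z numeric vector of Z values or a [scan_image()].
#' @param k_max maximum component count, `>= 2`.
#' @param seed integer seed used for every fit.
#' @param out_dir if non-`NULL` and `z` is a [scan_image()], a segmented
#'   control PNG `sweep_k<k>.png` is written per k.
#' @return A named list (`"k2"`, `"k3"`, ...) of `spm_gmm` fits.
#' @export
gmm_sweep <- function(z, k_max, seed = 0L, out_dir = NULL) {
  if (k_max < 2) stop("k_max must be >= 2")
  ks <- 2:k_max
  fits <- lapply(ks, function(k) fit_gmm(z, k, seed = seed))
  names(fits) <- paste0("k", ks)
  if (!is.null(out_dir) && inherits(z, "scan_image")) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(ks))
      write_label_png(fits[[i]]$labels, ks[i],
                      file.path(out_dir, sprintf("sweep_k%02d.png", ks[i])))
  }
  fits
}

#' Cluster height differences
#'
#' The difference between mixture means is the average height difference
#' between the segmented molecular regions: every cluster is referenced to
#' the lowest-mean cluster, so for a 3-cluster monolayer fit the two values
#' are the dark-molecule and bright-molecule heights above the background.
#'
#' @param result a `spm_gmm` fit.
#' @return Numeric vector of `K - 1` height differences (`means[i] -
#'   means[1]`, i = 2..K), in the Z units of the input; empty for K = 1.
#' @export
cluster_heights <- function(result) {
  stopifnot(inherits(result, "spm_gmm"))
  if (result$n_clusters < 2) return(numeric(0))
  result$means[-1] - result$means[1]
}

#' Per-cluster pixel fractions
#'
#' Fraction of image points hard-assigned to each cluster; sums to 1
#' exactly.
#'
#' @param result a `spm_gmm` fit (or any object with 1-based `labels` and
#'   `n_clusters`).
#' @return Numeric vector of K fractions.
#' @export
pixel_fractions <- function(result) {
  labs <- as.vector(result$labels)
  tabulate(labs, result$n_clusters) / length(labs)
}

#' Segment an image series with per-frame mixture fits
#'
#' Each frame is fitted independently (no warm starting) with the same
#' `k` and `seed`, one segmented PNG is written per frame (K evenly spaced
#' grey levels, lowest cluster black, highest white) and a cumulative
#' tab-separated table collects, per (frame, cluster): image index, file
#' name, cluster id, mean, variance, weight, pixel fraction and height
#' versus the lowest cluster. A frame whose fit fails is flagged in the
#' `status` column and processing continues.
#'
#' @param series an [image_series()] (already filtered upstream).
#' @param k number of mixture components.
#' @param seed integer seed reused for every frame.
#' @param out_dir if non-`NULL`, per-frame PNGs `seg_gmm_<index>.png` and
#'   the table `gmm_clusters.tsv` are written there.
#' @return The cumulative table as a data.frame.
#' @export
segment_series_gmm <- function(series, k, seed = 0L, out_dir = NULL) {
  stopifnot(inherits(series, "image_series"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- series_file_names(series)
  rows <- vector("list", length(series$frames))
  for (i in seq_along(series$frames)) {
    idx <- series$indices[i]
    fit <- tryCatch(fit_gmm(series$frames[[i]], k, seed = seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      message("frame ", idx, ": fit failed (", conditionMessage(fit), ")")
      rows[[i]] <- data.frame(image = idx, file = files[i],
                              cluster = NA_integer_, mean = NA_real_,
                              variance = NA_real_, weight = NA_real_,
                              pixel_fraction = NA_real_, height = NA_real_,
                              status = "failed")
      next
    }
    rows[[i]] <- data.frame(image = idx, file = files[i],
                            cluster = seq_len(k),
                            mean = fit$means, variance = fit$variances,
                            weight = fit$weights,
                            pixel_fraction = pixel_fractions(fit),
                            height = fit$means - fit$means[1],
                            status = "ok")
    if (!is.null(out_dir))
      write_label_png(fit$labels, k,
                      file.path(out_dir, sprintf("seg_gmm_%04d.png", idx)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out_dir))
    utils::write.table(tab, file.path(out_dir, "gmm_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
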