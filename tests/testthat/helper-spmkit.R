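# shared fixtures built in code

zero_bg <- list(a = c(0, 0), b = c(0, 0), c = c(0, 0))

random_image <- function(nr = 16, nc = 16, seed = 1) {
  set.seed(seed)
  scan_image(matrix(rnorm(nr * nc, sd = 10), nr, nc))
}

# clean monolayer spec: no line background, no outliers unless asked
clean_spec <- function(seed = 1, ...) {
  monolayer_spec(seed = seed, line_background = zero_bg,
                 outlier_fraction = 0, ...)
}

# independent percentile oracle: linear interpolation between order
# statistics, written from the definition (not via quantile())
sorted_percentile <- function(z, p) {
  s <- sort(z)
  h <- (length(s) - 1) * p / 100
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# independent per-row quadratic fit via the normal equations (3x3 solve)
normal_eq_residual <- function(x, zrow) {
  X <- cbind(1, x, x^2)
  beta <- solve(crossprod(X), crossprod(X, zrow))
  zrow - as.vector(X %*% beta)
}
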