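# Independent oracles used to cross-check the package's estimators.
# These are deliberately written by a different route than the implementation
# (explicit normal equations / direct prefix scans), never by calling it.

# OLS via explicit normal equations: X is the design matrix (with intercept
# column), returns coefficients, their standard errors and R^2.
ols_oracle <- function(X, y) {
  X <- as.matrix(X)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(
    coef = unname(drop(beta)),
    se = unname(sqrt(diag(xtx_inv) * sigma2)),
    r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2),
    sigma = sqrt(sigma2)
  )
}

line_oracle <- function(x, y) ols_oracle(cbind(1, x), y)

# Magnus evaluation coded independently: saturation pressure in hPa directly.
magnus_oracle_hpa <- function(ta, rh) {
  es_hpa <- 6.108 * exp((17.2694 * ta) / (ta + 237.3))
  es_hpa * (100 - rh) / 100
}

# O(n^2) running maximum: max over every prefix, recomputed from scratch.
prefix_max_oracle <- function(d) {
  vapply(seq_along(d), function(i) max(d[seq_len(i)]), numeric(1))
}

# Small scenario for unit tests where the property under test does not depend
# on the full study scale.
quick_config <- function(seed = 11, n_sprouts = 2, ...) {
  scenario_config(seed = seed, n_sprouts = n_sprouts, ...)
}

hourly_series <- function(diameters, start = "2016-06-01", tz = "UTC") {
  tibble::tibble(
    timestamp = as.POSIXct(start, tz = tz) + 3600 * (seq_along(diameters) - 1),
    diameter_um = diameters
  )
}
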