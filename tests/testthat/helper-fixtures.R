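# shared fixtures: a coarse basis set reused across tests (calibration is
# deterministic, so building it once is safe)
test_basis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_basis_set(calibrate_infant_hrf(dt = 0.1))
    cache
  }
})

# independent 3-point Pearson oracle: the textbook sum formula, no cor()
pearson3_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# independent OLS oracle via the SVD pseudo-inverse
ols_pinv_oracle <- function(X, y) {
  s <- svd(X)
  s$v %*% ((1 / s$d) * crossprod(s$u, y))
}

# naive direct discrete convolution (double loop semantics), sampled at
# volume times; mirrors the documented design-matrix construction
naive_task_columns <- function(protocol, basis, n_volumes, tr) {
  dt <- basis$dt
  grid <- seq(0, n_volumes * tr + max(basis$time), by = dt)
  u <- numeric(length(grid))
  for (j in seq_len(protocol$n_stimuli)) {
    on <- protocol$onsets[j]
    off <- on + max(protocol$durations[j], dt)
    u[grid >= on & grid < off] <- 1
  }
  vol_idx <- round((seq_len(n_volumes) - 1) * tr / dt) + 1L
  sapply(seq_len(ncol(basis$functions)), function(b) {
    k <- basis$functions[, b]
    x <- numeric(length(grid))
    for (i in seq_along(grid)) {
      jmax <- min(i, length(k))
      x[i] <- sum(u[i - seq_len(jmax) + 1L] * k[seq_len(jmax)]) * dt
    }
    x[vol_idx]
  })
}

# quick raw series set for one infant record
record_series_set <- function(rec, tr = 2.5) roi_series_set(rec$roi_series, tr)

# light-weight DPMS psFC for one record (preprocess + windows + network mean)
record_dpms_psfc <- function(rec, config, network = config$networks$DPMS) {
  prep <- preprocess_series(roi_series_set(rec$roi_series, config$tr))
  network_mean_psfc(
    build_connectivity_matrix(extract_prestim_windows(prep, rec$protocol)),
    network)
}
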