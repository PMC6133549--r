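# assemble an roi_series_set directly from a volumes x ROI matrix
make_set <- function(m, tr = 2.5) {
  if (is.null(colnames(m))) colnames(m) <- paste0("R", seq_len(ncol(m)))
  roi_series_set(m, tr)
}

test_that("pre-stimulus windows are the three volumes before the stimulus", {
  set.seed(1)
  m <- matrix(rnorm(100 * 2), 100, 2)
  s <- make_set(m)

  w1 <- extract_prestim_windows(s, stimulus_protocol(60), n_prestim = 3)
  expect_equal(w1$volumes[1, ], c(21L, 22L, 23L))   # 0-based
  expect_equal(w1$lags[1], 60 - 21 * 2.5)           # 7.5 s
  expect_equal(unname(w1$segments[, 1, 1]), m[22:24, 1])

  w2 <- extract_prestim_windows(s, stimulus_protocol(62.4), n_prestim = 3)
  expect_equal(w2$volumes[1, ], c(21L, 22L, 23L))
  expect_equal(w2$lags[1], 62.4 - 21 * 2.5)         # 9.9 s
  expect_true(w2$lags[1] >= 7.5 && w2$lags[1] < 10)

  expect_error(extract_prestim_windows(s, stimulus_protocol(5)),
               "stimulus 1")
  expect_error(extract_prestim_windows(s, stimulus_protocol(2000)),
               "beyond")
})

test_that("a full 10-stimulus session yields 10 windows of 3 samples per ROI", {
  cfg <- cohort_config(seed = 31)
  rec <- generate_cohort(cfg, basis = test_basis())[[1]]
  prep <- preprocess_series(roi_series_set(rec$roi_series, cfg$tr))
  w <- extract_prestim_windows(prep, rec$protocol)
  expect_equal(dim(w$segments), c(3L, 15L, 10L))
  expect_true(all(w$lags >= 7.5 & w$lags < 10))
})

test_that("pairwise pre-stimulus correlations follow the Pearson definition", {
  # perfect linear dependence on three points
  seg <- array(0, dim = c(3, 3, 4),
               dimnames = list(NULL, c("A", "B", "C"), NULL))
  for (j in 1:4) {
    seg[, "A", j] <- c(1, 2, 3)
    seg[, "B", j] <- c(2, 4, 6)
    seg[, "C", j] <- c(3, 2, 1)
  }
  w <- structure(list(segments = seg, tr = 2.5,
                      roi_labels = c("A", "B", "C"), n_stimuli = 4L,
                      n_prestim = 3L),
                 class = "prestim_windows")
  expect_equal(as.numeric(pairwise_prestim_correlation(w, "A", "A")), 1)
  expect_equal(as.numeric(pairwise_prestim_correlation(w, "A", "B")), 1)
  expect_equal(as.numeric(pairwise_prestim_correlation(w, "A", "C")), -1)

  # random segments: mean of per-stimulus textbook-formula correlations
  set.seed(12)
  seg2 <- array(rnorm(3 * 2 * 10), dim = c(3, 2, 10),
                dimnames = list(NULL, c("X", "Y"), NULL))
  w2 <- structure(list(segments = seg2, tr = 2.5,
                       roi_labels = c("X", "Y"), n_stimuli = 10L,
                       n_prestim = 3L),
                  class = "prestim_windows")
  oracle <- mean(vapply(1:10, function(j)
    pearson3_oracle(seg2[, 1, j], seg2[, 2, j]), numeric(1)))
  expect_equal(as.numeric(pairwise_prestim_correlation(w2, "X", "Y")),
               oracle, tolerance = 1e-12)
})

test_that("zero-variance segments are dropped from the average, not zeroed", {
  set.seed(13)
  m <- matrix(rnorm(100 * 2), 100, 2)
  m[22:24, 2] <- 5           # constant segment in the window before t=60
  s <- make_set(m)
  p <- stimulus_protocol(c(60, 90, 120), 1)
  w <- extract_prestim_windows(s, p)
  r <- pairwise_prestim_correlation(w, "R1", "R2")
  expect_equal(attr(r, "n_dropped"), 1L)
  per <- attr(r, "per_stimulus")
  expect_true(is.na(per[1]))
  expect_equal(as.numeric(r), mean(per[2:3]))
})

test_that("connectivity matrices are symmetric with unit diagonal", {
  cfg <- cohort_config(seed = 32)
  rec <- generate_cohort(cfg, basis = test_basis())[[1]]
  prep <- preprocess_series(roi_series_set(rec$roi_series, cfg$tr))
  w <- extract_prestim_windows(prep, rec$protocol)
  cm <- build_connectivity_matrix(w, networks = cfg$networks)
  expect_equal(cm$matrix, t(cm$matrix), tolerance = 1e-15)
  expect_equal(unname(diag(cm$matrix)), rep(1, 15))
  expect_true(all(abs(cm$matrix) <= 1 + 1e-12))
  expect_equal(length(unique(cm$matrix[lower.tri(cm$matrix)])), 105L)

  # two identical ROI series give an off-diagonal entry of 1
  m <- cbind(A = rnorm(100), B = 0)
  m[, "B"] <- m[, "A"]
  w2 <- extract_prestim_windows(make_set(m), stimulus_protocol(c(60, 90)))
  cm2 <- build_connectivity_matrix(w2)
  expect_equal(cm2$matrix["A", "B"], 1)
})

test_that("without shared fluctuations the mean off-diagonal psFC is near zero", {
  b <- test_basis()
  cfg <- cohort_config(n_infants = 200, shared_weight = 0, seed = 33)
  co <- generate_cohort(cfg, basis = b)
  offdiag <- vapply(co, function(rec) {
    prep <- preprocess_series(roi_series_set(rec$roi_series, cfg$tr))
    cm <- build_connectivity_matrix(extract_prestim_windows(prep, rec$protocol))
    mean(cm$matrix[lower.tri(cm$matrix)])
  }, numeric(1))
  expect_lt(abs(mean(offdiag)), 0.05)
})

test_that("network means equal the enumeration over below-diagonal pairs", {
  rois <- c("ACC", "AI", "AMY", "mFG", "PAG", "RVM")
  cmat <- matrix(0.7, 6, 6, dimnames = list(rois, rois))
  diag(cmat) <- 1
  expect_equal(network_mean_psfc(cmat, rois), 0.7)

  set.seed(14)
  v <- matrix(rnorm(36), 6, 6, dimnames = list(rois, rois))
  v <- (v + t(v)) / 2; diag(v) <- 1
  hand <- mean(v[cbind(
    c("AI", "AMY", "AMY", "mFG", "mFG", "mFG", "PAG", "PAG", "PAG", "PAG",
      "RVM", "RVM", "RVM", "RVM", "RVM"),
    c("ACC", "ACC", "AI", "ACC", "AI", "AMY", "ACC", "AI", "AMY", "mFG",
      "ACC", "AI", "AMY", "mFG", "PAG"))])
  expect_equal(network_mean_psfc(v, rois), hand, tolerance = 1e-12)

  # brainstem-excluded subset: the 6 pairs of the 4 cortical/subcortical ROIs
  red <- c("ACC", "AI", "AMY", "mFG")
  hand_red <- mean(c(v["AI", "ACC"], v["AMY", "ACC"], v["AMY", "AI"],
                     v["mFG", "ACC"], v["mFG", "AI"], v["mFG", "AMY"]))
  expect_equal(network_mean_psfc(v, red), hand_red, tolerance = 1e-12)

  expect_error(network_mean_psfc(v, "ACC"), "fewer than 2")
  expect_error(network_mean_psfc(v, c("ACC", "XXX")), "XXX")
})

test_that("per-stimulus network means average back to the pooled mean", {
  cfg <- cohort_config(seed = 34)
  rec <- generate_cohort(cfg, basis = test_basis())[[1]]
  prep <- preprocess_series(roi_series_set(rec$roi_series, cfg$tr))
  w <- extract_prestim_windows(prep, rec$protocol)
  cm <- build_connectivity_matrix(w)
  by_stim <- psfc_by_stimulus(w, cfg$networks$DPMS)
  expect_length(by_stim, 10L)
  expect_equal(mean(by_stim), network_mean_psfc(cm, cfg$networks$DPMS),
               tolerance = 1e-12)

  # identical windows across stimuli give identical per-stimulus values
  seg <- array(rep(rnorm(3 * 2), 5), dim = c(3, 2, 5),
               dimnames = list(NULL, c("A", "B"), NULL))
  w2 <- structure(list(segments = seg, tr = 2.5, roi_labels = c("A", "B"),
                       n_stimuli = 5L, n_prestim = 3L),
                  class = "prestim_windows")
  expect_equal(length(unique(psfc_by_stimulus(w2, c("A", "B")))), 1L)
})

test_that("correlations are affine-invariant and flip sign with negative scale", {
  set.seed(15)
  m <- matrix(rnorm(100 * 3), 100, 3)
  colnames(m) <- c("A", "B", "C")
  p <- stimulus_protocol(c(60, 90, 120), 1)
  base <- build_connectivity_matrix(
    extract_prestim_windows(make_set(m), p))$matrix

  m_pos <- m; m_pos[, "B"] <- 5 + 2.3 * m[, "B"]
  pos <- build_connectivity_matrix(
    extract_prestim_windows(make_set(m_pos), p))$matrix
  expect_equal(pos, base, tolerance = 1e-12)

  m_neg <- m; m_neg[, "B"] <- 5 - 2.3 * m[, "B"]
  neg <- build_connectivity_matrix(
    extract_prestim_windows(make_set(m_neg), p))$matrix
  expect_equal(neg["A", "B"], -base["A", "B"], tolerance = 1e-12)
  expect_equal(neg["B", "C"], -base["B", "C"], tolerance = 1e-12)
  expect_equal(neg["A", "C"], base["A", "C"], tolerance = 1e-12)
})

test_that("recovered DPMS psFC increases with the shared-fluctuation weight", {
  b <- test_basis()
  levels <- c(0.3, 0.65, 1.0)
  means <- vapply(levels, function(w) {
    vals <- numeric(0)
    for (s in 1:150) {
      cfg <- cohort_config(n_infants = 1, shared_weight = w, seed = 40000 + s)
      rec <- generate_cohort(cfg, basis = b)[[1]]
      vals <- c(vals, record_dpms_psfc(rec, cfg))
    }
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
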