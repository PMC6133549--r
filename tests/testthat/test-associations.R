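test_that("a deterministic linear relation is recovered exactly", {
  set.seed(30)
  psfc <- runif(13, 0, 0.5)
  ga <- rnorm(13, 40, 1.2)
  ga <- ga - drop(cbind(1, psfc) %*% ols_pinv_oracle(cbind(1, psfc), ga)) + 40
  pct <- 3 - 2 * psfc                       # exact, GA orthogonal to psFC
  res <- psfc_association(pct, psfc, ga)
  expect_equal(res$beta, -2, tolerance = 1e-10)
  expect_equal(res$r, -1, tolerance = 1e-10)
  expect_equal(res$n, 13L)
  expect_equal(sign(res$beta), sign(res$r))
})

test_that("residual and partial age adjustment agree when GA is orthogonal", {
  set.seed(31)
  psfc <- runif(13)
  ga <- rnorm(13)
  ga <- resid(lm(ga ~ psfc)) + 40           # orthogonalise GA to psFC
  pct <- 2 - 1.5 * psfc + rnorm(13, 0, 0.2)
  r1 <- psfc_association(pct, psfc, ga, method = "residual")$r
  r2 <- psfc_association(pct, psfc, ga, method = "partial")$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("degenerate association inputs are rejected", {
  expect_error(psfc_association(1:3, 1:3, 1:3), "at least 4")
  expect_error(psfc_association(rnorm(6), rep(0.2, 6), rnorm(6)), "constant")
  expect_error(psfc_association(c(1, NA, 3, 4, 5), rnorm(5), rnorm(5)),
               "missing")
})

test_that("the psFC slope test keeps its nominal type-I error", {
  set.seed(32)
  n_rej <- 0L
  for (i in 1:1000) {
    pct <- rnorm(13)
    psfc <- runif(13)
    ga <- runif(13, 38, 43)
    if (psfc_association(pct, psfc, ga)$p < 0.05) n_rej <- n_rej + 1L
  }
  expect_gt(n_rej / 1000, 0.035)
  expect_lt(n_rej / 1000, 0.065)
})

test_that("edgewise models count edges and collapse to the network model", {
  set.seed(33)
  psfc <- runif(13, 0, 0.5)
  ga <- runif(13, 38, 43)
  pct <- 2 - 1.5 * psfc + rnorm(13, 0, 0.1)
  edges <- matrix(rep(psfc, 15), ncol = 15)
  colnames(edges) <- paste0("e", 1:15)
  res <- edgewise_association(edges, pct, ga)
  expect_equal(nrow(res), 15L)
  net <- psfc_association(pct, psfc, ga)
  expect_true(all(abs(res$beta - net$beta) < 1e-10))
  expect_equal(res$p_bonferroni, pmin(1, res$p * 15))

  # a 6-node network yields exactly 15 edge columns
  cfg <- cohort_config(seed = 34)
  co <- generate_cohort(cfg, basis = test_basis())
  meas <- analyze_cohort(co, basis = test_basis())
  et <- network_edge_table(meas$cms, cfg$networks$DPMS)
  expect_equal(ncol(et), 15L)
  expect_equal(nrow(et), 13L)
})

test_that("when only ACC-PAG carries coupling that edge dominates", {
  b <- test_basis()
  hits <- 0L
  n_cohorts <- 250L
  # the activity mask is placed outside the DPMS so that evoked-response
  # tails cannot leak amplitude-dependent signal into the tested edges,
  # and the cohort is enlarged: with 13 infants the largest-|beta| rank is
  # dominated by sampling noise of the low-variance null edges
  for (s in seq_len(n_cohorts)) {
    cfg <- cohort_config(n_infants = 40,
                         dpms_coupled_rois = c("ACC", "PAG"),
                         active_rois = c("SMA", "PCC"),
                         seed = 50000 + s)
    co <- generate_cohort(cfg, basis = b)
    meas <- analyze_cohort(co, basis = b)
    et <- network_edge_table(meas$cms, cfg$networks$DPMS)
    res <- edgewise_association(et, meas$table$percent_change,
                                meas$table$ga_weeks)
    if (res$edge[which.max(abs(res$beta))] == "ACC-PAG") hits <- hits + 1L
  }
  expect_gte(hits / n_cohorts, 0.90)
})

test_that("network RM-ANOVA matches the paired t-test with two levels", {
  set.seed(35)
  tbl <- cbind(DPMS = rnorm(13, 0.1, 0.1), Control = rnorm(13, 0.15, 0.1))
  res <- compare_network_connectivity(tbl)
  tt <- t.test(tbl[, 1], tbl[, 2], paired = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
})

test_that("identical network columns give F = 0, p = 1", {
  v <- rnorm(13)
  res <- compare_network_connectivity(cbind(A = v, B = v, C = v))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_equal(unname(res$tukey), rep(1, 3))
  expect_length(res$tukey, 3L)   # levels * (levels - 1) / 2
})

test_that("network RM-ANOVA keeps its nominal size under exchangeability", {
  set.seed(36)
  n_rej <- 0L
  for (i in 1:1000) {
    subj <- rnorm(13, 0, 0.1)
    tbl <- sapply(1:3, function(k) 0.1 + subj + rnorm(13, 0, 0.08))
    colnames(tbl) <- c("DPMS", "Control", "DMN")
    if (compare_network_connectivity(tbl)$p < 0.05) n_rej <- n_rej + 1L
  }
  expect_gt(n_rej / 1000, 0.035)
  expect_lt(n_rej / 1000, 0.065)
})

test_that("incomplete tables and single infants are rejected", {
  tbl <- cbind(A = c(1, 2, NA, 4), B = 1:4)
  expect_error(compare_network_connectivity(tbl), "missing cells")
  expect_error(stimulus_stability(matrix(rnorm(10), 1, 10)),
               "at least 2 infants")
})

test_that("stimulus-number stability is calibrated under stationarity", {
  b <- test_basis()
  pvals <- vapply(1:250, function(s) {
    cfg <- cohort_config(n_infants = 6, seed = 60000 + s)
    co <- generate_cohort(cfg, basis = b)
    per <- t(vapply(co, function(rec) {
      prep <- preprocess_series(roi_series_set(rec$roi_series, cfg$tr))
      psfc_by_stimulus(extract_prestim_windows(prep, rec$protocol),
                       cfg$networks$DPMS)
    }, numeric(10)))
    stimulus_stability(per)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # an injected monotone drift of half the within-infant SD per stimulus
  # step is detected with high power
  set.seed(37)
  n_rej <- 0L
  for (i in 1:100) {
    cfg <- cohort_config(n_infants = 6, seed = 70000 + i)
    co <- generate_cohort(cfg, basis = b)
    per <- t(vapply(co, function(rec) {
      prep <- preprocess_series(roi_series_set(rec$roi_series, cfg$tr))
      psfc_by_stimulus(extract_prestim_windows(prep, rec$protocol),
                       cfg$networks$DPMS)
    }, numeric(10)))
    sd_w <- mean(apply(per, 1, sd))
    drifted <- per + outer(rep(1, nrow(per)), seq_len(10)) * sd_w / 2
    if (stimulus_stability(drifted)$p < 0.05) n_rej <- n_rej + 1L
  }
  expect_gt(n_rej / 100, 0.80)
})

test_that("brainstem exclusion uses the six cortical/subcortical edges", {
  cfg <- cohort_config(seed = 38)
  co <- generate_cohort(cfg, basis = test_basis())
  meas <- analyze_cohort(co, basis = test_basis())
  sens <- sensitivity_excluding_brainstem(meas$cms,
                                          meas$table$percent_change,
                                          meas$table$ga_weeks,
                                          cfg$networks)
  expect_equal(attr(sens$DPMS, "rois"), c("ACC", "AI", "AMY", "mFG"))
  expect_equal(choose(length(attr(sens$DPMS, "rois")), 2), 6)
  hand <- vapply(meas$cms, network_mean_psfc, 0,
                 network = c("ACC", "AI", "AMY", "mFG"))
  expect_equal(unname(attr(sens$DPMS, "psfc")), unname(hand))
  expect_equal(attr(sens$Control, "rois"),
               c("CAL", "CAU", "HIP", "RGY", "SMA"))
})

test_that("brainstem exclusion preserves the association when brainstem
           edges carry no coupling, and attenuates it when only they do", {
  b <- test_basis()
  # activity mask outside the DPMS (no evoked-tail leakage into the tested
  # edges); large cohorts keep the sampled correlations close to their
  # population values
  cfg1 <- cohort_config(n_infants = 300,
                        dpms_coupled_rois = c("ACC", "AI", "AMY", "mFG"),
                        active_rois = c("SMA", "PCC"), seed = 39)
  meas1 <- analyze_cohort(generate_cohort(cfg1, basis = b), basis = b)
  full1 <- psfc_association(meas1$table$percent_change,
                            meas1$table$psfc_DPMS, meas1$table$ga_weeks)
  sens1 <- sensitivity_excluding_brainstem(meas1$cms,
                                           meas1$table$percent_change,
                                           meas1$table$ga_weeks,
                                           cfg1$networks)
  # cortical-only coupling: the association survives brainstem exclusion
  # (and sharpens slightly, as the uninformative edges are dropped)
  expect_lt(full1$r, -0.5)
  expect_lt(sens1$DPMS$r, -0.5)
  expect_lt(sens1$DPMS$p, 0.01)
  expect_lt(abs(sens1$DPMS$r - full1$r), 0.25)

  # brainstem-only coupling: excluding PAG/RVM removes the signal
  cfg2 <- cohort_config(n_infants = 300,
                        dpms_coupled_rois = c("PAG", "RVM"),
                        active_rois = c("SMA", "PCC"), seed = 40)
  meas2 <- analyze_cohort(generate_cohort(cfg2, basis = b), basis = b)
  full2 <- psfc_association(meas2$table$percent_change,
                            meas2$table$psfc_DPMS, meas2$table$ga_weeks)
  sens2 <- sensitivity_excluding_brainstem(meas2$cms,
                                           meas2$table$percent_change,
                                           meas2$table$ga_weeks,
                                           cfg2$networks)
  expect_lt(full2$p, 0.01)
  expect_lt(abs(sens2$DPMS$r), abs(full2$r))
  expect_lt(abs(sens2$DPMS$r), 0.2)
})
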