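#' Detect motion-outlier volumes via DVARS
#'
#' DVARS at volume `t` is the root-mean-square over units (voxels or ROIs)
#' of the volume-to-volume intensity difference — the rate of change of
#' the signal between volumes.  Volumes whose DVARS exceeds the boxplot
#' upper fence (75th percentile + 1.5 * IQR of the DVARS series) are
#' flagged; an absolute threshold can be supplied instead.
#'
#' @param series_matrix Numeric matrix, volumes x units.
#' @param absolute Optional absolute DVARS threshold overriding the
#'   boxplot fence.
#' @return Integer vector of flagged volume indices (1-based; the later
#'   volume of each high-difference pair), with attribute `dvars` (length
#'   `n_volumes`, zero for the first volume).
#' @export
detect_motion_outliers <- function(series_matrix, absolute = NULL) {
  m <- as.matrix(series_matrix)
  if (nrow(m) < 2) stop("DVARS needs at least 2 volumes")
  d <- diff(m)
  dvars <- c(0, sqrt(rowMeans(d^2)))
  thr <- if (!is.null(absolute)) absolute else {
    q <- stats::quantile(dvars[-1], c(0.25, 0.75), names = FALSE)
    q[2] + 1.5 * (q[2] - q[1])
  }
  out <- which(dvars > thr)
  structure(as.integer(out), dvars = dvars, threshold = thr)
}

#' Fit an ordinary least-squares GLM to one series
#'
#' Time-series general linear model: the series is regressed on an
#' intercept plus the design-matrix columns.  The first task regressor's
#' coefficient (the canonical-basis contrast of parameter estimates) is
#' the evoked-amplitude estimate; its t statistic and two-sided p-value
#' are reported.
#'
#' @param series Numeric vector.
#' @param design A `design_matrix` whose row count matches the series.
#' @return An object of class `glm_fit`: list with `coefficients` (named,
#'   including `(Intercept)`), `se`, `canonical` (coefficient, t, p —
#'   `NA` when the design has no task columns), `sigma2`, `df_residual`,
#'   `residuals`, `fitted` and `design` (labels, task peaks).
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(design, "design_matrix"))
  y <- as.numeric(series)
  if (length(y) != nrow(design$matrix))
    stop("series length ", length(y), " does not match design rows ",
         nrow(design$matrix))
  X <- cbind(`(Intercept)` = 1, design$matrix)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design: collinear columns ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(crossprod(X))))
  names(se) <- colnames(X)

  canonical <- list(coef = NA_real_, t = NA_real_, p = NA_real_)
  if (design$n_task > 0) {
    cn <- colnames(X)[2]   # first task regressor
    tval <- beta[cn] / se[cn]
    canonical <- list(coef = unname(beta[cn]), t = unname(tval),
                      p = unname(2 * stats::pt(-abs(tval), df)))
  }
  structure(list(coefficients = beta, se = se, canonical = canonical,
                 sigma2 = sigma2, df_residual = df,
                 residuals = as.numeric(res), fitted = as.numeric(X %*% beta),
                 design = list(labels = design$labels,
                               task_peaks = design$task_peaks,
                               n_task = design$n_task)),
            class = "glm_fit")
}

#' Percent BOLD change from a GLM fit
#'
#' Converts the canonical-regressor coefficient into percent signal
#' change using the regressor-peak convention: `100 * coef * peak(x) /
#' baseline`, where `peak(x)` is the maximum of the canonical task
#' regressor and `baseline` the mean raw signal.  The convention is
#' recorded so alternative scalings remain comparable.  Scale-invariant:
#' multiplying the raw signal by a positive constant leaves the result
#' unchanged.
#'
#' @param fit A `glm_fit`.
#' @param baseline Mean raw signal of the unit (must be positive).
#' @return List of class `percent_change`: `percent`, `convention`,
#'   `baseline`.
#' @export
percent_bold_change <- function(fit, baseline) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be positive, got ", baseline)
  if (fit$design$n_task == 0)
    stop("fit has no task regressors")
  pct <- 100 * fit$canonical$coef * fit$design$task_peaks[1] / baseline
  structure(list(percent = unname(pct),
                 convention = "coef * canonical regressor peak / mean signal * 100",
                 baseline = baseline),
            class = "percent_change")
}

#' Quantify the noxious-evoked response of one infant
#'
#' Full evoked-response path for a session: DVARS motion-outlier
#' detection on the raw ROI series, design construction (three-function
#' infant basis + outlier indicator columns), per-ROI GLM within the
#' activity mask, and percent BOLD change averaged across the mask ROIs.
#'
#' @param set An `roi_series_set` of raw (unfiltered, un-demeaned) series.
#' @param protocol A `stimulus_protocol`.
#' @param basis A `basis_set`.
#' @param active_rois ROI labels of the activity mask.
#' @param detect_outliers Run DVARS detection and include indicator
#'   columns.
#' @param highpass_hz Optional high-pass cutoff applied before the GLM
#'   (baseline is taken from the raw series).
#' @return List with `percent_change` (scalar, mean over mask ROIs),
#'   `per_roi` (data frame: roi, coef, t, p, percent), `outliers`.
#' @export
quantify_evoked <- function(set, protocol, basis, active_rois,
                            detect_outliers = TRUE, highpass_hz = NULL) {
  stopifnot(inherits(set, "roi_series_set"))
  if (!all(active_rois %in% colnames(set$series)))
    stop("active_rois not all present in the series set")
  outliers <- if (detect_outliers) detect_motion_outliers(set$series)
              else integer(0)
  dm <- build_design_matrix(protocol, basis, nrow(set$series), set$tr,
                            outliers = outliers)
  baselines <- colMeans(set$series)
  work <- if (!is.null(highpass_hz))
    preprocess_series(set, highpass_hz = highpass_hz, demean = FALSE)
  else set
  per <- lapply(active_rois, function(r) {
    fit <- fit_glm(work$series[, r], dm)
    pc <- percent_bold_change(fit, baselines[[r]])
    data.frame(roi = r, coef = fit$canonical$coef, t = fit$canonical$t,
               p = fit$canonical$p, percent = pc$percent)
  })
  per <- do.call(rbind, per)
  list(percent_change = mean(per$percent), per_roi = per,
       outliers = as.integer(outliers))
}
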