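#' Extract pre-stimulus windows
#'
#' For every stimulus, identifies the volume in which it occurred (a
#' stimulus at time `t` belongs to volume `floor(t / TR)`, 0-based) and
#' selects the three volumes immediately prior.  At TR 2.5 s the window
#' spans 7.5 s of acquisition; because the stimulus can fall anywhere
#' within its volume, the window start precedes the stimulus by between
#' 7.5 and 10 s.
#'
#' @param set An `roi_series_set` (demeaned full-length series).
#' @param protocol A `stimulus_protocol`.
#' @param n_prestim Number of pre-stimulus volumes per window.
#' @return An object of class `prestim_windows`: list with `segments` (3D
#'   array, `n_prestim` x ROI x stimulus), `volumes` (0-based window
#'   volume indices, matrix stimulus x `n_prestim`), `lags` (seconds from
#'   window start to stimulus onset), `tr`, `roi_labels`, `n_stimuli`.
#' @export
extract_prestim_windows <- function(set, protocol, n_prestim = 3) {
  stopifnot(inherits(set, "roi_series_set"),
            inherits(protocol, "stimulus_protocol"), n_prestim >= 2)
  tr <- set$tr
  n_vol <- nrow(set$series)
  rois <- colnames(set$series)
  n_stim <- protocol$n_stimuli

  seg <- array(NA_real_, dim = c(n_prestim, length(rois), n_stim),
               dimnames = list(NULL, rois, NULL))
  vols <- matrix(NA_integer_, n_stim, n_prestim)
  lags <- numeric(n_stim)
  for (j in seq_len(n_stim)) {
    k0 <- floor(protocol$onsets[j] / tr)   # 0-based stimulus volume
    if (k0 < n_prestim)
      stop("stimulus ", j, " (onset ", protocol$onsets[j],
           " s) has fewer than ", n_prestim, " preceding volumes")
    if (k0 >= n_vol)
      stop("stimulus ", j, " (onset ", protocol$onsets[j],
           " s) falls beyond the acquired ", n_vol, " volumes")
    win0 <- (k0 - n_prestim):(k0 - 1L)      # 0-based
    vols[j, ] <- win0
    lags[j] <- protocol$onsets[j] - win0[1] * tr
    seg[, , j] <- set$series[win0 + 1L, , drop = FALSE]
  }
  structure(list(segments = seg, volumes = vols, lags = lags, tr = tr,
                 roi_labels = rois, n_stimuli = n_stim,
                 n_prestim = n_prestim),
            class = "prestim_windows")
}

# per-stimulus ROI x ROI correlation matrices; zero-variance segments -> NA
.per_stimulus_cor <- function(windows) {
  lapply(seq_len(windows$n_stimuli), function(j) {
    s <- windows$segments[, , j, drop = TRUE]
    sds <- apply(s, 2, stats::sd)
    r <- suppressWarnings(stats::cor(s))
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
    diag(r) <- ifelse(sds == 0, NA_real_, 1)
    r
  })
}

#' Mean pre-stimulus correlation between two ROIs
#'
#' For each stimulus, the sample Pearson correlation between the two ROIs'
#' three-point pre-stimulus segments; the per-stimulus correlations are
#' then averaged arithmetically across stimuli.  Stimuli where either
#' segment has zero variance yield an undefined correlation and are
#' dropped from the average (recorded in the `n_dropped` attribute) rather
#' than set to zero.
#'
#' @param windows A `prestim_windows` object.
#' @param roi_a,roi_b ROI labels.
#' @param fisher Average on the Fisher-z scale instead of raw r.
#' @return The mean correlation, with attributes `per_stimulus` (the
#'   per-stimulus values) and `n_dropped`.
#' @export
pairwise_prestim_correlation <- function(windows, roi_a, roi_b,
                                         fisher = FALSE) {
  stopifnot(inherits(windows, "prestim_windows"), windows$n_stimuli >= 1)
  if (!all(c(roi_a, roi_b) %in% windows$roi_labels))
    stop("unknown ROI label")
  per <- vapply(.per_stimulus_cor(windows),
                function(r) r[roi_a, roi_b], numeric(1))
  ok <- !is.na(per)
  m <- if (fisher) tanh(mean(atanh(pmin(pmax(per[ok], -1 + 1e-12),
                                        1 - 1e-12))))
       else mean(per[ok])
  structure(m, per_stimulus = per, n_dropped = sum(!ok))
}

#' Build a per-infant connectivity matrix
#'
#' Mean pre-stimulus Pearson correlation for every pair of ROIs, arranged
#' as a symmetric matrix with unit diagonal.  Per-stimulus matrices are
#' retained for the stimulus-stability analysis.
#'
#' @param windows A `prestim_windows` object.
#' @param rois ROI subset (default: all).
#' @param networks Optional named list of network -> ROI labels, stored as
#'   the membership map.
#' @param fisher Average on the Fisher-z scale.
#' @return An object of class `connectivity_matrix`: list with `matrix`,
#'   `roi_labels`, `n_stimuli`, `networks` and `per_stimulus` (list of
#'   per-stimulus correlation matrices).
#' @export
build_connectivity_matrix <- function(windows, rois = windows$roi_labels,
                                      networks = NULL, fisher = FALSE) {
  stopifnot(inherits(windows, "prestim_windows"), length(rois) >= 2)
  per <- lapply(.per_stimulus_cor(windows),
                function(r) r[rois, rois, drop = FALSE])
  stack <- simplify2array(per)
  cm <- if (fisher) {
    z <- atanh(pmin(pmax(stack, -1 + 1e-12), 1 - 1e-12))
    tanh(apply(z, c(1, 2), mean, na.rm = TRUE))
  } else apply(stack, c(1, 2), mean, na.rm = TRUE)
  diag(cm) <- 1
  structure(list(matrix = cm, roi_labels = rois,
                 n_stimuli = windows$n_stimuli,
                 networks = networks, per_stimulus = per),
            class = "connectivity_matrix")
}

#' Network mean pre-stimulus connectivity
#'
#' Arithmetic mean of the below-diagonal connectivity-matrix entries
#' restricted to a network's ROIs.  Supports reduced subsets such as the
#' DPMS without its brainstem nodes.
#'
#' @param cm A `connectivity_matrix`, or a plain symmetric matrix with ROI
#'   dimnames.
#' @param network Character vector of ROI labels (>= 2).
#' @return Scalar mean of the `n*(n-1)/2` below-diagonal entries.
#' @export
network_mean_psfc <- function(cm, network) {
  m <- if (inherits(cm, "connectivity_matrix")) cm$matrix else cm
  if (length(network) < 2)
    stop("network mean undefined for fewer than 2 ROIs")
  if (!all(network %in% rownames(m)))
    stop("unknown ROI labels: ",
         paste(setdiff(network, rownames(m)), collapse = ", "))
  sub <- m[network, network]
  mean(sub[lower.tri(sub)], na.rm = TRUE)
}

#' Per-stimulus network mean connectivity
#'
#' For each stimulus, the network mean computed from that stimulus's
#' single-window correlation matrix; input to the stimulus-number
#' stability analysis.
#'
#' @param x A `prestim_windows` or `connectivity_matrix` object.
#' @param network Character vector of ROI labels (>= 2).
#' @return Numeric vector, one network mean per stimulus.
#' @export
psfc_by_stimulus <- function(x, network) {
  per <- if (inherits(x, "prestim_windows")) .per_stimulus_cor(x)
         else if (inherits(x, "connectivity_matrix")) x$per_stimulus
         else stop("need prestim_windows or connectivity_matrix")
  vapply(per, function(r) {
    if (!all(network %in% rownames(r)))
      stop("unknown ROI labels in network")
    sub <- r[network, network]
    mean(sub[lower.tri(sub)], na.rm = TRUE)
  }, numeric(1))
}

#' Write a connectivity matrix and its long-format edge table
#'
#' @param cm A `connectivity_matrix`.
#' @param path CSV path for the matrix; the per-stimulus edge table is
#'   written to `<path base>_edges.csv` with columns
#'   `roi_a, roi_b, stimulus, r`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.csv(as.data.frame(cm$matrix), path, row.names = TRUE)
  pairs <- which(lower.tri(cm$matrix), arr.ind = TRUE)
  long <- do.call(rbind, lapply(seq_along(cm$per_stimulus), function(j)
    data.frame(roi_a = cm$roi_labels[pairs[, 2]],
               roi_b = cm$roi_labels[pairs[, 1]],
               stimulus = j,
               r = cm$per_stimulus[[j]][pairs])))
  utils::write.csv(long, sub("\\.csv$", "_edges.csv", path),
                   row.names = FALSE)
  invisible(path)
}
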