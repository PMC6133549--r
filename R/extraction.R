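#' ROI mask container
#'
#' A set of voxel indices with per-voxel weights in a named space.  Most
#' ROIs use unit weights; small brainstem ROIs (e.g. the RVM) use the
#' registration mask weights, giving a weighted mean series.
#'
#' @param label ROI label.
#' @param voxels Integer matrix, one row per voxel, columns x/y/z (1-based).
#' @param weights Per-voxel positive weights; recycled.
#' @param space Free-text space tag.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(label, voxels, weights = 1, space = "EPI") {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) == 0L) stop("ROI '", label, "' has an empty mask")
  weights <- rep_len(as.numeric(weights), nrow(voxels))
  if (any(weights <= 0)) stop("mask weights must be positive")
  structure(list(label = label, voxels = voxels, weights = weights,
                 space = space),
            class = "roi_mask")
}

#' Convert a 3D weight array to an `roi_mask`
#'
#' Non-zero array entries become mask voxels with the array values as
#' weights (the form produced by [render_volumes()] and by reading a NIfTI
#' mask).
#'
#' @param label ROI label.
#' @param arr 3D numeric array of weights.
#' @param space Space tag.
#' @return An `roi_mask`.
#' @export
mask_from_array <- function(label, arr, space = "EPI") {
  idx <- which(arr != 0, arr.ind = TRUE)
  roi_mask(label, idx, weights = arr[idx], space = space)
}

#' Read a NIfTI mask file as an `roi_mask`
#'
#' @param label ROI label.
#' @param path NIfTI file path.
#' @param space Space tag.
#' @return An `roi_mask`.
#' @export
read_mask <- function(label, path, space = "EPI") {
  mask_from_array(label, as.array(RNifti::readNifti(path)), space = space)
}

.voxel_series_matrix <- function(image, mask) {
  d <- dim(image)
  stopifnot(length(d) == 4L)
  if (any(mask$voxels < 1L) ||
      any(mask$voxels > matrix(d[1:3], nrow(mask$voxels), 3, byrow = TRUE)))
    stop("mask '", mask$label, "' extends outside the image")
  flat <- matrix(image, nrow = prod(d[1:3]), ncol = d[4])
  lin <- (mask$voxels[, 3] - 1L) * d[1] * d[2] +
    (mask$voxels[, 2] - 1L) * d[1] + mask$voxels[, 1]
  flat[lin, , drop = FALSE]
}

#' Exclude signal-dropout voxels from a mask
#'
#' Voxels whose temporal-mean intensity falls more than `threshold` below
#' the image's maximum-signal reference are removed, mirroring the
#' exclusion of voxels with more than 10% signal loss near susceptibility
#' dropout.  The reference is the `reference_quantile` (default 98th
#' percentile, a robust maximum: the literal voxelwise maximum is a single
#' noisy voxel) of temporal-mean intensity over `brain_mask` voxels, or
#' over the ROI's own voxels when no brain mask is supplied; a numeric
#' `reference` overrides it.
#'
#' @param mask An `roi_mask`.
#' @param image 4D array.
#' @param threshold Fractional signal loss that triggers exclusion.
#' @param reference Optional explicit reference intensity.
#' @param brain_mask Optional `roi_mask` (e.g. union of all ROIs) defining
#'   where the reference is computed.
#' @param reference_quantile Quantile used for the robust maximum.
#' @return The reduced `roi_mask`, with attributes `n_excluded` and
#'   `reference`.
#' @export
exclude_dropout_voxels <- function(mask, image, threshold = 0.10,
                                   reference = NULL, brain_mask = NULL,
                                   reference_quantile = 0.98) {
  stopifnot(inherits(mask, "roi_mask"), threshold >= 0, threshold < 1)
  vox_mean <- rowMeans(.voxel_series_matrix(image, mask))
  if (is.null(reference)) {
    ref_src <- if (is.null(brain_mask)) vox_mean else
      rowMeans(.voxel_series_matrix(image, brain_mask))
    reference <- stats::quantile(ref_src, reference_quantile, names = FALSE)
  }
  keep <- vox_mean >= (1 - threshold) * reference
  if (!any(keep))
    stop("ROI '", mask$label, "': all voxels excluded by the ",
         round(100 * threshold), "% signal-loss rule")
  out <- roi_mask(mask$label, mask$voxels[keep, , drop = FALSE],
                  mask$weights[keep], mask$space)
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "reference") <- reference
  out
}

#' Exclude CSF voxels from a mask
#'
#' Removes voxels labelled as cerebrospinal fluid in a tissue segmentation
#' aligned with the mask.
#'
#' @param mask An `roi_mask`.
#' @param segmentation 3D array of tissue labels.
#' @param csf_label The label value marking CSF.
#' @return The reduced `roi_mask` with attribute `n_excluded`; unchanged
#'   (with a warning) when the segmentation contains no CSF label at all.
#' @export
exclude_csf_voxels <- function(mask, segmentation, csf_label = "CSF") {
  stopifnot(inherits(mask, "roi_mask"))
  if (!any(segmentation == csf_label)) {
    warning("segmentation contains no '", csf_label,
            "' label; mask unchanged")
    attr(mask, "n_excluded") <- 0L
    return(mask)
  }
  lab <- segmentation[mask$voxels]
  keep <- lab != csf_label
  if (!any(keep))
    stop("ROI '", mask$label, "': every voxel is labelled CSF")
  out <- roi_mask(mask$label, mask$voxels[keep, , drop = FALSE],
                  mask$weights[keep], mask$space)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Extract a weighted mean ROI time series
#'
#' Per-volume weighted mean of the voxel intensities in the mask, weights
#' normalised to sum to one.
#'
#' @param image 4D array.
#' @param mask An `roi_mask`.
#' @return Numeric vector, one value per volume.
#' @export
extract_series <- function(image, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- .voxel_series_matrix(image, mask)
  w <- mask$weights / sum(mask$weights)
  as.numeric(crossprod(m, w))
}

#' ROI time-series set
#'
#' @param series Numeric matrix, volumes x ROIs, with ROI column names.
#' @param tr Repetition time, seconds.
#' @param provenance List of processing flags.
#' @return An object of class `roi_series_set`.
#' @export
roi_series_set <- function(series, tr, provenance = list()) {
  series <- as.matrix(series)
  stopifnot(tr > 0, !is.null(colnames(series)))
  structure(list(tr = tr, series = series, provenance = provenance),
            class = "roi_series_set")
}

#' Extract all ROI series from a rendered image
#'
#' Convenience wrapper: applies [exclude_dropout_voxels()] (optional) and
#' [extract_series()] to a named list of masks.
#'
#' @param image 4D array.
#' @param masks Named list of `roi_mask`s or 3D weight arrays.
#' @param tr Repetition time.
#' @param dropout_threshold Fractional signal-loss threshold; `NULL`
#'   disables dropout exclusion.
#' @return An `roi_series_set`; excluded-voxel counts are recorded in the
#'   provenance.
#' @export
extract_roi_set <- function(image, masks, tr, dropout_threshold = 0.10) {
  masks <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    if (inherits(m, "roi_mask")) m else mask_from_array(names(masks)[i], m)
  })
  names(masks) <- vapply(masks, `[[`, "", "label")
  excluded <- integer(length(masks))
  names(excluded) <- names(masks)
  if (!is.null(dropout_threshold)) {
    masks <- lapply(masks, exclude_dropout_voxels, image = image,
                    threshold = dropout_threshold)
    excluded <- vapply(masks, function(m) attr(m, "n_excluded"), 0L)
  }
  series <- vapply(masks, function(m) extract_series(image, m),
                   numeric(dim(image)[4]))
  roi_series_set(series, tr,
                 provenance = list(dropout_threshold = dropout_threshold,
                                   excluded_voxels = as.list(excluded)))
}

#' Gaussian running-line high-pass filter
#'
#' Removes slow drifts by subtracting, at each time point, the prediction
#' of a Gaussian-weighted least-squares straight-line fit centred there
#' (the convention of standard fMRI high-pass temporal filtering), then
#' adds the series mean back.  The Gaussian SD is half the cutoff period:
#' `sigma = 0.5 / cutoff_hz` seconds.
#'
#' @param y Numeric series.
#' @param tr Sampling interval, seconds.
#' @param cutoff_hz High-pass cutoff frequency, Hz.
#' @return Filtered series of the same length.
#' @export
highpass_filter <- function(y, tr, cutoff_hz = 0.01) {
  F <- .highpass_matrix(length(y), tr, cutoff_hz)
  as.numeric(F %*% y)
}

# the running-line fit is linear in y, so the whole filter is one matrix:
# filtered = (I - A + 11'/n) y, with A the local weighted-regression hat
# matrix; cached per (n, tr, cutoff) since it is reused across series
.hp_cache <- new.env(parent = emptyenv())

.highpass_matrix <- function(n, tr, cutoff_hz) {
  if (cutoff_hz >= 1 / (2 * tr))
    stop("high-pass cutoff ", cutoff_hz, " Hz is at or above Nyquist (",
         1 / (2 * tr), " Hz)")
  key <- paste(n, tr, cutoff_hz, sep = "|")
  if (!is.null(.hp_cache[[key]])) return(.hp_cache[[key]])
  sigma_vol <- (0.5 / cutoff_hz) / tr
  x <- seq_len(n)
  W <- exp(-outer(x, x, "-")^2 / (2 * sigma_vol^2))
  sw <- rowSums(W)
  sx <- as.numeric(W %*% x)
  sxx <- as.numeric(W %*% x^2)
  det <- sw * sxx - sx^2
  # row i of A: weights of the fitted value at i as a function of y
  A <- ((sxx - sx * x) / det) * W + ((sw * x - sx) / det) * (W * rep(x, each = n))
  F <- diag(n) - A + matrix(1 / n, n, n)
  .hp_cache[[key]] <- F
  F
}

#' Preprocess an ROI series set
#'
#' Applies, in order: optional grand-mean scaling (the mean over the whole
#' set is scaled to `grand_mean_target`), Gaussian running-line high-pass
#' filtering at `highpass_hz`, and demeaning of each series (demeaning is
#' applied to the full-length series, before any window extraction).
#' Provenance flags are updated.
#'
#' @param set An `roi_series_set`.
#' @param highpass_hz High-pass cutoff, Hz; `NULL` skips filtering.
#' @param grand_mean_target Target grand mean; `NULL` (default) skips
#'   scaling.
#' @param demean Demean each series after filtering.
#' @return The processed `roi_series_set`.
#' @export
preprocess_series <- function(set, highpass_hz = 0.01,
                              grand_mean_target = NULL, demean = TRUE) {
  stopifnot(inherits(set, "roi_series_set"))
  s <- set$series
  if (!is.null(grand_mean_target)) {
    s <- s * (grand_mean_target / mean(s))
    set$provenance$grand_mean_target <- grand_mean_target
  }
  if (!is.null(highpass_hz)) {
    s <- .highpass_matrix(nrow(s), set$tr, highpass_hz) %*% s
    set$provenance$highpass_hz <- highpass_hz
  }
  if (demean) {
    s <- sweep(s, 2, colMeans(s))
    set$provenance$demeaned <- TRUE
  }
  colnames(s) <- colnames(set$series)
  set$series <- s
  set
}

#' Write an ROI series set as CSV with a JSON provenance sidecar
#'
#' @param set An `roi_series_set`.
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(set, path) {
  stopifnot(inherits(set, "roi_series_set"))
  utils::write.csv(as.data.frame(set$series), path, row.names = FALSE)
  jsonlite::write_json(c(list(tr = set$tr), set$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ROI series CSV (with optional provenance sidecar)
#'
#' @param path CSV path.
#' @param tr Repetition time; read from the sidecar when present.
#' @return An `roi_series_set`.
#' @export
read_roi_set <- function(path, tr = NULL) {
  s <- as.matrix(utils::read.csv(path, check.names = FALSE))
  side <- paste0(path, ".json")
  prov <- list()
  if (file.exists(side)) {
    prov <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(tr)) tr <- prov$tr
    prov$tr <- NULL
  }
  if (is.null(tr)) stop("tr not given and no provenance sidecar found")
  roi_series_set(s, tr, provenance = prov)
}
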