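#' Stimulus protocol container
#'
#' Holds the onsets and durations of noxious stimulation events on the
#' acquisition clock (seconds from scan start).  The experimental protocol
#' applies brief (~1 s) mechanical noxious stimuli with a minimum
#' inter-stimulus interval so successive haemodynamic responses do not
#' overlap; the constructor enforces strictly increasing onsets and the
#' minimum gap.
#'
#' @param onsets Numeric vector of event onsets, seconds, strictly
#'   increasing.
#' @param durations Event durations in seconds; recycled to the number of
#'   onsets.  Defaults to 1 s.
#' @param min_isi Minimum allowed gap between successive onsets, seconds.
#'   Use 0 to accept arbitrary spacing.
#'
#' @return An object of class `stimulus_protocol` with fields `onsets`,
#'   `durations` and `n_stimuli`.
#' @export
stimulus_protocol <- function(onsets, durations = 1, min_isi = 25) {
  onsets <- as.numeric(onsets)
  durations <- rep_len(as.numeric(durations), length(onsets))
  ord <- order(onsets)          # event order in the input table is irrelevant
  onsets <- onsets[ord]
  durations <- durations[ord]
  if (length(onsets) > 1L) {
    gaps <- diff(onsets)
    if (any(gaps <= 0)) stop("onsets must be distinct")
    if (any(gaps < min_isi))
      stop("inter-stimulus interval below minimum: gap ",
           format(min(gaps)), " s < ", min_isi, " s")
  }
  if (any(onsets < 0)) stop("onsets must be non-negative")
  if (any(durations < 0)) stop("durations must be non-negative")
  structure(list(onsets = onsets, durations = durations,
                 n_stimuli = length(onsets)),
            class = "stimulus_protocol")
}

#' Read / write a stimulus events table
#'
#' Events files are tab-separated with header columns `onset` and
#' `duration`, both in seconds on the scan-start clock.
#'
#' @param path File path.
#' @param min_isi Passed to [stimulus_protocol()] on read.
#' @return For `read_events`, a `stimulus_protocol`; for `write_events`,
#'   `path` invisibly.
#' @export
read_events <- function(path, min_isi = 25) {
  df <- utils::read.delim(path)
  if (!all(c("onset", "duration") %in% names(df)))
    stop("events file must have columns 'onset' and 'duration'")
  stimulus_protocol(df$onset, df$duration, min_isi = min_isi)
}

#' @rdname read_events
#' @param protocol A `stimulus_protocol`.
#' @export
write_events <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  utils::write.table(
    data.frame(onset = protocol$onsets, duration = protocol$durations),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build an event-related design matrix
#'
#' Convolves the stimulus event train with each basis function on the fine
#' (`basis$dt`) grid and samples the result at volume acquisition times
#' `0, tr, 2*tr, ...`, giving three task regressors per event train.  One
#' unit-indicator nuisance column is appended per flagged motion-outlier
#' volume (1 at that volume, 0 elsewhere), which removes the volume from
#' influencing the task fit.
#'
#' @param protocol A `stimulus_protocol`; may be empty (zero task columns).
#' @param basis A `basis_set` from [build_basis_set()].
#' @param n_volumes Number of volumes acquired.
#' @param tr Repetition time, seconds.
#' @param outliers Integer vector of motion-outlier volume indices
#'   (1-based), e.g. from [detect_motion_outliers()].
#'
#' @return An object of class `design_matrix`: list with `matrix`
#'   (`n_volumes` x regressors), `labels`, `n_task`, `task_peaks` (maximum
#'   of each task column, used by the percent-change convention), `tr` and
#'   `outliers`.
#' @export
build_design_matrix <- function(protocol, basis, n_volumes, tr,
                                outliers = integer(0)) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(basis, "basis_set"),
            n_volumes >= 1, tr > 0)
  scan_end <- n_volumes * tr
  bad <- protocol$onsets >= scan_end
  if (any(bad))
    stop("stimulus onset beyond scan end (", scan_end, " s): onset ",
         paste(format(protocol$onsets[bad]), collapse = ", "), " s")
  outliers <- sort(unique(as.integer(outliers)))
  if (length(outliers) && (min(outliers) < 1L || max(outliers) > n_volumes))
    stop("outlier volume index out of range 1..", n_volumes)

  dt <- basis$dt
  vol_times <- (seq_len(n_volumes) - 1L) * tr
  n_task <- if (protocol$n_stimuli > 0L) ncol(basis$functions) else 0L

  task <- matrix(numeric(0), nrow = n_volumes, ncol = 0)
  if (n_task > 0L) {
    grid <- seq(0, scan_end + max(basis$time), by = dt)
    u <- numeric(length(grid))
    for (j in seq_len(protocol$n_stimuli)) {
      on <- protocol$onsets[j]
      off <- on + max(protocol$durations[j], dt)  # model >=1 fine-grid bin
      u[grid >= on & grid < off] <- 1
    }
    vol_idx <- round(vol_times / dt) + 1L
    # open convolution via zero-padded FFT; the event-train transform is
    # shared across the three basis functions
    nk <- nrow(basis$functions)
    L <- stats::nextn(length(grid) + nk - 1L, 2)
    U <- stats::fft(c(u, numeric(L - length(u))))
    task <- apply(basis$functions, 2, function(k) {
      K <- stats::fft(c(k, numeric(L - nk)))
      x <- Re(stats::fft(U * K, inverse = TRUE))[seq_along(grid)] / L * dt
      x[vol_idx]
    })
    colnames(task) <- paste0("task_", basis$labels)
  }

  nuis <- matrix(0, nrow = n_volumes, ncol = length(outliers))
  if (length(outliers)) {
    nuis[cbind(outliers, seq_along(outliers))] <- 1
    colnames(nuis) <- paste0("outlier_", outliers)
  }

  X <- cbind(task, nuis)
  structure(list(
    matrix = X,
    labels = colnames(X),
    n_task = n_task,
    task_peaks = if (n_task > 0L) apply(task, 2, max) else numeric(0),
    tr = tr,
    outliers = outliers
  ), class = "design_matrix")
}
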