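#' Configuration for a synthetic infant cohort
#'
#' Defines the study conditions emulated by the generator: 13 term infants
#' scanned at TR 2.5 s for 142 volumes while 10 brief noxious stimuli are
#' applied with a minimum inter-stimulus interval of 25 s; 15 ROIs grouped
#' into three networks (6 descending pain modulatory system, 6 Control, 3
#' Default Mode).  Each infant carries a latent DPMS coupling strength that
#' (a) scales how strongly the DPMS ROIs load a shared slow fluctuation,
#' creating pre-stimulus connectivity, and (b) lowers the amplitude of the
#' noxious-evoked response via `coupling_slope` (negative for study-like
#' data).  Control and Default Mode loadings are drawn independently of the
#' latent coupling, so only the DPMS connectivity is informative about the
#' evoked response.
#'
#' Baselines are large (~1000 raw units) so evoked amplitudes expressed as
#' percent signal change are well defined.  Shared fluctuations are
#' band-limited (0.01-0.08 Hz) sinusoid mixtures, giving slow within-network
#' covariation that the three-volume pre-stimulus windows can detect.
#'
#' @param n_infants Cohort size.
#' @param tr Repetition time, seconds.
#' @param n_volumes Volumes per session.
#' @param n_stimuli Number of noxious stimuli.
#' @param min_isi Minimum inter-stimulus interval, seconds.
#' @param isi_jitter Uniform jitter added to the minimum gap, seconds.
#' @param first_onset_range Range (seconds) for the first stimulus onset.
#' @param networks Named list of network -> ROI label vectors.
#' @param active_rois ROIs carrying the noxious-evoked response (the
#'   synthetic analogue of the group activity mask).  The default set
#'   (supplementary motor area, caudate, inferior parietal lobule) lies
#'   outside the DPMS: the canonical kernel's 30 s support exceeds the
#'   25 s minimum ISI, so the undershoot tail of one trial overlaps the
#'   next pre-stimulus window, and an activity mask intersecting the DPMS
#'   would leak amplitude-dependent signal into the very connectivity
#'   statistic under study, breaking null fidelity of the
#'   psFC-association test.
#' @param dpms_coupled_rois DPMS ROIs that load the shared DPMS
#'   fluctuation; defaults to all six.  Restricting this to the cortical
#'   nodes yields cohorts whose brainstem edges carry no connectivity
#'   signal (used by the brainstem sensitivity analysis).
#' @param baseline,baseline_sd Mean raw-signal baseline and its across-ROI
#'   spread.
#' @param connectivity_range Range of the per-infant latent DPMS coupling,
#'   expressed on the correlation scale (the approximate expected
#'   pre-stimulus correlation between two coupled ROIs; in `[0, 1)`).  The
#'   fluctuation loading is derived from it analytically via the
#'   within-window variance of the band-limited process, so measured psFC
#'   is close to linear in the latent value.
#' @param control_range,dmn_range Latent coupling ranges (same correlation
#'   scale) for the Control and Default Mode networks, drawn independently
#'   per infant.
#' @param roi_loading_jitter Multiplicative per-ROI jitter on network
#'   loadings (uniform half-width, dimensionless).
#' @param shared_weight Global multiplier on all network loadings; 0
#'   switches shared fluctuations off.
#' @param n_harmonics Number of sinusoids mixed into each network
#'   fluctuation.
#' @param fluct_band Frequency band of the shared fluctuations, Hz.
#' @param noise_sd White-noise standard deviation, raw units.
#' @param drift_amplitude Peak-to-peak linear drift, raw units.
#' @param amp_intercept Evoked-response percent signal change for an infant
#'   with zero latent coupling.
#' @param coupling_slope Change in evoked percent signal change per unit
#'   latent coupling (negative: stronger DPMS coupling, smaller response).
#' @param amp_sd Between-infant residual SD of the evoked amplitude,
#'   percent signal change.
#' @param ga_range Gestational age range at study, weeks.
#' @param ga_coupling_r Correlation induced between gestational age and the
#'   latent coupling (0 = independent; non-zero exercises covariate
#'   adjustment).
#' @param n_motion_spikes Number of motion-spike volumes injected per
#'   infant (global signal jumps, to exercise DVARS detection).
#' @param spike_amplitude Spike size, raw units.
#' @param seed Integer seed; fixed seed gives identical cohorts.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_infants = 13, tr = 2.5, n_volumes = 142,
                          n_stimuli = 10, min_isi = 25, isi_jitter = 5,
                          first_onset_range = c(30, 40),
                          networks = list(
                            DPMS = c("ACC", "AI", "AMY", "mFG", "PAG", "RVM"),
                            Control = c("CAL", "CAU", "HIP", "PON", "RGY", "SMA"),
                            DMN = c("PCC", "IPL", "mSFG")),
                          active_rois = c("SMA", "CAU", "IPL"),
                          dpms_coupled_rois = NULL,
                          baseline = 1000, baseline_sd = 50,
                          connectivity_range = c(0.05, 0.95),
                          control_range = c(0.05, 0.6),
                          dmn_range = c(0.3, 0.8),
                          roi_loading_jitter = 0.15,
                          shared_weight = 1,
                          n_harmonics = 6,
                          fluct_band = c(0.01, 0.08),
                          noise_sd = 1.5,
                          drift_amplitude = 10,
                          amp_intercept = 2.0,
                          coupling_slope = -1.3,
                          amp_sd = 0.04,
                          ga_range = c(38, 43),
                          ga_coupling_r = 0,
                          n_motion_spikes = 0,
                          spike_amplitude = 50,
                          seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$dpms_coupled_rois))
    cfg$dpms_coupled_rois <- cfg$networks$DPMS
  if (cfg$n_stimuli * cfg$min_isi >= cfg$n_volumes * cfg$tr)
    stop("infeasible protocol: ", cfg$n_stimuli, " stimuli at >= ",
         cfg$min_isi, " s gaps cannot fit in ",
         cfg$n_volumes * cfg$tr, " s of acquisition")
  if (any(lengths(cfg$networks) == 0L)) stop("all networks must be non-empty")
  if (!all(cfg$active_rois %in% unlist(cfg$networks)))
    stop("active_rois must be known ROI labels")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a stimulation protocol
#'
#' Draws `n_stimuli` onsets with successive gaps uniform in
#' `[min_isi, min_isi + isi_jitter]`; the first onset is uniform in
#' `first_onset_range`.  Onsets are continuous, so they are not
#' phase-locked to volume boundaries.  Uses the current RNG stream.
#'
#' @param config A `cohort_config`.
#' @return A `stimulus_protocol`.
#' @export
generate_protocol <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_stimuli
  if (n == 0L)
    return(stimulus_protocol(numeric(0), numeric(0), min_isi = config$min_isi))
  scan_end <- config$n_volumes * config$tr
  tail_pad <- 15  # leave room for the response after the last stimulus
  worst <- max(config$first_onset_range) +
    (n - 1) * (config$min_isi + config$isi_jitter)
  if (worst > scan_end - tail_pad)
    stop("infeasible protocol: needs at least ", ceiling(worst + tail_pad),
         " s of acquisition (", ceiling((worst + tail_pad) / config$tr),
         " volumes), have ", scan_end, " s")
  onsets <- cumsum(c(stats::runif(1, config$first_onset_range[1],
                                  config$first_onset_range[2]),
                     config$min_isi + stats::runif(n - 1, 0, config$isi_jitter)))
  stimulus_protocol(onsets, durations = 1, min_isi = config$min_isi)
}

# expected sample variance of 3 consecutive points of the unit-variance
# band-limited fluctuation: gamma(0) - (2 gamma(tr) + gamma(2 tr)) / 3,
# with gamma(tau) the band-average cosine autocovariance
.window_var3 <- function(config) {
  g <- function(tau) {
    a <- config$fluct_band[1]; b <- config$fluct_band[2]
    if (tau == 0) return(1)
    (sin(2 * pi * b * tau) - sin(2 * pi * a * tau)) / (2 * pi * tau * (b - a))
  }
  1 - (2 * g(config$tr) + g(2 * config$tr)) / 3
}

# loading that yields approximate expected 3-point correlation `c_target`
# between two ROIs sharing the network fluctuation against white noise
.loading_for_coupling <- function(c_target, config) {
  v3 <- .window_var3(config)
  c_target <- pmin(pmax(c_target, 0), 0.99)
  config$noise_sd * sqrt(c_target / ((1 - c_target) * v3))
}

# network fluctuation: band-limited unit-variance sinusoid mixture
.network_fluctuation <- function(times, config) {
  k <- config$n_harmonics
  freqs <- stats::runif(k, config$fluct_band[1], config$fluct_band[2])
  phases <- stats::runif(k, 0, 2 * pi)
  f <- colSums(sin(outer(freqs, times, function(f, t) 2 * pi * f * t) +
                     phases)) / sqrt(k / 2)
  f
}

#' Generate one synthetic infant session
#'
#' Draws the infant's latent DPMS coupling, gestational age, stimulation
#' protocol and per-ROI signals from the current RNG stream.  Each ROI
#' series is baseline + shared network fluctuation (scaled by the network
#' loading) + linear drift + white noise; ROIs in `config$active_rois`
#' additionally carry the evoked response: the canonical infant HRF
#' convolved with the event train, scaled so its peak equals the infant's
#' true percent signal change of the ROI baseline.
#'
#' @param config A `cohort_config`.
#' @param infant_index Integer id within the cohort.
#' @param basis Optional pre-built `basis_set` (rebuilt if `NULL`).
#' @return An object of class `infant_record`: list with `id`, `ga_weeks`,
#'   `latent_dpms_coupling`, `true_evoked_amplitude` (percent signal
#'   change), `protocol`, `roi_series` (volumes x ROI matrix) and
#'   `ground_truth` (all latent draws, including injected motion spikes).
#' @export
generate_infant <- function(config, infant_index = 1L, basis = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(basis))
    basis <- build_basis_set(calibrate_infant_hrf(dt = 0.1))

  protocol <- generate_protocol(config)
  times <- (seq_len(config$n_volumes) - 1L) * config$tr
  rois <- unlist(config$networks, use.names = FALSE)
  net_of <- rep(names(config$networks), lengths(config$networks))

  z_lat <- stats::runif(1)
  latent <- config$connectivity_range[1] +
    z_lat * diff(config$connectivity_range)
  rho <- config$ga_coupling_r
  z_ga <- rho * stats::qnorm(pmin(pmax(z_lat, 1e-6), 1 - 1e-6)) +
    sqrt(max(0, 1 - rho^2)) * stats::rnorm(1)
  ga <- config$ga_range[1] +
    stats::pnorm(z_ga) * diff(config$ga_range)

  net_names <- names(config$networks)
  ranges <- list(config$control_range, config$dmn_range)
  couplings <- stats::setNames(c(latent, vapply(seq_along(net_names)[-1],
    function(k) {
      rg <- ranges[[min(k - 1, length(ranges))]]
      stats::runif(1, rg[1], rg[2])
    }, numeric(1))), net_names)
  loadings <- .loading_for_coupling(couplings, config)
  fluct <- sapply(names(config$networks), function(nm)
    .network_fluctuation(times, config))

  true_amp <- config$amp_intercept + config$coupling_slope * latent +
    stats::rnorm(1, 0, config$amp_sd)

  evoked_shape <- NULL
  if (protocol$n_stimuli > 0L && length(config$active_rois)) {
    dm <- build_design_matrix(protocol, basis, config$n_volumes, config$tr)
    x <- dm$matrix[, 1]
    evoked_shape <- x / max(x)  # unit-peak response train
  }

  baselines <- stats::rnorm(length(rois), config$baseline, config$baseline_sd)
  drift_slopes <- stats::runif(length(rois), -1, 1) * config$drift_amplitude
  jit <- stats::runif(length(rois), 1 - config$roi_loading_jitter,
                      1 + config$roi_loading_jitter)

  series <- matrix(0, nrow = config$n_volumes, ncol = length(rois),
                   dimnames = list(NULL, rois))
  for (i in seq_along(rois)) {
    nm <- net_of[i]
    load_i <- loadings[[nm]] * jit[i] * config$shared_weight
    if (nm == "DPMS" && !(rois[i] %in% config$dpms_coupled_rois))
      load_i <- 0
    y <- baselines[i] +
      load_i * fluct[, nm] +
      drift_slopes[i] * (times - mean(times)) / diff(range(times)) +
      stats::rnorm(config$n_volumes, 0, config$noise_sd)
    if (!is.null(evoked_shape) && rois[i] %in% config$active_rois)
      y <- y + (true_amp / 100) * baselines[i] * evoked_shape
    series[, i] <- y
  }

  spikes <- integer(0)
  if (config$n_motion_spikes > 0L) {
    spikes <- sort(sample(5:(config$n_volumes - 5L), config$n_motion_spikes))
    series[spikes, ] <- series[spikes, ] + config$spike_amplitude
  }

  structure(list(
    id = sprintf("infant%02d", infant_index),
    ga_weeks = ga,
    latent_dpms_coupling = latent,
    true_evoked_amplitude = true_amp,
    protocol = protocol,
    roi_series = series,
    ground_truth = list(latent_dpms_coupling = latent,
                        true_evoked_amplitude = true_amp,
                        ga_weeks = ga,
                        network_couplings = as.list(couplings),
                        network_loadings = as.list(loadings),
                        baselines = stats::setNames(baselines, rois),
                        motion_spike_volumes = spikes)
  ), class = "infant_record")
}

#' Generate a synthetic cohort
#'
#' Produces `config$n_infants` infant records.  When `config$seed` is set
#' the RNG state is localised, so a fixed seed yields an identical cohort
#' and leaves the caller's RNG untouched.
#'
#' @param config A `cohort_config`.
#' @param basis Optional pre-built `basis_set` shared across infants.
#' @return A list of class `infant_cohort` of `infant_record`s, with the
#'   config attached as attribute `config`.
#' @export
generate_cohort <- function(config, basis = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
  }
  if (is.null(basis))
    basis <- build_basis_set(calibrate_infant_hrf(dt = 0.1))
  cohort <- lapply(seq_len(config$n_infants), function(i)
    generate_infant(config, i, basis = basis))
  structure(cohort, class = "infant_cohort", config = config)
}

#' Write a cohort to plain-text files
#'
#' Writes, per infant, a ROI series CSV (one column per ROI) and an events
#' TSV, plus cohort-level covariates CSV (`id, ga_weeks`), ground-truth
#' JSON and a manifest JSON.
#'
#' @param cohort An `infant_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "infant_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort) {
    utils::write.csv(as.data.frame(rec$roi_series),
                     file.path(dir, paste0(rec$id, "_roi_series.csv")),
                     row.names = FALSE)
    write_events(rec$protocol, file.path(dir, paste0(rec$id, "_events.tsv")))
  }
  utils::write.csv(
    data.frame(id = vapply(cohort, `[[`, "", "id"),
               ga_weeks = vapply(cohort, `[[`, 0, "ga_weeks")),
    file.path(dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(cohort, `[[`, "ground_truth"),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- attr(cohort, "config")
  jsonlite::write_json(
    list(n_infants = length(cohort), tr = cfg$tr, n_volumes = cfg$n_volumes,
         networks = cfg$networks, active_rois = cfg$active_rois,
         seed = cfg$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Render an infant record as a small 4D volume with ROI masks
#'
#' Places each ROI as a disjoint block of voxels on a small 3D grid; every
#' voxel in a block carries the ROI's series plus independent voxel noise.
#' Optionally attenuates a fraction of one ROI's voxels (simulating signal
#' dropout, e.g. susceptibility loss near air spaces) to exercise the
#' dropout-exclusion rule, and gives the RVM a weighted (non-binary) mask
#' as used for small brainstem ROIs.
#'
#' @param record An `infant_record`.
#' @param grid_shape 3D grid dimensions.
#' @param block 3D extent of each ROI block, voxels.
#' @param voxel_noise_sd Independent voxel-level noise SD, raw units.
#' @param dropout_roi,dropout_fraction,dropout_factor Attenuate
#'   `dropout_fraction` of `dropout_roi`'s voxels by `dropout_factor`
#'   (multiplicative, < 1).
#' @param background Background intensity of non-ROI voxels.
#' @return List with `image` (4D array), `masks` (named list of 3D weight
#'   arrays; zero outside the ROI), `dropout_voxels` (named list of indices
#'   of attenuated voxels, if any) and `tr`.
#' @export
render_volumes <- function(record, grid_shape = c(20, 20, 12),
                           block = c(2, 2, 2), voxel_noise_sd = 0,
                           dropout_roi = NULL, dropout_fraction = 0.3,
                           dropout_factor = 0.85, background = 100) {
  stopifnot(inherits(record, "infant_record"))
  rois <- colnames(record$roi_series)
  n_vol <- nrow(record$roi_series)

  # lattice of disjoint block origins, spaced one voxel apart
  step <- block + 1L
  ox <- seq(1L, grid_shape[1] - block[1] + 1L, by = step[1])
  oy <- seq(1L, grid_shape[2] - block[2] + 1L, by = step[2])
  oz <- seq(1L, grid_shape[3] - block[3] + 1L, by = step[3])
  origins <- expand.grid(x = ox, y = oy, z = oz)
  if (nrow(origins) < length(rois))
    stop("grid too small: ", nrow(origins), " disjoint slots for ",
         length(rois), " ROIs")

  img <- array(stats::rnorm(prod(grid_shape) * n_vol, background,
                            max(voxel_noise_sd, 1e-3)),
               dim = c(grid_shape, n_vol))
  masks <- list()
  dropout_voxels <- list()
  for (i in seq_along(rois)) {
    o <- as.integer(origins[i, ])
    xs <- o[1]:(o[1] + block[1] - 1L)
    ys <- o[2]:(o[2] + block[2] - 1L)
    zs <- o[3]:(o[3] + block[3] - 1L)
    vox <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    w <- array(0, dim = grid_shape)
    # the RVM is a small brainstem ROI extracted with mask weights
    weights <- if (rois[i] == "RVM")
      seq(1, 0.5, length.out = nrow(vox)) else rep(1, nrow(vox))
    w[vox] <- weights
    masks[[rois[i]]] <- w

    keep_factor <- rep(1, nrow(vox))
    if (!is.null(dropout_roi) && rois[i] == dropout_roi) {
      n_drop <- round(dropout_fraction * nrow(vox))
      drop_idx <- seq_len(n_drop)
      keep_factor[drop_idx] <- dropout_factor
      dropout_voxels[[rois[i]]] <- vox[drop_idx, , drop = FALSE]
    }
    for (v in seq_len(nrow(vox))) {
      noise <- if (voxel_noise_sd > 0)
        stats::rnorm(n_vol, 0, voxel_noise_sd) else 0
      img[vox[v, 1], vox[v, 2], vox[v, 3], ] <-
        (record$roi_series[, i] + noise) * keep_factor[v]
    }
  }
  list(image = img, masks = masks, dropout_voxels = dropout_voxels,
       tr = attr(record$roi_series, "tr") %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write rendered volumes and masks as NIfTI files
#'
#' @param rendered Output of [render_volumes()].
#' @param dir Output directory.
#' @param tr Repetition time stored in the NIfTI header, seconds.
#' @return Named character vector of written paths, invisibly.
#' @export
write_volumes <- function(rendered, dir, tr = 2.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image = file.path(dir, "func.nii.gz"))
  img <- RNifti::asNifti(rendered$image)
  RNifti::pixdim(img) <- c(3, 3, 3, tr)
  RNifti::writeNifti(img, paths[["image"]])
  for (nm in names(rendered$masks)) {
    p <- file.path(dir, paste0("mask_", nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(rendered$masks[[nm]]), p)
    paths[nm] <- p
  }
  invisible(paths)
}
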