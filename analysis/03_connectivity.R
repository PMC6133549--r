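#!/usr/bin/env Rscript
# Step 3: pre-stimulus functional connectivity.
#
# High-pass filters (0.01 Hz) and demeans each ROI series, extracts the
# three volumes immediately preceding each stimulus, correlates every ROI
# pair within each window, averages the 10 per-stimulus correlations into
# a per-infant connectivity matrix, and summarises network means for the
# DPMS, Control and Default Mode networks.  Writes per-infant matrices,
# the long edge table, network means and per-stimulus DPMS means.

suppressPackageStartupMessages(library(prestimfc))

cov <- read.csv("results/cohort/covariates.csv")
manifest <- jsonlite::read_json("results/cohort/manifest.json",
                                simplifyVector = TRUE)
networks <- manifest$networks

dir.create("results/connectivity", showWarnings = FALSE)
net_rows <- list(); stim_rows <- list()
for (id in cov$id) {
  set <- read_roi_set(file.path("results/cohort",
                                paste0(id, "_roi_series.csv")),
                      tr = manifest$tr)
  protocol <- read_events(file.path("results/cohort",
                                    paste0(id, "_events.tsv")))
  prep <- preprocess_series(set, highpass_hz = 0.01, demean = TRUE)
  w <- extract_prestim_windows(prep, protocol)
  cm <- build_connectivity_matrix(w, networks = networks)
  write_connectivity(cm, file.path("results/connectivity",
                                   paste0(id, "_matrix.csv")))
  net_rows[[id]] <- data.frame(
    id = id,
    t(vapply(networks, function(n) network_mean_psfc(cm, n), numeric(1))))
  stim_rows[[id]] <- data.frame(id = id, stimulus = 1:10,
                                dpms_psfc = psfc_by_stimulus(cm, networks$DPMS))
}
net <- do.call(rbind, net_rows)
write.csv(net, "results/network_psfc.csv", row.names = FALSE)
write.csv(do.call(rbind, stim_rows), "results/psfc_by_stimulus.csv",
          row.names = FALSE)

for (n in names(networks))
  message(sprintf("%s mean psFC: %.3f +/- %.3f", n, mean(net[[n]]),
                  sd(net[[n]])))
message("Wrote results/connectivity/, results/network_psfc.csv, results/psfc_by_stimulus.csv")
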