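#!/usr/bin/env Rscript
# Step 4: association analyses.
#
# Relates each network's mean pre-stimulus connectivity to the percent
# BOLD change with gestational age as a covariate (reporting beta, p and
# the age-adjusted Pearson r), fits the 15 DPMS edge models, compares
# network connectivity with a repeated-measures ANOVA + Tukey post-hoc,
# tests stability across stimulus number, and reruns the association with
# brainstem nodes excluded.  Writes results/associations.csv,
# results/edge_associations.csv, results/anova.json.

suppressPackageStartupMessages(library(prestimfc))

cov <- read.csv("results/cohort/covariates.csv")
pct <- read.csv("results/percent_change.csv")
net <- read.csv("results/network_psfc.csv")
stim <- read.csv("results/psfc_by_stimulus.csv")
manifest <- jsonlite::read_json("results/cohort/manifest.json",
                                simplifyVector = TRUE)
networks <- manifest$networks
stopifnot(identical(cov$id, pct$id), identical(cov$id, net$id))

# per-network associations
assoc <- lapply(names(networks), function(nm)
  psfc_association(pct$percent_change, net[[nm]], cov$ga_weeks, label = nm))
assoc_df <- data.frame(network = vapply(assoc, `[[`, "", "label"),
                       beta = vapply(assoc, `[[`, 0, "beta"),
                       p = vapply(assoc, `[[`, 0, "p"),
                       r = vapply(assoc, `[[`, 0, "r"),
                       n = vapply(assoc, `[[`, 0L, "n"))

# DPMS edge models, from the stored per-infant matrices
cms <- lapply(cov$id, function(id)
  as.matrix(read.csv(file.path("results/connectivity",
                               paste0(id, "_matrix.csv")), row.names = 1)))
edges <- edgewise_association(network_edge_table(cms, networks$DPMS),
                              pct$percent_change, cov$ga_weeks)
write.csv(edges, "results/edge_associations.csv", row.names = FALSE)

# network comparison and stimulus-number stability
nm_mat <- as.matrix(net[, names(networks)])
anova_net <- compare_network_connectivity(nm_mat)
stim_mat <- t(vapply(split(stim$dpms_psfc, stim$id), identity, numeric(10)))
anova_stim <- stimulus_stability(stim_mat)

# brainstem-exclusion sensitivity
sens <- sensitivity_excluding_brainstem(cms, pct$percent_change,
                                        cov$ga_weeks, networks)
sens_df <- data.frame(network = vapply(sens, `[[`, "", "label"),
                      beta = vapply(sens, `[[`, 0, "beta"),
                      p = vapply(sens, `[[`, 0, "p"),
                      r = vapply(sens, `[[`, 0, "r"))

write.csv(rbind(assoc_df, cbind(sens_df, n = assoc_df$n[1])),
          "results/associations.csv", row.names = FALSE)
jsonlite::write_json(
  list(network_anova = anova_net[c("levels", "F", "p", "tukey")],
       stimulus_anova = anova_stim[c("F", "p")]),
  "results/anova.json", auto_unbox = TRUE, digits = NA)

message("Age-adjusted psFC-response associations:")
for (a in assoc) print(a)
message(sprintf("Network RM-ANOVA: F = %.2f, p = %.4g", anova_net$F,
                anova_net$p))
message(sprintf("Stability across stimulus number: F = %.2f, p = %.3f",
                anova_stim$F, anova_stim$p))
message("Brainstem-exclusion sensitivity:")
for (a in sens) print(a)
message("Wrote results/associations.csv, results/edge_associations.csv, results/anova.json")
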