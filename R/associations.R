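#' Association between network psFC and noxious-evoked response
#'
#' Fits `percent_change ~ intercept + psFC + GA` by ordinary least
#' squares and reports the psFC slope (beta) and its p-value, the
#' gestational-age coefficient, and the age-adjusted Pearson correlation.
#' The age-adjusted r is, by default, the correlation between the
#' GA-residualised response and the psFC values (residualising the
#' response on GA with an intercept, following the regression fit); the
#' `"partial"` method residualises both variables on GA (the classical
#' partial correlation), which differs slightly whenever psFC and GA are
#' correlated.
#'
#' @param percent_change Per-infant percent BOLD change (response).
#' @param psfc Per-infant network mean pre-stimulus connectivity.
#' @param ga_weeks Per-infant gestational age, decimal weeks (weeks +
#'   days / 7).
#' @param label Label stored in the result.
#' @param method `"residual"` (default) or `"partial"` for the
#'   age-adjusted correlation.
#' @return An object of class `association_result`: list with `label`,
#'   `beta`, `p`, `ga_beta`, `r`, `n`, `method`.
#' @export
psfc_association <- function(percent_change, psfc, ga_weeks,
                             label = "network",
                             method = c("residual", "partial")) {
  method <- match.arg(method)
  n <- length(percent_change)
  if (n < 4) stop("need at least 4 infants, got ", n)
  if (length(psfc) != n || length(ga_weeks) != n)
    stop("percent_change, psfc and ga_weeks must have equal length")
  if (anyNA(c(percent_change, psfc, ga_weeks)))
    stop("missing values are not allowed")
  if (stats::sd(psfc) == 0)
    stop("psFC is constant across infants: slope not identifiable")

  fit <- stats::lm(percent_change ~ psfc + ga_weeks)
  sm <- summary(fit)$coefficients
  resp_resid <- stats::resid(stats::lm(percent_change ~ ga_weeks))
  r <- if (method == "residual") stats::cor(resp_resid, psfc)
       else stats::cor(resp_resid, stats::resid(stats::lm(psfc ~ ga_weeks)))

  structure(list(label = label,
                 beta = unname(sm["psfc", "Estimate"]),
                 p = unname(sm["psfc", "Pr(>|t|)"]),
                 ga_beta = unname(sm["ga_weeks", "Estimate"]),
                 r = r, n = n, method = method),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.3f, p = %.4g, age-adjusted r = %.3f (n = %d)\n",
              x$label, x$beta, x$p, x$r, x$n))
  invisible(x)
}

#' Per-infant edge table for a network
#'
#' Collects each infant's below-diagonal connectivity entries for a
#' network into an infants x edges matrix.
#'
#' @param cms List of `connectivity_matrix` objects, one per infant.
#' @param network Character vector of ROI labels.
#' @return Numeric matrix with edge names `roiA-roiB` as columns.
#' @export
network_edge_table <- function(cms, network) {
  pairs <- utils::combn(network, 2)
  out <- t(vapply(cms, function(cm) {
    m <- if (inherits(cm, "connectivity_matrix")) cm$matrix else cm
    apply(pairs, 2, function(p) m[p[1], p[2]])
  }, numeric(ncol(pairs))))
  colnames(out) <- apply(pairs, 2, paste, collapse = "-")
  out
}

#' Edgewise psFC-response associations
#'
#' Fits the age-adjusted association model separately for every edge of a
#' network (15 edges for the 6-node DPMS).  P-values are reported
#' unadjusted, as in per-edge exploratory analyses; a Bonferroni column
#' is added for transparency but flagging uses the unadjusted values.
#'
#' @param edge_psfc Infants x edges matrix from [network_edge_table()].
#' @param percent_change,ga_weeks Per-infant vectors.
#' @param alpha Flagging threshold on the unadjusted p-value.
#' @return Data frame: `edge, beta, p, r, p_bonferroni, flagged`.
#' @export
edgewise_association <- function(edge_psfc, percent_change, ga_weeks,
                                 alpha = 0.05) {
  res <- lapply(colnames(edge_psfc), function(e)
    psfc_association(percent_change, edge_psfc[, e], ga_weeks, label = e))
  out <- data.frame(
    edge = vapply(res, `[[`, "", "label"),
    beta = vapply(res, `[[`, 0, "beta"),
    p = vapply(res, `[[`, 0, "p"),
    r = vapply(res, `[[`, 0, "r"))
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$flagged <- out$p < alpha
  out
}

# classical univariate repeated-measures ANOVA: subject as blocking factor
.rm_anova <- function(tbl, factor_name) {
  tbl <- as.matrix(tbl)
  if (nrow(tbl) < 2)
    stop("repeated-measures ANOVA needs at least 2 infants")
  if (anyNA(tbl)) {
    miss <- which(is.na(tbl), arr.ind = TRUE)
    stop("incomplete table: missing cells at ",
         paste(sprintf("(infant %d, level %s)", miss[, 1],
                       colnames(tbl)[miss[, 2]]), collapse = "; "))
  }
  if (is.null(colnames(tbl)))
    colnames(tbl) <- paste0("L", seq_len(ncol(tbl)))
  long <- data.frame(
    value = as.vector(tbl),
    subject = factor(rep(seq_len(nrow(tbl)), times = ncol(tbl))),
    level = factor(rep(colnames(tbl), each = nrow(tbl)),
                   levels = colnames(tbl)))
  fit <- stats::aov(value ~ subject + level, data = long)
  an <- summary(fit)[[1]]
  ss_level <- an["level", "Sum Sq"]
  if (ss_level < 1e-12 * max(1, an["subject", "Sum Sq"])) {
    # all levels identical: no within-subject effect at all
    k <- ncol(tbl)
    tuk <- utils::combn(colnames(tbl), 2, paste, collapse = "-")
    return(list(levels = colnames(tbl), F = 0, p = 1,
                tukey = stats::setNames(rep(1, length(tuk)), tuk),
                factor = factor_name))
  }
  tk <- stats::TukeyHSD(fit, "level")$level
  list(levels = colnames(tbl),
       F = unname(an["level", "F value"]),
       p = unname(an["level", "Pr(>F)"]),
       tukey = stats::setNames(tk[, "p adj"], rownames(tk)),
       factor = factor_name)
}

#' Compare mean connectivity across networks
#'
#' One-way repeated-measures ANOVA (subject as blocking factor, the
#' classical univariate F on the within-subject error term) of per-infant
#' network mean psFC across networks, with Tukey HSD post-hoc comparisons
#' of all network pairs computed on the same error term.
#'
#' @param network_means Infants x networks matrix (named columns) of mean
#'   psFC.
#' @return An object of class `anova_result`: list with `levels`, `F`,
#'   `p`, `tukey` (named adjusted p-values per pair) and `factor`.
#' @export
compare_network_connectivity <- function(network_means) {
  res <- .rm_anova(network_means, "network")
  structure(res, class = "anova_result")
}

#' Stability of psFC across stimulus number
#'
#' Repeated-measures ANOVA of the per-stimulus network mean psFC with
#' stimulus number as the within-subject factor; a non-significant result
#' indicates the connectivity is not driven by the preceding stimuli.
#'
#' @param per_stimulus_psfc Infants x stimuli matrix of network means,
#'   e.g. rows of [psfc_by_stimulus()] outputs.
#' @return An `anova_result`.
#' @export
stimulus_stability <- function(per_stimulus_psfc) {
  m <- as.matrix(per_stimulus_psfc)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("stim", seq_len(ncol(m)))
  structure(.rm_anova(m, "stimulus"), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA (%s, %d levels): F = %.3f, p = %.4g\n",
              x$factor, length(x$levels), x$F, x$p))
  for (nm in names(x$tukey))
    cat(sprintf("  Tukey %s: p = %.4g\n", nm, x$tukey[nm]))
  invisible(x)
}

#' Brainstem-exclusion sensitivity analysis
#'
#' Recomputes the network mean psFC on reduced ROI sets — by default the
#' DPMS without its brainstem nodes (PAG, RVM) and the Control network
#' without the pons — and reruns the age-adjusted association for each.
#' Brainstem signal is vulnerable to cardiorespiratory and motion noise,
#' so agreement between full and reduced associations indicates the
#' result is not brainstem-noise driven.
#'
#' @param cms List of per-infant `connectivity_matrix` objects.
#' @param percent_change,ga_weeks Per-infant vectors.
#' @param networks Named list of full network ROI sets.
#' @param exclude Named list of ROI labels to drop from each network.
#' @return Named list of `association_result`s, one per reduced network,
#'   each with attribute `psfc` (the reduced per-infant network means).
#' @export
sensitivity_excluding_brainstem <- function(cms, percent_change, ga_weeks,
                                            networks,
                                            exclude = list(
                                              DPMS = c("PAG", "RVM"),
                                              Control = "PON")) {
  out <- list()
  for (nm in names(exclude)) {
    reduced <- setdiff(networks[[nm]], exclude[[nm]])
    if (length(reduced) < 2)
      stop("network ", nm, " has fewer than 2 ROIs after exclusion")
    psfc <- vapply(cms, network_mean_psfc, numeric(1), network = reduced)
    res <- psfc_association(percent_change, psfc, ga_weeks,
                            label = paste0(nm, " minus ",
                                           paste(exclude[[nm]],
                                                 collapse = "/")))
    attr(res, "psfc") <- psfc
    attr(res, "rois") <- reduced
    out[[nm]] <- res
  }
  out
}
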