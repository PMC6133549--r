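---
title: "Pre-stimulus DPMS connectivity and noxious-evoked BOLD activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-stimulus DPMS connectivity and noxious-evoked BOLD activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

The descending pain modulatory system (DPMS) — anterior cingulate cortex
(ACC), anterior insula (AI), amygdala (AMY), middle frontal gyrus (mFG,
within dorsolateral prefrontal cortex), periaqueductal gray (PAG) and
rostral ventromedial medulla (RVM) — facilitates or inhibits nociceptive
input. In newborn term infants the maturity of this system is unknown.
The analysis implemented here asks: does the *pre-stimulus* functional
coupling of the infant DPMS predict how strongly the brain responds to a
brief mechanical noxious stimulus?

The design is event-related infant fMRI: 10 noxious stimuli (~1 s,
minimum inter-stimulus interval 25 s) during a 142-volume acquisition at
TR 2.5 s, in 13 term infants (gestational age 38–43 weeks at study).
Two control networks — a topographically matched "Control" network (CAL,
CAU, HIP, PON, RGY, SMA) and the Default Mode Network (PCC, IPL, mSFG) —
establish the specificity of any DPMS effect and guard against global
signal confounds.

## The pre-stimulus connectivity statistic (psFC)

Each ROI's mean time series is high-pass filtered and demeaned over its
full length. A stimulus at time $t$ belongs to volume
$k = \lfloor t / \mathrm{TR} \rfloor$ (0-based); its pre-stimulus window
is the three volumes $k-3, k-2, k-1$, spanning 7.5 s of acquisition and
starting between 7.5 and 10 s before the stimulus (because the stimulus
can fall anywhere within volume $k$). For an ROI pair, the per-stimulus
Pearson correlation of the two 3-point segments is averaged
arithmetically over the 10 stimuli; repeating this over all pairs gives a
per-infant connectivity matrix, and the network psFC is the mean of the
below-diagonal entries restricted to the network's ROIs.

Numerical choices:

* Correlations are averaged on the raw scale, not Fisher-z; a `fisher`
  flag provides the transformed average for comparison. With 3-point
  windows, per-stimulus correlations frequently approach $\pm 1$, where
  the z-transform diverges, so the raw mean is both the documented
  procedure and the numerically safer default.
* A zero-variance 3-point segment leaves that stimulus's correlation
  undefined; it is dropped from the average (with a count recorded)
  rather than set to 0, which would bias edges toward the null.
* An onset exactly on a volume boundary belongs to the volume it starts.

## The term-infant HRF and the evoked-response model

Term infants have a slower haemodynamic response than adults. The
canonical kernel is a double gamma, $h(t) = g_1(t) - c\,g_2(t)$, with
both lobes gamma densities, calibrated so the assembled kernel's mode is
at 7 s and its undershoot-to-peak magnitude ratio $|\min h| / \max h$ is
0.49. Only (peak, ratio) constrain the shape, so the calibration fixes
the lobe shapes ($\alpha_1 = 6$, $\alpha_2 = 12$, undershoot mode at 2.2
times the positive mode) and solves for the undershoot amplitude $c$ by
grid bracketing plus root refinement, iterating the positive lobe's mode
because subtracting the undershoot drags the kernel's argmax slightly
earlier. Calibration is deterministic and idempotent: re-running it on
the measured (peak, ratio) reproduces the kernel to $10^{-6}$.

The three-function basis set is the canonical kernel plus its temporal
derivative (finite differences) and dispersion derivative (numerical
sensitivity to a time-dilation of the kernel), each orthogonalised
against the canonical and normalised to unit peak. The second and third
functions absorb latency and width mismatch in the GLM; all downstream
quantification uses only the first (canonical) coefficient. The exact
second and third functions of the optimal infant basis are not published;
the derivative surrogate is the standard construction and is flagged as a
choice, not asserted as equivalent.

Design matrices convolve the event train (1 s boxcars on a 0.1 s grid)
with each basis function and sample at volume acquisition times
$0, \mathrm{TR}, 2\,\mathrm{TR}, \dots$; slice-timing is not modelled.
Motion outliers are detected by DVARS — the root-mean-square across
units of the volume-to-volume signal difference — thresholded at the
boxplot upper fence (75th percentile + 1.5 IQR), and each flagged volume
contributes one unit-indicator nuisance column. Per ROI, ordinary least
squares gives the canonical coefficient; percent BOLD change is
`100 * coef * peak(canonical regressor) / mean raw signal`, averaged over
the activity-mask ROIs. The scaling convention is recorded in the output
because other conventions (e.g. regressor height rather than peak) exist;
the group-level cluster inference that would define the activity mask
from real images is out of scope — the mask is an input (for synthetic
data, the generator's set of responsive ROIs).

## ROI extraction from volumes

When the input is a 4D image plus masks rather than pre-extracted series:
voxels with more than 10% signal loss relative to the maximum-signal
reference are excluded before averaging. A literal per-image maximum is a
single noisy voxel, so the reference is the 98th percentile (configurable)
of temporal-mean intensity over a supplied brain mask, or the ROI's own
voxels otherwise. CSF-labelled voxels are removed when a segmentation is
supplied. Extraction is the weighted voxel mean with weights normalised
to sum to one (unit weights except for small brainstem ROIs such as the
RVM, which carry registration mask weights).

High-pass filtering follows the Gaussian-weighted running-line
convention of the standard fMRI toolchain: at each time point a local
straight line is fitted with Gaussian weights of SD equal to half the
cutoff period (50 s for the 0.01 Hz default) and subtracted, the series
mean being added back. This passes a 0.05 Hz oscillation with gain above
0.9 while removing a full-scan linear drift almost entirely. The filter
is linear, so it is implemented as a cached $n \times n$ matrix applied
to all series at once.

## Association models

The response variable is the per-infant percent BOLD change; the model is

$$\text{percent change} = \beta_0 + \beta_1\,\text{psFC} +
\beta_2\,\text{GA} + \varepsilon$$

with gestational age in decimal weeks. The reported age-adjusted $r$ is
the Pearson correlation between the GA-residualised response and psFC
(residualising the response only, following the regression fit); the
alternative partial correlation (residualising both) is available behind
a flag and coincides with the default whenever GA is orthogonal to psFC.
Edge-level models repeat this per ROI pair (15 edges for the 6-node
DPMS) with unadjusted p-values, plus a Bonferroni column for
transparency. Network comparison uses the classical univariate
repeated-measures ANOVA (subject as blocking factor) with Tukey HSD on
the within-subject error term; sphericity corrections are off by default.
The same machinery tests stability of the DPMS psFC across stimulus
number. The brainstem sensitivity analysis recomputes network means on
DPMS∖{PAG, RVM} (exactly the 6 edges of ACC/AI/AMY/mFG) and
Control∖{PON} and refits the association.

## The synthetic cohort generator

The generator emulates the study conditions so every stage can be
verified without images: 13 infants, TR 2.5 s, 142 volumes, 10 stimuli
with gaps uniform on [25, 30] s and a first onset uniform on [30, 40] s
(onsets are continuous, hence not phase-locked to volume boundaries).
Each ROI series is

baseline (≈1000 raw units, so percent change ≈ amplitude/baseline × 100)
+ network fluctuation × loading + linear drift + white noise,

with the shared fluctuation a unit-variance mixture of six sinusoids at
frequencies uniform on 0.01–0.08 Hz with random phases — band-limited so
that three-point window correlations have predictable sign structure.
The per-infant latent DPMS coupling is expressed on the correlation
scale: a value $c$ is converted to a loading
$\lambda = \sigma \sqrt{c / ((1-c)\,v_3)}$, where $v_3$ is the analytic
expected 3-point sample variance of the band-limited process, so the
expected pre-stimulus correlation between two coupled ROIs is
approximately $c$ and measured psFC is close to linear in the latent
value. Control and Default Mode loadings are drawn independently per
infant (DMN higher on average, mimicking its robust resting-state
coherence), so only DPMS connectivity is informative about the response.
The evoked amplitude is
$a = a_0 + s\,c + \varepsilon_a$ with $s < 0$: infants with stronger
DPMS coupling respond less. The evoked train is scaled so its peak
equals $a$% of the ROI baseline, making noise-free recovery exact.

Default values: latent coupling uniform on [0.05, 0.95], $a_0 = 2.0$%,
$s = -1.3$%/unit, $\varepsilon_a \sim N(0, 0.04^2)$, white noise SD 1.5
raw units (0.15% of baseline), drift ±10 units per scan. Gestational age
is uniform on 38–43 weeks, independent of coupling by default; a config
switch induces GA–coupling correlation for covariate-adjustment tests.
Fixed seeds give byte-identical cohorts, and every latent quantity is
serialised with the data.

**Calibration.** The defaults were chosen so the population age-adjusted
correlation between measured psFC and measured percent change is a
strong negative of about −0.85; measured over 150 simulated cohorts
(1950 infants) it is −0.86. Two constraints shaped the calibration.
First, with 10 stimuli and 3-point windows, the per-window realisation
noise of the Pearson correlation (which all network edges share, because
they share the windows) leaves a per-infant psFC measurement SD of about
0.12 that no amount of edge-averaging removes; against a latent SD of
0.26 this attenuation is what keeps the population correlation below
unity even with an almost noise-free amplitude pathway. Second, the
activity mask must not intersect the DPMS (see below), or evoked-tail
leakage both attenuates the association and breaks null fidelity. Under
zero coupling the psFC slope test rejects at 4.5% (600 cohorts),
consistent with its nominal 5% level, and essentially all 13-infant
cohorts generated under the defaults yield a negative age-adjusted r.

## What the generator does and does not emulate

It reproduces the data *structure* the analysis assumes: slow
within-network covariation whose strength varies across infants, evoked
responses with the infant HRF, drift, white noise, optional motion-spike
volumes, optional rendered 4D volumes with weighted masks and
susceptibility-dropout voxels. It does not emulate scanner physics,
realistic motion, cardiorespiratory waveforms, spatial autocorrelation,
or the empirical variance decomposition of infant BOLD (which the source
study does not report); synthetic noise levels are free parameters.
Passing tests therefore demonstrate that the pipeline measures what it
claims on data satisfying its assumptions — not that those assumptions
hold in any given infant data set.

One emergent, realistic artefact is worth noting: the canonical kernel's
support (30 s) exceeds the minimum ISI (25 s), so the undershoot tail of
one trial overlaps the next trial's pre-stimulus window. In cohorts
whose activity mask intersects the DPMS, this leaks an
amplitude-dependent component into pre-stimulus correlations among
active ROIs — enough to inflate the null rejection rate of the
psFC-association test from 5% to about 9%. The pipeline applies no
additional exclusion (none is part of the documented procedure); instead
the generator's default activity mask (SMA, CAU, IPL) lies outside the
DPMS, and the targeted-coupling verification tests do the same for the
network they test. Analyses of real data whose activity map overlaps the
connectivity network inherit this leakage; it is a property of the
design (ISI shorter than the HRF support), not of the implementation.

## Problem sizes used in verification

The verification suite runs the oracle-equivalence checks on 100 random
fixtures per statistic, sign-recovery on 500 default cohorts, null
calibration of the psFC slope test on 1000 zero-coupling cohorts,
edge-dominance on 250 cohorts of 40 infants (largest-|β| ranking across
15 edges is noise-dominated at n = 13), stability-ANOVA calibration on
250 six-infant cohorts, and the shared-weight monotonicity sweeps on
150–450 single-infant draws per level. These sizes keep Monte-Carlo
error comfortably inside the asserted bounds.

## Known limitations

* The psFC estimator is intentionally simple (3-point windows, raw
  averaging); its sampling noise is large and correlated across edges,
  which bounds attainable effect-recovery correlations (see
  Calibration).
* The activity mask is an input; group-level cluster inference is not
  implemented.
* Registration, ICA denoising and segmentation are upstream of this
  pipeline: image inputs are assumed denoised and aligned.
* RM-ANOVA p-values assume sphericity; with three networks and 13
  infants the Tukey comparisons are approximate at best, matching the
  descriptive use they serve here.
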