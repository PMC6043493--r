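---
title: "Comparing voxelwise myelin proxies on a synthetic quantitative-MRI phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing voxelwise myelin proxies on a synthetic quantitative-MRI phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinmetrics)
```

## The problem

Myelin cannot be observed directly by MRI; what can be measured are
quantities that myelin influences — relaxation rates, magnetization
transfer, and T1/T2 contrast. This package implements three voxelwise
proxies of myelin volume fraction (MVF), a common calibration that puts
them on one scale, and the statistics used to ask how well they agree. All
of it runs against a synthetic phantom with known ground truth, so every
stage is testable without scanner data.

## The three proxies

**MT saturation.** A FLASH triplet (T1-weighted: TR 10 ms, flip 13°;
PD-weighted and MT-weighted: TR 24 ms, flip 4°) is inverted voxelwise for
the apparent longitudinal rate, the apparent amplitude, and the fractional
saturation imposed by one MT pulse per TR. The estimators are algebraic
inverses of the rational FLASH approximation
$S = A\,\alpha\,\mathrm{TR}\,R_1 / (\alpha^2/2 + \mathrm{TR}\,R_1 + \delta)$:
on signals generated from that model they recover $(R_1, A, \delta)$ to
machine precision, which the test suite asserts at a 1e-10 relative
tolerance over random protocol draws. Flip angles are accepted in degrees at
every interface and converted to radians internally — the $\alpha^2/2$
small-angle terms are meaningless otherwise.

**Relaxometry MVF.** A four-compartment model (myelin, cellular water, free
water, excess parenchymal water) maps compartment volumes to effective
$(R_1, R_2, \mathrm{PD})$. Free and excess parenchymal water are fixed at
CSF relaxometry ($R_1$ 0.24 s⁻¹, $R_2$ 0.87 s⁻¹, PD 100 %) and the myelin
water $R_2$ at 77 s⁻¹. The full forward kernel behind commercial
implementations is a Bloch-simulation optimisation that is not public; this
package adopts a documented fast-exchange approximation instead — PD-weighted
mean water rates plus exchange terms linear in the myelin fraction
($\Delta R_1 = k\,V_{MY}$ and $\Delta R_2 = k\,V_{MY}\,R_{2,my}/20\,s^{-1}$
with $k$ = 2 s⁻¹) — calibrated once so a white-matter-like state
($V_{MY}\approx0.31$) lands near literature WM values ($R_1$ ≈ 1.15 s⁻¹,
$R_2$ ≈ 12 s⁻¹, PD ≈ 66 p.u.). The inversion architecture is the point, not
the kernel: a lookup grid enumerates every 4-part composition of unity at a
configurable step (0.01 for analysis), stores the forward triples, and each
measured voxel is projected onto the nearest admissible candidate under
per-axis scales (1 s⁻¹, 10 s⁻¹, 25 p.u.) chosen so the three axes contribute
comparably. Candidates above the 40 % physiological myelin ceiling are
excluded from projection, so no estimate can exceed the cap; distance ties
resolve to the lower myelin fraction, keeping the estimator conservative and
deterministic. Nearest-candidate search is exact (a spatial-hash search in
C++), and on noise-free phantoms the round trip recovers truth within one
grid step.

**Calibrated T1w/T2w ratio.** T1- and T2-weighted contrasts are synthesised
from the quantitative maps with the spin-echo equation
$S = \mathrm{PD}(1-e^{-\mathrm{TR}R_1})e^{-\mathrm{TE}R_2}$ (TR/TE 500/10 ms
and 4500/100 ms), then linearly calibrated so each subject's eye and muscle
mode intensities map onto fixed reference modes (eye 28.2/99.9, muscle
58.6/21.1 for T1w/T2w). The calibration line makes the anchor mapping exact
by construction, which the tests verify to machine precision, and absorbs
any linear intensity scaling — the ratio is invariant to per-contrast gains.
Modes are estimated from a fixed-width histogram (Freedman–Diaconis width,
bins centred on multiples of the width, ties to the lower bin): the binning
rule is a package choice made for determinism, since mode estimation has no
canonical convention.

## Transmit-field handling

The dual-angle method measures the local flip-angle scale from two
acquisitions proportional to $\sin\alpha$ and $\sin2\alpha$ via
$\sin\alpha/\sin2\alpha = 1/(2\cos\alpha)$. At a 10° nominal angle the
ratio sits immediately next to the arccosine domain boundary, so the
voxelwise inversion amplifies image noise roughly sixty-fold and the
one-sided domain truncation biases the field upward. Because a transmit
field is smooth by physics, the pipeline fits a low-order polynomial
surface to the ratio data by Gauss–Newton least squares
(`fit_b1_field()`): no voxel is discarded, the noise enters symmetrically,
and on noise-free data the fit reproduces the field to machine precision.
The raw voxelwise map remains available (`b1_smooth = FALSE`).

The fitted field is used twice: the excitation flip angles inside the
estimators are corrected voxelwise (standard multi-parameter-mapping
practice — without it the apparent saturation scales as $1/b^2$ in the
local field $b$), and the empirical residual correction
$\mathrm{MT_{sat}} = \delta_{app}(1-0.4)/(1-0.4\,RF_{local})$ removes the
dependence of the MT pulse's saturation efficiency on the local field. The
phantom's forward model applies exactly that efficiency law
($\delta_{local} = \delta(1-0.4b)/0.6$), so the corrected saturation on a
noise-free phantom is independent of the simulated field to better than
1e-6 — the closure the acceptance suite checks.

## What the phantom emulates, and what it does not

Geometry is deliberately trivial: bilateral axis-aligned 5³-voxel box ROIs
on an 8³ lattice over a CSF background (one ROI id labels both mirrored
boxes, matching bilateral-aggregate analysis), with a pure-tissue 3³ core
and a partial-volume shell that exercises the 0.95 threshold rules;
subcortical grey voxels carry a 50/50 WM/GM split so they pass only the
WM + GM mask, as in real segmentations of subcortical nuclei. Defaults
follow the study conditions the package emulates: 48 WM, 12 subcortical and
20 cortical ROIs, 20 subjects, class MVF means 30.70/17.38/10.57 % with SDs
4.81/4.11/6.07 %.

Each subject draws, per ROI, a shared myelin signal (anatomical profile
fixed across the cohort plus a subject deviation, SD 1.5 %) and two
metric-specific latents: the MT latent adds class offsets (+3.17 %
subcortical, +5.61 % cortical) reproducing the MT metric's flatter
grey/white contrast plus noise (SD 2 %), and the ratio latent adds larger
noise (SD 5.5 %) applied as a multiplicative non-myelin modulation of the
T1-weighted contrast — the ratio is deliberately the loosest myelin
reporter. This shared-signal-plus-metric-noise structure is what produces
the qualitative cohort behaviour the tests assert: the two relaxation-based
metrics correlate more strongly with each other in white matter than either
does with the ratio. Noise is additive Gaussian at 1 % of mean signal
(high-SNR regime; Rician effects are negligible there and Gaussian keeps
the estimator tests analytic). Not emulated: realistic anatomy and cortical
folding, registration and segmentation error, k-space artefacts, motion,
and field inhomogeneities beyond the smooth polynomial transmit surface.
Passing tests therefore demonstrate correctness of the estimators and
statistics, not robustness to those real-data effects.

## Statistics

Correlations are Spearman's rank coefficient pooled over subject × ROI
within a region class (48 ROIs × 20 subjects = 960 white-matter pairs at
defaults). Confidence intervals use the Fisher transform with the plain
standard error $1/\sqrt{n-3}$ — the convention that reproduces the
published interval arithmetic this package's acceptance checks recompute.
For the rank coefficient that interval is mildly anticonservative (its
Fisher-z variance is about $1.06/(n-3)$); `spearman_ci(ci_method =
"bonett")` provides the variance-matched Bonett–Wright interval, and the
coverage test exercises both. Correlation equality uses the independent
two-sample Z test on Fisher-transformed coefficients; because the compared
correlations share a metric, a Steiger-style dependent variant is available
behind `dependent = TRUE`.

Steel–Dwass all-pairs comparisons standardise each pairwise rank sum
(average ranks, tie-corrected variance). For large groups the statistic is
referred to the studentised-range distribution; for small groups the
package enumerates every group assignment exhaustively (C++) and uses the
maximum absolute statistic per arrangement as the simultaneous reference —
the exact small-sample analogue, selected automatically whenever the
arrangement count is feasible (the two paths differ by far more than
rounding at three-to-five per group, so the exact path is not optional
there). Regression and ANCOVA are ordinary least squares: slope equality by
the interaction F test, intercepts compared in the common-slope model when
slopes do not differ.

Calibration is a zero-intercept white-matter-mean scaling: the factor is
the ratio of reference to target means over all WM ROI means pooled across
subjects, making the calibrated WM means equal to machine precision. On the
bundled reference class means the factors evaluate to 8.39 (MT saturation)
and 14.55 (ratio); the 8.39-vs-8.40 discrepancy with the conventionally
quoted value is the rounding of the means entering the division, so the
package computes from unrounded means and reports both.

## Numerical choices and degenerate inputs

Voxels where an estimator's denominator falls below 1e-12 of the signal
scale, where a signal is non-positive, or where the dual-angle ratio leaves
the arccosine domain are flagged `NA` — never silently zeroed — and excluded
from ROI means; ROIs emptied by masking are dropped and logged rather than
emitted as NaN rows, keeping downstream correlations pairwise-complete. The
partial-volume threshold is inclusive at 0.95. The lookup step must divide
unity; steps up to 0.5 are accepted so tiny grids can be enumerated against
combinatorial oracles. Reports round to two decimals; underlying CSVs keep
full precision, and the pooled ROI table is serialised at 17 significant
digits so a compare-stage re-run from disk reproduces the report
byte-for-byte. All randomness flows from explicit seeds (subject s uses
base seed + s; ROI geometry and the anatomical profile use a shared
cohort-level seed), making whole-pipeline runs bit-reproducible.

## Problem sizes

The test suite runs phantoms at 32³–48³ with 12–22 ROIs for unit and
property tests, a 64³ phantom with the full 48/12/20 ROI complement for the
lookup round trip, and two full 20-subject 64³ pipeline runs for the
determinism check; the acceptance script adds a fresh 20-subject cohort.
These sizes keep the complete suite in the minutes range while leaving
every stage at (or above) the structural scale of the study being emulated.

## Known limitations

The forward compartment kernel is an interchangeable approximation, not the
proprietary Bloch-simulated one, so absolute relaxometry-MVF values should
be read as model-consistent rather than scanner-faithful. The ratio
metric's absolute scale depends on the synthetic eye/muscle tissue
parameters. The excess-parenchymal-water pool is carried only as a fourth
composition axis; nothing distinguishes it from free water beyond the
composition. And the phantom's correlation structure is put in by its
generator — cohort-level correlation results validate the pipeline's
behaviour under a known model, never a biological claim.
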