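# myelinmetrics

Quantitative MRI offers several voxelwise proxies for myelin content, and a
recurring question is whether they measure the same thing. This package
implements three of the common proxies end to end and the statistical
machinery for comparing them, exercised on synthetic brain phantoms with
known ground-truth myelin content:

- **MT saturation (MT_sat)** — from a spoiled gradient-echo (FLASH) triplet
  with T1-, PD- and MT-weighting, the apparent quantities are estimated
  voxelwise and corrected for the local transmit field measured by the
  dual-angle method:

  - `R1app = 1/2 (S_T1 a_T1/TR_T1 - S_PD a_PD/TR_PD) / (S_PD/a_PD - S_T1/a_T1)`
  - `A_app = S_PD S_T1 (TR_PD a_T1/a_PD - TR_T1 a_PD/a_T1) / (S_T1 TR_PD a_T1 - S_PD TR_T1 a_PD)`
  - `delta_app = (A_app a_MT / S_MT - 1) R1app TR_MT - a_MT^2/2`
  - `MT_sat = delta_app (1 - 0.4) / (1 - 0.4 RF_local)`, with
    `RF_local` from `sin(a)/sin(2a) = 1/(2 cos a)`.

  These estimators invert the rational FLASH signal model
  `S = A a (TR R1) / (a^2/2 + TR R1 + delta)` exactly — an identity the test
  suite verifies to 1e-10 over random protocol draws.

- **Relaxometry myelin volume fraction (MVF_SyMRI-style)** — a
  four-compartment tissue model (myelin, cellular, free and excess
  parenchymal water; free/excess pools fixed at CSF values R1 = 0.24 s⁻¹,
  R2 = 0.87 s⁻¹, PD = 100 %, myelin R2 fixed at 77 s⁻¹) maps compartment
  volumes to effective (R1, R2, PD). A lookup grid over every composition of
  the unit simplex is inverted by nearest-candidate projection in scaled
  (R1, R2, PD) space; candidates above the 40 % physiological myelin cap are
  inadmissible, so no estimate ever exceeds it.

- **Calibrated T1w/T2w ratio** — T1- and T2-weighted contrasts are
  synthesised from the quantitative maps (spin-echo equation, TR/TE 500/10 ms
  and 4500/100 ms), linearly calibrated against eye and muscle reference
  modes (`I_C = [(E_R-M_R)/(E_S-M_S)] I + [(E_S M_R - E_R M_S)/(E_S-M_S)]`,
  references 28.2/99.9 eye and 58.6/21.1 muscle), and divided.

ROI means are extracted under partial-volume masks thresholded at 0.95 (WM
ROIs by the WM map, cortical GM by the GM map, subcortical GM by WM + GM),
the MT and ratio metrics are calibrated to the relaxometry metric by
white-matter means, and the comparison report mirrors the standard analysis:
per-class means with grey-to-white contrast percentages and their
Steel–Dwass comparison, Spearman correlations with Fisher confidence
intervals per region, correlation-equality Z tests, per-ROI correlations,
and regression with ANCOVA line comparison.

The phantom generator is first-class, tested code: lattice-placed bilateral
box ROIs over a CSF background, per-ROI ground-truth myelin drawn from
class distributions (WM 30.7 %, subcortical GM 17.4 %, cortical GM 10.6 %
by default), quantitative maps from the forward compartment model, a smooth
polynomial transmit-field surface, FLASH triplets and dual-angle B1 images,
partial-volume maps, and eye/muscle calibration structures.

## Worked example

```r
library(myelinmetrics)

cfg <- run_config(
  out_dir = file.path(tempdir(), "demo"),
  phantom = phantom_config(grid_shape = c(32, 32, 32), n_wm_rois = 8,
                           n_subcortical_rois = 2, n_cortical_rois = 4,
                           seed = 7),
  n_subjects = 6, lookup_step = 0.02
)
res <- run_all(cfg)
print(res$report)
```

```
<comparison_report>
  scaling factors: mtsat = 8.249, t1w_t2w_ratio = 12.34
  white-matter Spearman rho:
    mvf_mtsat vs mvf_symri: 0.86 [0.76-0.92] (strong)
    mvf_mtsat vs mvf_t1wt2w: 0.53 [0.30-0.71] (moderate)
    mvf_symri vs mvf_t1wt2w: 0.44 [0.18-0.65] (weak)
```

The scaling factors are the white-matter-mean calibrations of the raw
MT-saturation index (percent units) and the raw T1w/T2w ratio onto the
relaxometry MVF scale; on the reference class means they evaluate to 8.39
and 14.55. The correlation block is the white-matter column of the pooled
correlation table: the two relaxation-based metrics agree most strongly,
while the ratio metric tracks myelin more loosely — the qualitative
behaviour the generator's shared-signal-plus-metric-noise design encodes.
`res$report` also carries the per-class summary (`table1`), the full
correlation matrix with equality tests (`table2`, `table2_ztests`), per-ROI
correlations (`table3`) and the regression/ANCOVA tables (`table4`,
`table4_ancova`); `build_report()` writes them as CSV plus a Markdown
summary, and `autoplot()` / `plot_metric_scatter()` draw them.

A thin command-line wrapper is installed with the package
(`inst/exec/myelincompare`): `myelincompare simulate|compare|run-all
--out DIR [--seed N ...]`.

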