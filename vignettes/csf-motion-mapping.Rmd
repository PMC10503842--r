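---
title: "Methods: CSF motion mapping and choroid plexus perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSF motion mapping and choroid plexus perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfmotion)
```

## The problem

Cerebrospinal fluid (CSF) in the basal cisterns moves slowly and
non-laminarly, too slowly for phase-contrast velocimetry and over
distances too long for spin-labeling of CSF itself. A practical
alternative is to treat the *signal decay* of diffusion-weighted MRI
across a range of low-to-intermediate b-values (0–1000 s/mm²) as a
motion probe: in a voxel whose water moves incoherently, the signal
falls off approximately exponentially in b, and the decay constant —
formally an apparent diffusion coefficient — scales with how much the
fluid moves. In Parkinson's disease, reduced glymphatic/neurofluid
transport is hypothesized; comparing suprasellar-cistern decay rates
between patients and controls, and relating them to choroid plexus
perfusion (a proxy for CSF production), operationalizes that hypothesis.

`csfmotion` implements the full measurement chain for both modalities,
a digital phantom that generates data with known ground truth, and the
cohort-level statistics. Because the source study's images are not
publicly deposited, every quantitative claim the package makes is
demonstrated by parameter recovery on the phantom, not by reanalysis of
patient data.

## Decay-rate mapping

The voxelwise model is the monoexponential

$$ S(b) = S_0 \, e^{-b D}, $$

with $S_0$ the non-diffusion-weighted signal and $D$ (mm²/s) the decay
rate. The fitting chain in `fit_decay_map()` is:

1. **Bulk-motion correction** (`correct_bulk_motion()`): every volume
   is realigned to the first b=0 volume by the integer-voxel
   translation within a ±3-voxel window that maximizes normalized
   cross-correlation. Volumes are mean-removed and shifts are circular,
   which makes the correlation norm independent of the shift, so the
   entire search is evaluated on one FFT cross-correlation surface per
   volume. Sub-voxel motion and rotation are out of scope; the phantom
   injects only integer translations.
2. **Direction combination** (`combine_directions()`): the six
   diffusion directions at each b are combined by their voxelwise
   geometric mean — equivalent to averaging log-signals, i.e. a
   trace-style isotropic decay. For isotropically moving CSF the
   directions are exchangeable, so any symmetric combination is
   unbiased in the noiseless limit; the geometric mean keeps the
   combined signal exactly exponential when the per-direction signals
   are. b=0 volumes are averaged arithmetically.
3. **Voxelwise fit** (`fit_decay_voxel()` / the vectorized map fit):
   nonlinear least squares of the model on the untransformed signal
   scale, initialized from ordinary least squares on the log-signal.
   The initializer is exact on noiseless data; the refinement (a damped
   Gauss–Newton iteration, vectorized across voxels) removes the
   low-signal bias that pure log-linear fitting has on noisy data. The
   two agree to well under 0.1% on noiseless input.

Numerical rules for degenerate voxels: shells with nonpositive signal
are dropped per voxel (not clipped) and counted out of
`n_shells_used`; at least 3 valid shells are required, otherwise the
voxel is invalid; $D$ is constrained nonnegative during iteration and a
voxel whose fit lands at or below the positivity floor of 1e-8 mm²/s
(for example, constant signal across shells) is flagged invalid rather
than reported as zero. $R^2$ is computed on the untransformed scale and
clamped to [0, 1]. ROI summaries (`summarize_roi()`) are arithmetic
means over valid voxels only.

The default protocol (`default_dwi_protocol()`) mirrors the targeted
acquisition: one leading b=0 plus, per direction, a pseudo-randomized
cycle through b = 0, 50, 100, 200, 300, 700, 1000 s/mm² — 43 volumes,
7 shells, 6 directions. b-values are taken as given per volume; they
are never recomputed from gradient physics. All shells enter the fit
with equal weight. No resampling or template normalization is
performed: phantom data, masks and maps share one grid by construction,
so ROI transfer is exact.

## Perfusion quantification

The ASL chain (`quantify_cbf()` and helpers) follows the standard
single-PLD pCASL recipe:

1. **Surround subtraction** (`surround_subtract()`): the series
   alternates control, label, …; each label is subtracted from the
   average of its two neighboring controls (the terminal label uses its
   single neighbor), which cancels linear drift.
2. **Slice-delay correction** (`effective_pld()`): for an ascending 2D
   readout, slice $k$ (0-based) is read out at
   $\mathrm{PLD}_k = \mathrm{PLD} + k \cdot t_{\mathrm{slice}}$. The
   per-slice increment has no universally correct default and must come
   from the acquisition; setting it to 0 disables the correction.
3. **M0 normalization and kinetic-model inversion**: the pair-averaged
   difference $\Delta M$ is divided by the equilibrium magnetization
   image and inverted through the post-bolus single-compartment closed
   form

   $$ \frac{\Delta M}{M_0} = \mathrm{CBF} \cdot
      \frac{2\,\alpha\, T_{1b}\,(1 - e^{-\tau/T_{1b}})\,
            e^{-\mathrm{PLD}_k/T_{1b}}}{6000\,\lambda}, $$

   with $\lambda = 0.9$ mL/g, $\alpha = 0.8$ (background-suppression
   losses folded in), $T_{1b} = 1624$ ms, label duration $\tau = 1800$
   ms and PLD $= 2000$ ms as defaults. Times are handled in
   milliseconds internally; the 6000 factor converts mL/g/s to
   mL/100 g/min. Because the acquisition is single-PLD, the closed-form
   inversion is the standard quantification and the forward expression
   (`forward_kinetic_signal()`) doubles as the test oracle.
4. **Noise floor**: a minimum of 10 mL/100 g/min is applied voxelwise
   *before* ROI averaging (`above_floor`), and `summarize_perfusion()`
   averages above-floor voxels only. Whether the floor should apply to
   voxels or to ROI means is ambiguous; voxelwise-first is the adopted
   interpretation. A consequence worth knowing: when voxel-level
   perfusion SNR is low, the floor truncates the noise distribution
   from below and biases ROI means upward — visible in noisy phantom
   runs, and the reason such a floor exists in the first place.

## The digital phantom

`build_tissue_atlas()` paints a deterministic geometry (seed-jittered
by ±1 voxel): a gray-matter ellipsoidal shell around a white-matter
core, two lateral-ventricle CSF blocks each containing a choroid plexus
sub-block, and a small midline inferior suprasellar-cistern region. The
default grid is 64×64×28, echoing the 28-slice acquisition while
staying desk-scale.

Default ground truth (`tissue_parameters()`) sets each region's decay
rate to the healthy-cohort reference means — white matter 0.00131, gray
matter 0.00138, ventricular CSF 0.00241, suprasellar cistern 0.00328
mm²/s — and choroid plexus perfusion to 31.3 mL/100 g/min. The choroid
plexus *decay* rate has no reported reference value, so it defaults to
a gray-matter-like 0.0014 mm²/s. Baseline signals give CSF the highest
S0 (long T2), and noise is referenced to white-matter S0 so that a
single `snr` number controls the whole phantom.

Noise models: Rician for DWI (magnitude images —
$\sqrt{(S+n_1)^2+n_2^2}$ with $n_1, n_2 \sim N(0, \sigma)$), Gaussian
for ASL volumes (difference-regime data). The source acquisition
publishes no noise characterization, so the working default `snr = 50`
is a free choice, logged wherever it is used. All generators are
bit-reproducible under a fixed seed, via a private RNG stream that does
not disturb the caller's.

What the phantom does *not* emulate: folded cortical anatomy,
partial-volume mixing at region boundaries, cardiac-gated pulsatility,
arterial transit-time dispersion, eddy currents, susceptibility
distortion, or sub-voxel/rotational motion. Recovery tests on the
phantom therefore validate the *estimators* — that the fitting chain
inverts its own forward physics correctly and behaves sanely under
noise — not robustness to every artifact of real data.

## The synthetic cohort

`simulate_cohort()` draws per-subject summary measures matching the
reference study's structure: 32 healthy and 27 PD subjects; per-group
ROI decay-rate and perfusion Normals (suprasellar cistern
0.00328 ± 0.00123 vs 0.00256 ± 0.00094 mm²/s; perfusion 31.3 ± 5.6 vs
31.5 ± 7.9 mL/100 g/min); age 67.6 ± 9.0 vs 66.0 ± 6.8 years; UPDRS
32.4 ± 12.5 (PD only); MoCA 26.5 ± 2.8 vs 24.3 ± 3.9.

The joint structure between suprasellar decay and choroid plexus
perfusion is a Gaussian copula: the target Spearman correlation
$\rho_s$ (−0.51 in PD) maps to the Pearson parameter by
$\rho = 2\sin(\pi \rho_s/6)$, exact for the bivariate normal. In the
healthy group the reference result is a null (*p* = 0.369), not a zero
estimate; the default of exactly 0 is an assumption. No UPDRS–decay
effect is injected by default (the reference trend was
non-significant), though the generator accepts one. No sex
counts are published, so the sex ratio defaults to 0.5 per group.

Draw-level guards keep values physical: decay rates are truncated below
at 1e-5 mm²/s, perfusion at the 10 mL/100 g/min floor, MoCA capped at
30 and rounded. These truncations slightly attenuate tail correlations
at cohort sizes; the copula calibration itself is verified at
n = 100,000, where the sample Spearman lands within ±0.01 of the
target.

## Cohort statistics

Group comparisons of continuous measures use the Wilcoxon rank-sum test
with midranks for ties; with combined n ≤ 12 and no ties the two-sided
p-value comes from exact enumeration, otherwise from the normal
approximation with tie-corrected variance and continuity correction (at
the study's 32/27 the approximation is standard). Exhaustive
computation shows the approximation stays within 0.02 of enumeration
over every attainable statistic once both groups have ≥ 4 members —
which is exactly the regime it serves; below that the implementation is
exact anyway. Categorical contrasts (sex) use the Pearson chi-squared
test without continuity correction; correlations are Spearman
(midranks, t-approximation p); regressions of decay on cohort, age and
sex are fitted as *separate* simple OLS models, mirroring the reference
analysis, with a joint model available but off by default. Significance
is two-sided p < 0.05 with no multiplicity adjustment across rows,
again matching the reference criterion. `cohort_analysis()` bundles
descriptives, comparisons, correlations and regressions, and
`write_cohort_analysis()` serializes them to TSV losslessly.

## Problem sizes used in the test suite

The suite validates at sizes chosen to keep a full run comfortable on a
laptop: most unit tests use a 16³ atlas; the noisy tissue-contrast
property (fitted region medians ordered CSF > gray matter > white
matter at snr = 50) uses 100 replicate 32×32×16 phantoms; rank-sum
calibration uses 1000 null replicates at 32/27; copula calibration uses
one draw of 100,000 pairs. These sizes are the package's own choices
and scale linearly if increased.

## Known limitations

- Motion correction is integer-voxel translation only; real head motion
  includes rotation and sub-voxel components.
- The monoexponential model deliberately ignores the biexponential
  (IVIM-style) structure that very low b-values can exhibit; the decay
  rate is an effective motion index over the sampled b-range, not a
  physiological flow rate.
- Single-PLD quantification cannot separate perfusion from arterial
  transit time; a transit-time change masquerades as a perfusion
  change.
- The voxelwise noise floor biases ROI perfusion upward at low SNR (see
  above); comparisons between groups acquired identically are affected
  equally, but absolute values at low SNR should be read with care.
- The phantom's statistical cohort and its image-level simulators are
  linked only through shared parameter tables; per-subject image
  rendering for a whole cohort is supported but summary-level
  generation is the default.
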