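---
title: "Methods: quantitative FDG-PET assessment of LVAD infection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative FDG-PET assessment of LVAD infection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvadpet)
```

## The measurement problem

A left ventricular assist device presents five anatomically distinct
surfaces where infection can seat: the driveline exit site, the driveline
within the subcutaneous tissues, the pump housing, the inflow cannula and
the outflow graft. FDG-PET/CT localizes infection as focal glucose
hypermetabolism, but visual reading alone does not grade extent. This
package quantifies each component independently from a volume-of-interest
(VOI) delineation, then aggregates a per-patient metabolic burden, and
finally evaluates how well each metric discriminates device-specific
infection from its absence.

The pipeline assumes the VOIs are given (drawn manually or derived from a
labelmap); it performs no registration, no attenuation-correction
modelling and no automated device detection.

## SUV normalization

Voxel values arriving as activity concentration `c` (kBq/mL) are converted
to body-weight standardized uptake values

$$\mathrm{SUV} = \frac{c \,[\mathrm{kBq/mL}] \cdot w \,[\mathrm{g}]}{D \,[\mathrm{kBq}]},$$

with body weight `w` and injected dose `D`, assuming tissue density
1 g/mL. Decay correction to injection time is assumed to have happened at
the scanner, as is standard for clinical SUV reporting, so no decay term
appears. Body-weight (rather than lean-body-mass) normalization is used
because the dosing protocol this pipeline targets is body-weight adapted
(3 MBq/kg). The unit tag (`kBq_per_mL` or `SUV`) travels with the volume
and every downstream operation checks it; converting an already-converted
volume is an error rather than a silent double normalization.

## Threshold segmentation, MTV and TLG

Within a VOI, the metabolically active subvolume is delineated by a
threshold rule, applied *inclusively* (a voxel is kept when its SUV is
greater than or equal to the threshold):

* **fixed absolute** — threshold at a constant SUV, default **3.0**;
* **fixed relative** — threshold at a fraction of the VOI's own SUVmax,
  default **50%**. The reference SUVmax is per component, never global
  across the device, because each component is evaluated independently.

The segmented set gives the metabolic tumor volume
$\mathrm{MTV} = n \cdot v$ (voxel count times voxel volume, cm³) and the
total lesion glycolysis
$\mathrm{TLG} = \mathrm{MTV}\cdot\overline{\mathrm{SUV}}_{\mathrm{seg}}$.
Both identities hold exactly (not to tolerance) in this implementation,
and MTV/TLG are non-increasing in the threshold — properties the
test-suite asserts against a brute-force per-voxel oracle.

Two deliberate design choices where practice varies:

* **No connectivity constraint.** All suprathreshold voxels inside the VOI
  count, regardless of contiguity. Vendor "single-click" tools may keep
  only the cluster around the seed; since the VOI already restricts the
  region, and connectivity behavior of such tools is not publicly
  specified, we do not emulate it. With plateau phantoms the two
  conventions coincide.
* **No partial-volume correction and no background subtraction**, keeping
  the measurement definition minimal and auditable.

The oncology term "metabolic tumor volume" is retained in this infection
context, as is common in device-infection imaging, to avoid inventing a
nonstandard name for a standard quantity.

## Semiquantitative metrics

* **SUVmax, SUVmean** — maximum and arithmetic mean over the full VOI.
* **SUVpeak** — the mean SUV within a 1.0 cm³ sphere (diameter ≈ 12.4 mm)
  centered on the VOI's hottest voxel, intersected with the image grid;
  sphere membership is by voxel-center distance. Peak conventions differ
  across the literature (mean-maximizing placement vs. max-centered); the
  max-centered variant is chosen for determinism and testability, with
  ties broken toward the lowest linear voxel index.
* **LBR** — lesion-to-background ratio: VOI SUVmax divided by the SUVmean
  of a user-supplied descending-aorta blood-pool mask. LBR is invariant
  under global rescaling of the volume.
* **Total MTV / total TLG** — sums over the five device components under
  one rule; the background region never contributes.

Per-patient exports carry both granularities: per-component rows and a
`total` row whose SUV-type entries are the maximum across components.
Whether a cohort analysis should operate per lesion or per patient is a
study-design decision; both paths are provided so the choice is explicit.

## Diagnostic evaluation

Test-positivity is `score ≥ cutoff`, matching the segmentation thresholds'
inclusive convention. The ROC curve is the empirical one over all distinct
score values plus the two trivial endpoints. The AUC is computed as the
trapezoidal area, which equals the tie-corrected Mann–Whitney rank
statistic; the suite checks the equivalence to 1e-12 on a thousand random
instances.

Inference uses DeLong's structural components: the variance of one AUC
for confidence intervals (normal approximation, truncated to [0, 1]) and
the paired covariance for comparing two markers on the same subjects. A
degenerate AUC of exactly 0 or 1 returns a point interval with a warning
rather than an undefined variance. Exact binomial-style intervals used by
some commercial packages are not implemented; interval construction is
therefore not expected to reproduce third-party CI bounds digit-for-digit.

The operating point is chosen by Youden's index `J = se + sp − 1`,
maximized over the observed score values. When several cutoffs tie, the
one with the higher sensitivity wins, then the higher cutoff — leaning
toward sensitivity, which is the natural priority when a missed device
infection is the costly error.

Predictive values are reported at a configurable assumed prevalence
(default **0.60**) through Bayes' rule rather than from raw sample counts,
because cohort class mixes rarely match the clinical population. The
analytic identities (`accuracy = se·π + sp·(1−π)` and the PPV/NPV
formulas) are asserted exactly in the tests.

## Two-group comparison

Group summaries report mean, SD (n−1), median and type-7 interpolated
quartiles (the convention is pinned so IQRs are reproducible). The
comparison test is Welch's unequal-variance t-test or the Mann–Whitney
U-test; `method = "auto"` selects Mann–Whitney when either group fails a
Shapiro–Wilk check at α = 0.05 (the normality-assessment method is our
choice; it is recorded in the result so reports are self-describing).
The Mann–Whitney p-value is exact — full enumeration of the permutation
distribution of U with a symmetric two-sided rule — when the combined n is
at most 12, and a tie- and continuity-corrected normal approximation
otherwise. No multiplicity correction is applied across metrics.

## The synthetic-data module

### Digital phantom

The phantom is a stylized, non-anatomical arrangement of solids (spheres,
boxes, cylinders with arbitrary axes) on a default **96³ grid at 2 mm**
isotropic spacing: background SUV 1.0, a plateau SUV per component, and a
descending-aorta tube (default plateau 1.7, a typical blood-pool value)
as the LBR reference. Geometry is specified in world millimetres with the
origin at the center of the first voxel; voxel membership is by center
point. Default plateaus (exit 6.0, subcutaneous driveline 4.5, pump 5.0,
inflow 3.5, outflow graft 2.5) straddle the absolute threshold so the two
segmentation rules disagree in a known way.

Because plateaus are exact, the generator emits an analytic ground-truth
table (voxel counts, MTV, segmented mean, TLG per component and rule)
valid whenever noise and smoothing are off; the suite requires the
segmentation pipeline to reproduce it *exactly*. Optional additive
Gaussian noise (SUV units, unclamped — clamping at zero would bias plateau
means), optional separable Gaussian smoothing (FWHM in mm, truncated at
3σ with edge renormalization), and an optional plateau ring around the
pump emulating an attenuation-correction artifact make the phantom harder
in controlled ways. What the phantom does **not** emulate: sinogram-level
acquisition, scatter and randoms, reconstruction point-spread,
respiratory motion, or anatomical texture. Passing phantom tests
therefore demonstrates correctness of the measurement definitions, not
clinical performance.

### Cohort simulator

Each lesion metric is log-normal within a group — all the targeted
quantities are positive and right-skewed (median below mean wherever both
are known), which log-normality captures with two parameters solved in
closed form: median/IQR targets give `μ = log(median)`,
`σ = log(q3/q1) / (2 z₀.₇₅)`; mean/SD targets use the moment equations
`σ² = log(1 + cv²)`, `μ = log(mean) − σ²/2`. Default group targets are
the package's built-in two-group table (`cohort_targets()`); default group
sizes are 11 infected vs. 6 non-infected, the cohort scale those targets
describe. Cross-metric dependence uses a single shared standard-normal
latent factor per patient with loading `a = √(2 sin(πρ/6))`, giving each
metric pair a Spearman rank correlation of approximately ρ (default 0.5).
The true within-patient correlation structure is unobservable from group
summary tables, so ρ is an explicit knob, never an estimate.

## Numerical and reproducibility choices

* Thresholds and ROC positivity are inclusive (`≥`) everywhere.
* MTV and TLG are computed by exact integer counting times voxel volume —
  no floating-point volume integration.
* Every stochastic component (phantom noise, cohort draws) takes an
  integer seed; generators restore the caller's RNG state. The
  simulate → quantify → evaluate chain is bit-reproducible at the file
  level given a seed, which the suite checks by checksum.
* Degenerate inputs fail loudly and specifically: empty VOIs for
  max-based statistics, single-class labels, zero background means,
  already-normalized volumes, geometry outside the grid.

## Problem sizes used by the test-suite

Unit and property tests run on 16³ random volumes (oracle equivalence,
100 instances), 64³ phantoms at 3 mm (ground-truth, noise, smoothing and
workflow checks), the full default 96³ phantom for the exact ground-truth
reproduction, 1000 random instances for the AUC/rank equivalence, 1200
replicates for DeLong null calibration, 800 replicates for CI coverage,
2000 replicates for Mann–Whitney null calibration, and 100 000 patients
per group for cohort-target recovery. These sizes make the stochastic
checks statistically sharp while keeping the default suite in the
tens-of-seconds range.

## Known limitations

* VOIs must be supplied; there is no device segmentation from CT.
* SUVpeak follows one (max-centered) of several published conventions.
* The DeLong normal interval can be slightly anticonservative at very
  small n or extreme AUC; the degenerate cases are flagged, not patched.
* The phantom's artifact rim is a plateau ring, not a physics simulation
  of attenuation overcorrection; it suffices to test that rim uptake
  outside the masks never leaks into component metrics.
* Log-normal marginals with a one-factor copula are a modelling choice;
  real lesion metrics may be more heavily tailed or more intricately
  dependent.
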