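---
title: "Uncertainty-aware quantification of aneurysm wall motion from ECG-gated 4D-CTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware quantification of aneurysm wall motion from ECG-gated 4D-CTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallpulse)
```

## The measurement problem

ECG-gated four-dimensional CT angiography reconstructs the cerebral
vasculature at many points of the cardiac cycle (here 20 phases, 0% to 95%
of the R-R interval in 5% steps). In principle this makes the *motion* of an
unruptured intracranial aneurysm wall observable: the sac volume may pulse
with the heartbeat (global volumetric pulsation, GVP), focal wall regions
may bulge (spatial wall pulsation, SWP), and irregular non-periodic wall
behaviour ("deformability") may hint at wall weakness. In practice the
expected motion is a few tenths of a millimetre — at or below the voxel
size — so every observed excursion is a mixture of biology, segmentation
jitter, reconstruction noise and interpolation artefacts. `wallpulse`
implements the full analysis chain with explicit, conservative
uncertainty gates at each decision point, together with a seeded phantom
generator so that every stage can be validated against known ground truth.

## Pipeline overview

A single examination is processed as follows (`run_examination()`):

1. **Segmentation.** Grey-valued volumes are thresholded at 180 HU
   (`threshold_segment()`); binary segmentations are accepted directly.
2. **Surface extraction.** The binary mask is smoothed with a `[3, 3, 3]`
   box filter and refined by linear interpolation
   (`smooth_and_resample()`); the wall surface is the 0.5 isosurface of the
   resulting occupancy field, extracted by marching tetrahedra
   (`extract_isosurface()`). The 0.5 level is the midpoint of a linearly
   smoothed binary field; the refinement factor trades surface resolution
   against run time (5 matches the reference processing chain; tests and
   examples use 2–3).
3. **Centerline and key points.** The box-smoothed volume is re-binarised
   and skeletonised by topology-preserving 3D thinning; the skeleton graph
   (reduced to its minimum spanning tree, short twigs pruned) yields
   endpoints, branch points and the *sac point* — the skeleton point with
   the largest inscribed sphere (`extract_centerline()`). Smoothing before
   skeletonisation matters: thinning a raw noisy mask produces dozens of
   spurious branches.
4. **Neck plane and sac isolation.** For each parent-vessel branch the
   centerline points are projected onto the surface toward the sac point;
   the projected point closest to the neck-adjacent branch point is that
   branch's cut point (`identify_neck_plane()`). With two branches the
   plane passes through both cut points, its normal the perpendicular from
   the cut-point line to the highest dome point — so the plane contains the
   cut-point line and faces the dome. (The alternative reading — a plane
   *spanned* by the cut line and the dome direction — would slice the sac
   vertically and cannot separate sac from parent, so it was rejected.)
   With three or more branches the plane passes through the three cut
   points closest to the neck. `cut_sac()` then clips the closed surface at
   the plane and caps both pieces; sac + remainder volumes add up to the
   original (the suite checks conservation on analytic spheres and
   phantoms).
5. **Displacement mapping.** For every vertex of the reference-phase sac
   mesh (phase 1, the 0% R-R gating origin) and every phase, the
   displacement is the Euclidean distance to the nearest vertex of that
   phase's mesh — non-negative by construction and zero at the reference
   phase (`compute_displacement()`). Nearest-vertex matching is the minimal
   correspondence consistent with an always-positive magnitude formula; it
   is exact for radial motion and for translations smaller than half the
   vertex spacing, but it *underestimates tangential* motion (the aperture
   problem). This is a real limitation of magnitude-only displacement
   mapping, not of the implementation.

## Detection rules and their uncertainty gates

**Size change** (`assess_size_change()`). A follow-up change in mean sac
volume is called significant when
$|V_{mean,2}-V_{mean,1}| > 2\sqrt{SD_1^2+SD_2^2}$, with means and SDs
(n−1 denominator) over the 20 phases of each examination. Applied to the
bundled example cohort of eleven aneurysms this yields 6/11 changed
(5 enlarged, 1 reduced) — the split the suite asserts.

**Noise floor** (`estimate_noise_sigma()`). Phase-to-phase noise is
estimated robustly from successive differences $d_i = V_{i+1}-V_i$ as
$\sigma_{noise} = \mathrm{MAD}(d)/(0.6745\sqrt2)$: division by 0.6745 makes
the MAD a Gaussian-equivalent SD and differencing independent equal-variance
noise doubles its variance, hence the $\sqrt2$. A literal division by 2 is
available (`divisor = "half"`) for compatibility with the ambiguous printed
form of the formula.

**GVP** (`detect_gvp()`). The pulsation amplitude is the raw peak-to-peak
range of the volume curve — no denoising is applied. Pulsation is present
only if the peak-to-peak range exceeds the resolution floor of 3 mm³ *and*
the oscillation (half peak-to-peak) amplitude exceeds $3\sigma_{noise}$.
The half-amplitude convention for the σ-criterion is deliberate: the range
of 20 pure-noise phases already averages 3.7σ, so a three-sigma gate on the
full range would fire on ~80% of noise-only series and would not gate
anything. Even with the half-amplitude reading, the family-wise
false-positive rate of the σ-criterion alone is ~7% (MAD estimation noise
on 19 differences); the 3 mm³ floor is what makes the combined rule
conservative in practice. `sigma_on = "peak_to_peak"` restores the literal
rule.

**SWP** (`detect_swp()`). Vertices with displacement amplitude > 0.3 mm
are grouped into edge-connected regions (vertex areas by barycentric
lumping); regions smaller than 5 mm² are discarded; SWP is present when
the remaining area reaches 5% of the sac surface, *focal* below 20%
involvement and *heterogeneous* at or above it. All four thresholds are
configuration values (`run_config()`), and every threshold echoed in a
report equals the configured value.

**Signal qualification** (`qualify_signal()`). Before dynamic
interpretation a phase-resolved signal must have a positive range and
$SNR = \Delta X / SD_{noise} \ge 3$ (the SNR threshold is configurable; no
canonical value is published, 3 is the package default). A varying signal
whose differences are MAD-zero has an infinite SNR sentinel and qualifies.
Note that for a noiseless sinusoid the difference-based noise estimate is
*not* zero — it sees the harmonic slope — so its SNR is large but finite.

**Harmonic decomposition and deformability** (`fit_first_harmonic()`,
`compute_mdc()`, `classify_deformability()`). The periodic component is the
least-squares first harmonic $\mu + a\sin(2\pi t/n) + b\cos(2\pi t/n)$ over
the equally spaced phases (equal to the first Fourier component, so pure
higher harmonics contribute nothing); fit plus residuals reconstruct the
input to machine precision. Residual variability is summarised by the
residual MAD and interpreted as deformability only when it exceeds the
larger of the Bland–Altman minimum detectable change
($MDC = 1.96\,SD(\textrm{differences})$ from repeated measurements) and any
additional noise floor. Signals that failed qualification return an
explicit *not-evaluable* status — exclusion by reliability criteria, never
a negative finding.

**Exploratory statistics** (`fisher_exact_two_sided()`,
`conditional_or()`, `risk_difference()`, `hedges_g()`, `spearman_rho()`,
`mann_whitney_u()`). The 2×2 machinery is implemented exactly: the
two-sided Fisher p-value by the point-probability method; the odds ratio as
the conditional MLE of the noncentral hypergeometric model with confidence
limits by inverting the one-sided exact tests (boundary tables yield 0 or
∞ points with one-sided intervals); the risk difference with the Newcombe
hybrid-score interval, which remains sensible at 0/n and n/n proportions
where a Wald interval collapses; Hedges' g with the small-sample correction
$J = 1-3/(4(n_1+n_2-2)-1)$ and its normal-approximation interval. Spearman
p-values are exact by full permutation enumeration for $n \le 9$; the
Mann–Whitney p is exact and tie-aware by enumeration for combined
$n \le 12$ and continuity-corrected normal beyond (the plain approximation
deviates from the exact answer by up to ~0.07 at 6 vs 6; with continuity
correction ~0.016). Base R's `fisher.test`, `cor.test` and `wilcox.test`
serve as independent oracles in the test suite, never as the
implementation. No multiplicity adjustment is applied anywhere — the
analysis battery is explicitly exploratory.

## The phantom generator

`generate_phantom()` voxelises a saccular aneurysm as a sphere on a
cylindrical parent vessel, at any number of cardiac phases:

* the parent vessel is a union of cylindrical half-lines meeting at the
  origin — two opposite axes give a straight vessel (two-branch neck rule),
  three give a Y-junction (three-point rule), so both neck-plane code paths
  are exercised;
* the sac radius is modulated as $r(1+\alpha\sin(2\pi t/n+\varphi))$;
* focal patches add a radial offset with a raised-cosine taper to zero at
  the patch rim (continuous surfaces keep voxelisation artefacts from
  dominating threshold tests), each patch with its own phase offset;
* boundary noise jitters the implicit surface within a band around it, per
  voxel and phase, after which the largest connected component is kept —
  emulating segmentation jitter rather than far-field speckle.

Everything is a pure function of the specification (including its seed);
the session RNG state is untouched. Analytic ground truth (per-phase sphere
volumes, patch cap areas) travels with the phantom.

Two phantom configurations reproduce the qualitative dissociation between
the global and the spatial measure: a global α-pulsation with no patch
gives GVP without SWP, and two equal antiphase patches give focal SWP while
the sac-volume excursion cancels below the 3 mm³ floor — shape change
without volume change. A *single* synchronous radial patch cannot
dissociate: any region with amplitude > 0.3 mm over ≥ 5 mm² necessarily
displaces more than $2 \times 0.3 \times 5 = 3$ mm³ peak-to-peak.

Default study conditions: 20 phases; 0.25 mm isotropic voxels for phantom
work (finer than the 0.5 mm in-plane acquisition resolution, so sub-voxel
motion thresholds are testable; the acquisition spacing remains available
as a configuration choice); sac radius 3 mm on a 1.2 mm parent vessel,
matching the small aneurysms (3–10 mm) the framework targets. What the
phantom does *not* emulate: CT noise texture, beam hardening, contrast
dynamics, ECG irregularity, or adjacent-vessel contact — passing tests
demonstrate correctness of the measurement chain, not clinical performance
on real scans.

## Morphology

On the isolated sac, `direct_parameters()` measures dome height H (maximal
signed distance above the neck plane), maximal extent from the neck
centroid H_max, sac diameter L_max, divergence-theorem volumes and surface
areas of sac and sac-plus-parent, and the neck polygon's maximal diameter,
perimeter and area (largest closed loop of the plane section).
`ratio_indices()` derives AR = H_max/N_max, SR = H_max/parent diameter
(parent diameter measured as twice the mean inscribed-sphere radius of
branch centerline points near the neck), UI = 1 − V/V(convex hull),
NSI = 1 − (36π)^{1/3}V^{2/3}/S, BF = W_max/N_max and CP = 1/2 − h*/H, with
W_max the maximal sac width parallel to the neck plane and h* its height.
The NSI constant (36π)^{1/3} is the isoperimetric normalisation that makes
a sphere score exactly zero; it is an argument (`nsi_constant`) for
compatibility with variants that normalise to a hemisphere. All six indices
are dimensionless and invariant to rigid motion and uniform scaling (tested
to 10⁻⁶ relative).

## Numerical choices and edge cases

* Convex hulls of dense isosurface meshes are computed after a
  deterministic stride to ≤ 6000 points (always retaining 13 directional
  extremes); on sphere-like meshes nearly every vertex is a hull vertex and
  the incremental construction would be quadratic, while the stride's
  volume deficit is orders of magnitude below mesh discretisation error.
* Plane sections snap vertices within 10⁻⁹·scale of the plane onto it and
  emit in-plane edges from the positive side only, so cuts through mesh
  rings (e.g. a sphere's equator) chain into closed loops.
* Marching tetrahedra orient every triangle away from the interior at
  emission; meshes of super-level sets strictly inside the grid are
  watertight, so divergence-theorem volumes are exact for the polyhedron.
* Degenerate tables (empty margins) return p = 1 by convention and
  NA effect estimates with a labelled reason; a tangent neck plane or an
  empty segmentation raises an error rather than returning zero-volume
  geometry — manual correction of failing segmentations is out of scope.
* Problem sizes in the test-suite and the acceptance script (0.25–0.4 mm
  phantoms, 2–3× refinement, 500–10 000 Monte-Carlo seeds) were chosen as
  the smallest sizes at which the measured quantities are stable to well
  below their test tolerances.

## Known limitations

* Nearest-vertex displacement underestimates tangential wall motion; a
  regularised registration would be needed to resolve it, and none is part
  of this framework.
* Box smoothing of a binary mask biases strongly curved surfaces slightly
  inward; at 0.25 mm voxels the sac-volume bias is ≈ 0.5% (the suite
  checks < 5% against a constructive-geometry oracle).
* The σ-criterion of GVP detection retains a ~7% family-wise false-positive
  rate under pure noise even in its half-amplitude form; in the full rule
  the 3 mm³ floor dominates for small sacs. Any per-phase three-sigma gate
  applied across 20 phases has a ≥ 5% family-wise rate; a criterion with a
  2% rate would need roughly a 3.5σ gate on the half-amplitude, which is
  not the stated rule and is therefore not the default.
* Baseline–follow-up registration is out of scope; longitudinal comparison
  is via volume summaries only.

## A worked phantom example

```{r example, eval = FALSE}
spec <- phantom_spec(sac_radius = 3, sac_center = c(0, 0, 4),
                     parent_radius = 1.2, voxel_spacing = 0.4,
                     n_phases = 20, global_pulsation_fraction = 0.02,
                     seed = 7)
phantom <- generate_phantom(spec)
report <- run_examination(phantom, run_config(resample_factor = 3))
report
report$gvp
report$indices
```

The sac volume of this phantom swings by ≈ 13 mm³ peak-to-peak (the
analytic value for α = 0.02 at r = 3 mm is 13.6 mm³), comfortably above
both the 3 mm³ floor and the noise gate, so GVP is present; no wall region
passes the spatial thresholds, so SWP is `none` — the global-only regime.
Cohort-level association analysis of per-examination outcomes is then
`run_cohort()`, and `reproduce_study_fixtures()` recomputes the complete
desk-scale analysis of the bundled example cohort.
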