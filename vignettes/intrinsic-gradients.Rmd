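---
title: "Intrinsic gradient analysis of folded cerebellar cortex: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic gradient analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lobulae` analyses task fMRI of the cerebellum in a per-lobule *intrinsic*
coordinate frame instead of scanner space. For each lobule, three
normalised coordinates are defined from boundary surfaces:

* **fissure depth** — 0 at the deep white-matter core of the fissure, 1 at
  the superficial cerebellar surface;
* **mediolateral** — 0 at the lateral free edge of the cortical band, 1 at
  the midline contact with the mirror lobule;
* **posterior–anterior** — 0 at the border with the posterior neighbouring
  lobule, 1 at the anterior border.

Each coordinate is the normalised geodesic position
$r(v) = d_o(v) / (d_o(v) + d_d(v))$, where $d_o$ and $d_d$ are
shortest-path distances from voxel $v$ to the origin and destination
boundary masks, with paths confined to the lobule ROI. Binning $r$ into
$K = 7$ half-open equal-width intervals yields the iso-distance *gradient
steps* used for profile statistics (step 1 = deep / lateral / posterior).

The functional question is whether two tasks with different proprioceptive
demands (MCFT vs SUFF) occupy different positions along these coordinates.
Per subject, a first-level GLM per run yields `MCFT>SUFF` z-maps, combined
across runs by fixed effects; the mean z per gradient step forms a
subjects-by-steps table that a one-way repeated-measures ANOVA tests for a
step effect, with Holm-adjusted pairwise post-hocs. A complementary
whole-cerebellum view computes z-weighted centres of gravity of supra-zero
activation in four quadrant ROIs and paired t-tests of the per-axis
MCFT − SUFF shift.

## Assumptions

* Inputs arrive co-registered: label map, WM probability map, cerebellum
  mask and BOLD runs share one grid. Registration, distortion/motion
  correction and atlas warping are upstream and out of scope.
* Axis convention: axis 1 runs left→right, axis 2 posterior→anterior,
  axis 3 inferior→superior; the origin sits at the centre of voxel
  (1,1,1). Positive Δx therefore means a rightward COG shift, which is
  *medial* in the left hemisphere and *lateral* in the right; the sign
  convention is recorded in every manifest.
* GLM noise is treated as white within runs (no prewhitening; see
  Limitations).

# Boundary-mask rules

All six masks per lobule are pure mask algebra with the 3×3×3
(26-neighbour) structuring element:

| boundary     | rule |
|--------------|------|
| deep         | `WM probability > 0.99` (strict), restricted to voxels 26-adjacent to the lobule |
| superficial  | `dilate₁(lobule) \ cerebellum` |
| anterior     | `dilate₁(lobule) ∩ dilate₁(anterior neighbour)` |
| posterior    | `dilate₁(lobule) ∩ dilate₁(posterior neighbour)` |
| medial       | `dilate₁(lobule) ∩ dilate₁(mirror lobule)` |
| lateral      | outline voxels not claimed by (or adjacent to) any of the above, lateral-side components |

Design choices a maintainer should know:

* **Dilated overlap.** Hard label maps are disjoint, so a strict
  intersection with a neighbouring lobule is empty; "overlap" is taken
  after one-voxel dilation of both masks, which yields the two facing
  voxel layers.
* **Strict WM threshold.** The comparison is `> 0.99`, not `≥`;
  configurable (`wm_threshold`). An empty deep mask is an error, replacing
  visual inspection of the threshold with an explicit check.
* **Precedence.** A voxel qualifying for several masks is assigned by the
  fixed order deep > superficial > medial > anterior > posterior >
  lateral, making the final set pairwise disjoint. The order is arbitrary
  but fixed.
* **Lateral components.** After subtraction, the lateral remainder of a
  folded band consists of two mirror-symmetric free-edge caps. The default
  (`component = "lateral_all"`) keeps every connected component whose
  centroid lies lateral of the lobule centroid: keeping only the largest
  cap (available as `component = "largest"`) would make the mediolateral
  coordinate non-monotone over half the band, because voxels near the
  discarded cap would be "far from lateral" despite sitting on the lateral
  edge.
* **Deep/superficial subtraction for the lateral mask.** Those two masks
  lie outside the lobule, so a literal subtraction from the outline is a
  no-op; the implementation instead removes outline voxels 26-adjacent to
  them. This is a documented interpretation, not asserted to be the
  original analysis's.

# Layering numerics

* **Metric.** Distances are geodesic within `roi ∪ sources` over the
  26-connected graph, edge weight = Euclidean distance between voxel
  centres in mm (so anisotropic voxels are handled). Geodesic rather than
  ambient Euclidean distance prevents layers from jumping across fissure
  gaps in folded geometry; an ambient mode (`metric = "euclidean"`) exists
  as a flagged option.
* **Binning.** Step $s$ covers $r \in ((s-1)/K, s/K]$; $r = 0$ maps to
  step 1. Ties at bin edges resolve to the lower step with tolerance
  1e-9. Equal-*distance* spacing only; equi-volume layering is out of
  scope.
* **Unreachable voxels** (isolated folia tips) get step 0, are excluded
  from profiles, and are counted in the run log; more than 20% unreachable
  is a connectivity error.
* **Verification.** The compiled Dijkstra engine is checked voxel-for-
  voxel against an independent pure-R Bellman–Ford fixed-point oracle on
  random slabs, corridors, blobs and folded annuli (±1 step allowed only
  within 1e-9 of a bin edge), and against the closed form on a 21-plane
  slab (exactly 3 planes per step at K = 7).

# GLM

* **HRF**: difference of two gamma densities parameterised by lobe modes —
  response peak 6 s, undershoot peak 16 s, undershoot ratio 1/6 — sampled
  at 0.1 s, convolved with the condition boxcar, sampled at acquisition
  times, unit-peak normalised. The reference pipeline's exact HRF is not
  published; parameters are configurable.
* **Drift**: Legendre polynomials (default order 1) rather than a
  high-pass filter; intercept last.
* **Inference**: per-voxel OLS; contrast t converted to z through
  tail-stable log-CDF transforms (finite to |z| ≈ 38). A voxel with zero
  residual variance and nonzero effect gets sign(cope)·38 with a warning.
* **Run combination**: "repeated-measures GLM across the four runs" is
  implemented as the standard within-subject fixed-effects combination
  (inverse-variance weighting of copes); random effects across runs are
  out of scope.
* **No spatial smoothing** by default — preserving spatial resolution is
  the point of the intrinsic-coordinate analysis.
* Thresholding is strict: `z > 3.1`.

# Step statistics

* ANOVA decomposition `SS_total = SS_subjects + SS_steps + SS_error`,
  `F = MS_steps / MS_error` on `(K−1, (K−1)(n−1))` df.
* **Sphericity**: Mauchly's W on the orthonormal-contrast covariance with
  the usual χ² approximation (df = K(K−1)/2 − 1). "Correction whenever
  appropriate" is operationalised as: apply Greenhouse–Geisser when
  Mauchly's p < 0.05; both corrected and uncorrected p-values are always
  reported. ε̂ = (Σλ)²/((K−1)Σλ²) over eigenvalues of the double-centred
  covariance, clamped to [1/(K−1), 1].
* **Degenerate inputs**: identical columns give F = 0, p = 1; zero error
  variance with a nonzero step effect is an error; with fewer subjects
  than steps the contrast covariance is singular and Mauchly's p is
  reported as 0 (forcing the conservative corrected p).
* **Missing steps**: a subject with an empty step is excluded from that
  ANOVA with a logged warning, never imputed.
* **Post-hoc family**: all K(K−1)/2 pairwise step comparisons within one
  lobule/hemisphere/direction form one Holm family. All tests are
  two-sided at α = 0.05.
* Everything is verified against a from-first-principles loops-and-
  Gram-Schmidt oracle, and Holm against the hand formula.

# COG analysis

z-weighted centroid over voxels with z > 0 (strict; an unweighted binary
option exists), no cluster-forming step, native space. Whether the
original shift tables are MCFT−SUFF or SUFF−MCFT is ambiguous; here Δ =
cog(MCFT) − cog(SUFF) always, with the axis sign convention logged.

# The synthetic phantom

## What it emulates

* Two exactly mirrored hemispheres of a folded grey-matter band (constant
  radial thickness, default 7 voxels at 48³/1 mm) around a white-matter
  core whose radius varies sinusoidally (default 4 folds) — enough
  non-convexity that naive Euclidean layering would fail.
* ≥3 consecutive lobule labels per hemisphere along the
  posterior–anterior axis, so interior lobules have both neighbours.
* A WM probability that exceeds 0.99 exactly on the deep fissure core,
  decays 0.99 → 0 across the band, and is 0.95 on a non-fissure "peduncle"
  wedge that fills the lateral opening (so the lateral free edges face
  tissue, as in real anatomy, rather than background).
* Four 5-minute runs per subject (90 volumes at TR 3.3 s) of 20 s-ON /
  10 s-OFF blocks, the two conditions alternating *within* each run
  (configurable to one-task-per-run; either arrangement is a
  plausible experimental design, so both are supported). The 2 s finger-cue
  sub-events within ON blocks are not modelled — contrasts are
  block-level, so each ON block is one boxcar.
* Activation: Gaussian blobs (sd 2.5 mm) centred at the voxel nearest the
  requested intrinsic coordinates, amplitude in percent signal change
  around baseline 100, modulated by the HRF-convolved boxcar; Gaussian
  noise, optionally AR(1).

## Stated-world defaults and why

| parameter | default | rationale |
|-----------|---------|-----------|
| grid | 48³ voxels, 1 mm iso | desk-scale testing, not anatomical realism |
| subjects × runs | 8 × 4 | the emulated protocol: eight participants, four runs |
| ON/OFF, TR | 20 s / 10 s, 3.3 s | the emulated block paradigm |
| amplitude | 2.5 % | with σ = 2 % the closed-form expected t at the blob centre is ≈ 8.3 over 4 combined runs (> 6), i.e. clearly detectable at z > 3.1 without being trivial |
| noise σ | 2 % of baseline | typical 7T grey-matter temporal SNR ≈ 50 |
| AR(1) ρ | 0 | prewhitening is not implemented, so the default acceptance world is white; AR(1) is available for robustness exploration |
| subject amplitude jitter | lognormal, sd 0.1 | mild between-subject effect-size variability so subject is a meaningful random factor |
| planted centres | MCFT (0.25, 0.8, 0.5); SUFF (0.75, 0.4, 0.5) | the hypothesised pattern: proprioceptive task deeper in the fissure and more medial |

## What a green test does not establish

The phantom's folding is a smooth sinusoid, its hemispheres are exact
mirrors, its noise is spatially independent and (by default) temporally
white, and its effects are isotropic Gaussians placed exactly on the
intrinsic grid. Passing recovery tests therefore establishes correctness
of the *machinery* (mask rules, layering, GLM, statistics, COG), not
robustness to physiological noise, motion residuals, segmentation error or
real cerebellar geometry. Bit-level equivalence to any particular
external layering tool is likewise not claimed — only the
7-iso-distance-step contract itself.

# Limitations

* No prewhitening: with strong temporal autocorrelation the GLM z-values
  are miscalibrated; the acceptance world uses ρ = 0.
* No motion/distortion simulation or correction; data are assumed
  pre-corrected.
* Fixed-effects (not random-effects) run combination.
* The minimal NIfTI-1 reader/writer covers single-file little/big-endian
  uint8/int16/int32/float32/float64 volumes with diagonal sforms — not
  the full NIfTI feature set (it is cross-checked against nibabel in the
  test suite).
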