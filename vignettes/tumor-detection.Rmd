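---
title: "Detecting tumor tissue in resting-state BOLD fMRI with spatial ICA and DICI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor tissue in resting-state BOLD fMRI with spatial ICA and DICI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldica)
```

## The problem and the model

Tumors disturb local vascularization, vasomotion and perfusion. Because the
BOLD contrast is sensitive to exactly these quantities, voxels inside a
lesion tend to share a coherent low-frequency time course that differs from
the signals of surrounding tissue. Spatial independent component analysis
(ICA) of a resting-state BOLD series can therefore isolate a *tumor-related
component*: a spatial map whose suprathreshold extent delineates the lesion,
obtained from data that were typically acquired anyway for presurgical
functional mapping.

Two practical obstacles stand between that observation and a usable tool:

1. **Model order.** ICA requires the total number of components (TNCs) up
   front. Too few components fuse the lesion with other structured sources;
   too many split it into core and rim fragments. The best order is
   subject-specific.
2. **Component identification.** A decomposition sweep produces hundreds of
   maps; picking the tumor-related one by eye is slow and subjective.

`boldica` addresses both with the Discriminability-Index-based Component
Identification (DICI) statistic. Each z-standardised component map is
binarized (`z > 1`, 26-connected clusters larger than 20 voxels retained)
and compared with a rough binary tumor template:

* the **hit rate** HR is the fraction of template voxels the component
  covers;
* the **false-alarm rate** FAR is the fraction of non-template brain voxels
  it covers;
* **DICI** = Φ⁻¹(HR) − Φ⁻¹(FAR), the classic signal-detection d′.

For every model order on a sweep grid (10 to 100 in steps of 10 by
default), all components are scored and the rank-1 component is that
order's candidate. The candidate with the largest DICI across the sweep is
the final tumor-related component, and its order is the *optimal TNCs*.
Ranks 2–4 and their pairwise DICI differences (ΔDICI) are reported as a
separability diagnostic: a healthy detection shows a clear gap between the
first and second DICI.

### Degenerate rates

A rate of exactly 0 or 1 has an infinite normal quantile. Following
standard signal-detection practice, such rates are pulled half a count
inward, to `1/(2N)` or `1 − 1/(2N)` with `N` the respective denominator; a
*fully empty* binarized map is marked invalid and excluded from ranking
rather than scored. Because the clamp uses the per-rate denominator, DICI
is exactly zero whenever HR = FAR holds at interior values, but the two
clamped boundary rates are not numerically symmetric when the template and
its complement differ in size — a deliberate trade-off in favour of the
standard half-count correction.

## The decomposition engine

Each decomposition at one model order follows the repeated-estimation
scheme used in individual-level presurgical ICA:

1. The masked voxel-by-time matrix (voxelwise means removed) is reduced to
   the leading `tncs` principal components.
2. Infomax ICA — here `ica::icaimax` with the logistic nonlinearity and
   Newton-type updates — is run `n_runs` times (25 by default) from random
   orthogonal initial rotations, seeds `base_rng_seed + i − 1`.
3. Runs are merged RAICAR-style: components are matched across runs by
   greedy maximum absolute spatial correlation against the first run's
   components (ties to the lower index), sign-aligned, and averaged. Each
   cluster's mean pairwise absolute correlation is its *reproducibility*;
   components are ordered by it.

The spatial sign of an ICA map is arbitrary, so each merged map is flipped
to positive skewness (lesions appear as positive z), then z-standardised to
mean 0, SD 1 over mask voxels — the standardisation domain deliberately
excludes off-brain voxels, whose zeros would deflate the SD.

Numerical settings: convergence tolerance `1e-5` on the unmixing update
(Newton iterations typically converge within a few hundred steps; tighter
tolerances occasionally exhaust `max_iter` without visibly changing the
maps), `max_iter` 500. Non-converged runs are kept but flagged. A
single-run decomposition reports reproducibility 1 by convention.

## Template generation

The rough tumor template comes from intensity-based 3D region growth on the
anatomical image, mirroring the familiar GUI VOI tools. From the seed, a
voxel joins when it is 26-connected to the grown region, within
`diff_from_origin` of the seed intensity, within `diff_from_edge` of *some*
admitted neighbour, and within `radius_mm` of the seed. Because the edge
rule accepts any admitted neighbour, the admitted set is the unique
monotone closure of the seed — the result cannot depend on traversal order.
Whether the classic "difference from edge" control is a growth constraint
or a post-hoc polish is ambiguous in the GUI tools, so both
interpretations are available: the parent-difference constraint above plus
one optional morphological closing (`closing_radius_vox`, default 1, 0 to
disable). After closing, the mask is clipped back to the radius bound and
always contains the seed.

The selection is deliberately tolerant of template quality: the template
only anchors *which* component wins, and the phantom experiments in the
test suite verify that the exact truth mask, a one-voxel dilation, and a
deliberately sloppy region-grown template select the same component.

## Preprocessing

Minimal and conventional: the first four frames are discarded
(equilibration), a brain mask is derived from the temporal mean (voxels
above 0.2 × the 98th percentile of nonzero intensities, largest
26-connected component kept), and each frame is smoothed with a 6-mm FWHM
isotropic Gaussian (σ = FWHM / (2√(2 ln 2)) per axis in voxel units).
Smoothing runs over the full field of view with edge renormalisation (the
smoothed all-ones field divides the result), so constants are preserved and
no mask decision leaks into the convolution; masking happens afterwards.
Slice timing, motion correction and coregistration are assumed done
upstream; `motion_gate()` merely applies the conventional exclusion rule
(any translation > 3 mm or rotation > 3°) to externally supplied motion
parameters.

## The synthetic phantom

Every stage is testable without patient data through a generative phantom
(`phantom_presets()`, `generate_phantom()`): a head ellipsoid with constant
baseline 100, a lesion whose voxels share band-limited (0.01–0.03 Hz)
coherent fluctuation, network-like confound ellipsoids with their own
0.01–0.08 Hz courses, per-voxel linear drift, and white Gaussian noise.
All courses are unit-variance, so amplitudes are contrast-to-noise ratios
against `noise_sd = 1`: lesion 3, networks 2, drift 1 — a strongly
vascularised lesion, consistent with the premise that intra-tumor BOLD
signals are highly coherent.

The lesion is heterogeneous: a core and an infiltrative rim carry courses
correlated at 0.9. This is what makes the model order genuinely matter on
the phantom, as it does in real data — at low orders the lesion fuses with
confounds, at the right order it appears whole, at high orders it splits
into partial components. A small peritumoral "vessel" source just outside
the lesion shares the lesion's mixed course, the way draining and feeding
vessels share tumor vasomotion; it guarantees that genuinely tumor-related
components carry some false-alarm load outside the template, as real
components always do.

Three presets fix the study conditions used throughout the tests:

| preset | grid | frames | lesion | purpose |
|---|---|---|---|---|
| `small_fast` | 24³ × 3 mm | 120 | homogeneous, 3 networks | fast screening; full pipeline in minutes |
| `default` | 28³ × 3 mm | 150 | core + rim (r = 0.9), 12 networks, vessel | robustness and baseline comparisons |
| `hard_low_cnr` | as default | 150 | lesion amplitude 1 | stress testing |

What the phantom does *not* emulate: hemodynamic response convolution,
head motion, physiological (cardiac/respiratory) noise, spatial
autocorrelation of scanner noise, susceptibility dropout, and multi-lesion
anatomy. Passing phantom tests therefore demonstrates the *algorithmic*
correctness and stability of the pipeline under its own assumptions, not
clinical performance; the latter requires patient data and expert review.

## Desk-scale test conditions

The full clinical sweep (TNCs 10–100, 25 runs each) is the package
default. The validation suite and the acceptance script run the sweep at
TNCs {10, 20, 30, 40} with 5 runs per order — sized to the phantom's
source count (a 28³ phantom carries ~16 structured sources, so orders
beyond 40 only model noise) and to a desktop CPU. Lesion recovery is
measured as the Dice overlap between the selected component's binarized
map and the ground-truth lesion across 20 phantom seeds; threshold
robustness sweeps the binarization threshold over z ∈ {0.5, …, 3}; template
tolerance swaps the truth template for a grown or dilated one. The suite
asserts only reproducible, seeded computations.

## Design choices where the design was open

* **Binarization connectivity** 26, matching the growth module.
* **Positive tail only**: after the skewness sign convention the lesion is
  positive; negative tails are never binarized.
* **Ties** (equal DICI): lower model order, then lower component index —
  parsimony first.
* **Only rank 1 per order is a candidate**; ranks 2–4 are diagnostics. For
  suspected multi-source lesions the full score table is available via
  `tidy(sel, all = TRUE)`.
* **FAR denominator**: non-template voxels *within the brain mask*, not the
  full field of view — off-brain voxels carry no signal and would dilute
  the rate.
* **Cluster-extent filtering** participates at every threshold of the
  robustness sweep, not only at the default.
* **Seed-correlation baseline**: unweighted mean course over in-sphere
  voxels (voxel-centre membership), Pearson correlation to every mask
  voxel, in-seed voxels included in the map, no cluster filtering.

## Known limitations

* A single winning component is assumed; multiple lesions, or a lesion
  whose compartments are temporally unrelated, will be only partially
  covered (the score table's ΔDICI flags such cases).
* DICI uses spatial overlap only; temporal/spectral features of the
  component are ignored.
* The brain-mask rule is intentionally crude and tuned for phantoms and
  echo-planar mean images, not for skull-stripping quality.
* Very small templates make single-voxel differences in the binarized map
  visible in FAR; the half-count clamp keeps scores finite but boundary
  cases deserve inspection, as the score table makes explicit via
  `n_supra_voxels`.
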