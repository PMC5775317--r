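# boldica

Automatic tumor-tissue detection from resting-state BOLD fMRI by spatial
independent component analysis (ICA) with Discriminability-Index-based
Component Identification (DICI).

## What it does and for whom

Lesions disturb vascularization, vasomotion and perfusion, so the voxels
inside a tumor share a coherent low-frequency BOLD time course that differs
from the surrounding tissue. Given a presurgical resting-state BOLD series
(usually acquired anyway for functional mapping) and a *rough* binary tumor
template, `boldica`:

1. decomposes the series with repeated individual-level spatial ICA at a
   sweep of model orders (TNCs, default 10–100 by 10; 25 randomized Infomax
   runs per order merged RAICAR-style into reproducible components);
2. binarizes each z-standardised component map (`z > 1`, 26-connected
   clusters > 20 voxels) and scores it against the template with

   **DICI = Φ⁻¹(HR) − Φ⁻¹(FAR)**,

   the signal-detection d′ of hit rate (template coverage) against
   false-alarm rate (non-template coverage);
3. selects the component with the largest DICI across the sweep — the
   best-fitted tumor-related component — and its model order, the optimal
   TNCs, and writes a per-order rank-1–4 DICI report with ΔDICI
   separability diagnostics, overlay figures, and NIfTI maps.

The package also provides the intensity-based 3D region-growth template
generator (radius / difference-from-origin / difference-from-edge), the
seed-correlation comparator (6-mm sphere, r > 0.5 / r > 0.8), minimal
preprocessing (frame discard, brain mask, 6-mm FWHM smoothing, motion
gating), and a fully synthetic lesion-bearing 4D phantom with ground truth
so that every stage is testable without patient data. Intended users are
methods researchers and pipeline developers working on presurgical
resting-state analysis.

## Worked example

```r
library(boldica)

spec <- phantom_presets("small_fast")   # 24^3 grid, 3 mm voxels, 120 frames
ph   <- generate_phantom(spec)
prep <- preprocess(ph$series)           # discard 4 frames, mask, 6-mm smooth

sel <- sweep_and_select(
  prep$series, prep$mask, ph$truth_tumor,
  decomposition_config(tncs = 10L, n_runs = 5L, base_rng_seed = 1L),
  dici_config(tncs_grid = c(10L, 20L, 30L, 40L)))
sel
#> <dici_selection>
#>   optimal TNCs: 40, component 4, DICI 4.784
#>   HR 0.997, FAR 0.0194

bin <- binarize_component(best_component_map(sel))
dice(bin, ph$truth_tumor)
#> [1] 0.794
```

The selected component covers 99.7% of the ground-truth lesion while
marking only 1.9% of non-lesion brain voxels (mostly the smoothing halo at
the lesion border, which also bounds the Dice overlap); DICI ≈ 4.8 with a
wide ΔDICI gap to the runner-up, i.e. an unambiguous detection.
`tidy(sel)` returns the rank-1–4 score table per model order, `glance(sel)`
the one-row summary, `autoplot(sel)` the DICI-vs-TNCs curve, and
`write_dici_report(sel, "report.tsv")` the TSV/JSON report.

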