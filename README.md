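# colonyprofiler

Quantitative image analysis for **micropatterned stem cell colonies** —
circular colonies of pluripotent cells (80–1000 µm diameter) imaged as
multi-channel confocal z-stacks during in-vitro gastrulation-like
differentiation. When such colonies pattern, fate markers organise into
concentric domains; the analysis problem is to turn raw fluorescence
stacks into reproducible, per-colony numbers describing that spatial
organisation. The package is aimed at stem cell and developmental
biology labs quantifying micropattern (or embryo section) imaging.

Cell-by-cell segmentation is unreliable at epithelial densities, so all
core quantification here is **voxel-based**:

* **Radial profiling.** Every in-colony voxel *v* with intensity
  *I<sub>c</sub>(v)* in channel *c* is assigned its distance
  *r(v) = ‖xy(v) − x₀‖* from the colony center *x₀* (the centroid of the
  nuclear mask). Voxels are binned into radial bands
  *[kw, (k+1)w)* and each band reports the arithmetic mean
  ⟨*I<sub>c</sub>*⟩. Profiles are averaged across colonies with equal
  colony weight, and displayed either raw, relative to the Hoechst
  profile, or rescaled so the channel maximum is 100 (per timepoint or
  across a time course).
* **Coexpression gating.** For a channel pair (A, B) each masked voxel
  contributes one intensity pair (a, b). A positivity gate per channel
  is the 0.99 quantile of that channel's voxel intensities in a 0 hr
  reference colony (markers absent before differentiation); quadrant
  percentages (−/−, +/−, −/+, +/+) summarise coexpression.
* **Nuclear masking.** A deterministic stand-in for a trained pixel
  classifier: Gaussian smoothing of the Hoechst channel, an automatic
  Otsu threshold, and a logistic mapping to per-voxel nuclear
  probabilities. Externally produced probability masks are accepted too.
* **Morphometrics and sections.** Colony height vs radius from the
  mask's z-extent, nuclei per 100 µm along line segments, inter-nuclear
  distances, and ROI/point quantification of 2D sections normalised to
  Hoechst.
* **Synthetic colonies.** A deterministic generator renders colonies
  with known cell positions, marker domains and noise, so every
  estimator in the package is validated against ground truth.

Results are tibbles designed for dplyr/ggplot2 pipelines, with
`tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

Simulate a 500 µm colony with a central SOX2-like domain (boundary at
125 µm) and an outer BRACHYURY-like ring (boundary at 200 µm), then
recover both boundaries from the image alone:

```r
library(colonyprofiler)
library(dplyr)

spec <- colony_spec(
  500,
  marker_models = list(
    marker_model("sox2", "center_high", 125, 15),
    marker_model("brachyury", "edge_high", 200, 15, level_outside = 0)),
  seed = 1)
sim <- generate_colony(spec)

grid     <- subtract_background(sim$grid, 20)
mask     <- classify_nuclei(grid)
geometry <- estimate_center(mask)
geometry
#> <colony_geometry> center (259.9, 261.2) um, fitted radius 249.3 um

profile <- radial_profile(grid, mask, geometry, bin_width_um = 10)
profile |> tidy() |> filter(channel == "sox2") |> head(3)
#>   colony_id channel bin_start_um bin_end_um mean_intensity n_voxels
#> 1 colony    sox2               0         10          8017.      237
#> 2 colony    sox2              10         20          8027.      469
#> 3 colony    sox2              20         30          8007.      984

recover_boundary(profile, "sox2")       #> 124.1  (truth: 125 um)
recover_boundary(profile, "brachyury")  #> 199.0  (truth: 200 um)

cells <- detect_cell_centroids(mask, grid)
nrow(cells)                             #> 956  (982 nuclei placed)
median(internuclear_distances(cells)$distance_um)  #> 11.1 um
```

The recovered half-maximum boundaries sit within ~1 µm of the generative
truth, the SOX2 profile is flat at its plateau value (8000 a.u.) inside
the central domain, and 97% of placed nuclei are detected with a
realistic epithelial spacing.

`autoplot(profile)` draws the center-to-edge profile;
`plot_coexpression(voxel_pairs(grid, mask, "sox2", "brachyury"))` draws
the density-coloured voxel scatter. Whole experiments run from one
config via `run_pipeline()` (or the `inst/scripts/colonyprofiler` CLI),
which writes stacks, masks, profiles, gates, morphometrics and a JSON
manifest with checksums — rerunning a config reproduces outputs
bit-for-bit.

## Package layout

| Area | Functions |
| --- | --- |
| containers | `voxel_grid()`, `nuclear_mask()` |
| synthetic data | `colony_spec()`, `marker_model()`, `noise_model()`, `generate_colony()`, `generate_timecourse()`, `generate_section_fixture()` |
| I/O | `read_stack()`/`write_stack()`, `read_mask()`/`write_mask()`, `write_profile()`, `write_table()`, `read_roi_json()` |
| masking | `subtract_background()`, `classify_nuclei()`, `detect_cell_centroids()` |
| radial profiling | `estimate_center()`, `radial_profile()`, `average_profiles()`, `normalize_profile()`, `recover_boundary()`, `dot_summary()` |
| coexpression | `voxel_pairs()`, `gate_from_reference()`, `quadrant_percentages()` |
| morphometrics | `height_profile()`, `nuclei_per_100um()`, `internuclear_distances()` |
| sections | `roi_mean()`, `point_cell_quant()` |
| orchestration | `run_pipeline()`, `make_fixtures()` |

See `vignettes/colony-quantification.Rmd` for the methods account:
model assumptions, parameter choices, numerical conventions and known
limitations.
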