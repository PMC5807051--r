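---
title: "Voxel-based quantification of micropatterned colonies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based quantification of micropatterned colonies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyprofiler)
```

# The measurement problem

Micropatterned colonies of pluripotent cells differentiate with
radially organised fate domains: a central population, one or more
concentric rings, and an outer rim, shifting over a 0–72 h time
course. The raw data are multi-channel confocal z-stacks — a Hoechst
(DNA) channel plus one channel per immunostained transcription factor —
at roughly 0.5–2 µm voxels. At epithelial densities (thousands of
nuclei per colony, ~10 µm apart) instance segmentation of single cells
is unreliable, and manual correction does not scale to whole-colony
stacks. Every core quantity in this package is therefore defined on
**voxels**, not cells: radial intensity profiles, coexpression gates
and quadrant percentages all operate on the set of in-colony voxels
selected by a nuclear probability mask. Cell-level detection exists
only for displays (dot plots) and morphometrics (inter-nuclear
distance, nuclei per 100 µm), where a centroid, not a boundary, is
needed.

# Pipeline model and assumptions

The pipeline is: background subtraction → nuclear probability mask →
colony geometry → radial profile / coexpression / morphometrics.

**Background subtraction** is grayscale opening per z-slice per channel
with a disc structuring element (the classical rolling-ball operator).
The ball radius (default 20 µm) must exceed the nuclear diameter
(~6 µm) so that nuclei are treated as foreground and only the smooth
background field is removed. A flat background maps to ~0; output is
clamped non-negative.

**Nuclear masking** stands in for a trained interactive pixel
classifier while keeping its output contract — a per-voxel probability
of "nucleus" in [0, 1]:

1. smooth the Hoechst channel with an anisotropic Gaussian whose
   physical sigma (default 1.2 µm) is divided by the per-axis voxel
   spacing, so smoothing is isotropic in µm even when dz ≠ dx;
2. choose a threshold automatically by Otsu's method on the smoothed
   channel (computed on the max-normalised histogram, so the decision
   is invariant to rescaling the channel by any k > 0);
3. map smoothed intensities through a logistic centred on the
   threshold with width 0.25 × threshold.

The binary "in-colony" region is probability ≥ 0.5, which is exactly
the Otsu decision; higher cutoffs give nested subsets (monotonicity).
The sigma default of 1.2 µm (0.4 × the nuclear radius rather than the
more common half-radius) is deliberate: at ~2 µm voxels a 1.5 µm sigma
measurably blurs the nuclear boundary and misplaces the automatic
threshold relative to the true nuclear surface, while 1.2 µm still
suppresses shot noise. Degenerate inputs (all-zero or perfectly uniform
nuclear channel) are errors, not silently empty masks. Externally
produced masks (e.g. from an interactive classifier) enter through
`read_mask()` and are treated identically downstream.

**Colony geometry.** The paper-scale protocol defines distances "from
the colony center" without defining the center; we use the
probability-weighted centroid of the thresholded mask projected to xy.
This requires no knowledge of the micropattern grid, works on cropped
single-colony stacks, and equals the disc center in the symmetric
limit. Note its one systematic property: deleting a fraction *f* of
the mask at mean lever arm *d* shifts the centroid by *f·d/(1−f)* —
about 7% of the radius for a 10% edge wedge — so grossly incomplete
masks should be inspected before profiling. The fitted radius is the
xy radius enclosing 99% of mask voxels, robust to stray voxels.

**Radial profile.** Bins are half-open [a, b) with the final bin
closed, a true partition: summed bin counts equal the masked voxel
count exactly, and binned means agree with a brute-force per-voxel loop
to 1e-9 relative tolerance (both are standing tests). Radius is
computed in xy only — the colony is a flat disc and height is a
separate measurement — and all z-planes contribute at their xy radius.
The default bin width of 10 µm resolves figure-scale structure
(50–100 bins per colony) without starving bins. Averaging across
colonies weights each colony equally (not by voxel count); bins missing
in some colonies average over the colonies with data and report
`n_colonies`. Normalisation to "max = 100" uses the maximum **bin
mean**, not the maximum voxel — raw voxel maxima are noise order
statistics that grow with colony size, while bin means are stable;
this choice is recorded in the `normalization` column.

**Boundary recovery.** Domain boundaries are read from a profile as the
half-maximum crossing between the profile's extremes, linearly
interpolated between bin centers; a step falling exactly at a bin edge
returns that edge. Flat profiles (no crossing) are errors.

**Coexpression gating.** Gates derive from the 0 hr reference: the
0.99 quantile (type-7) of the reference colony's masked voxel
intensities per channel. The 0.99 default tolerates the rare
spontaneously differentiated cells present in undifferentiated
colonies while keeping the false-positive rate at ~1% per channel.
Positivity is strictly greater than the gate — ties count negative, a
conservative call. Quadrant percentages are exact fractions of the
masked voxel count and sum to 100 by construction. Gates are applied
per colony; pooling across colonies is a caller-side `bind_rows()`
away, and both views are legitimate — per-colony gating is the default
because the reference and test colony then share acquisition
conditions.

**Morphometrics.** Colony height per radial bin is the z-extent of the
mask, using the 2.5th–97.5th percentile of contributing z indices
(inclusive, × dz) so single stray voxels cannot set the height; height
is bounded by the stack depth. Inter-nuclear distances are 3D
center-to-center distances, nearest-neighbour by default or over
supplied pairs (emulating manual adjacent-nucleus measurements).

**Nuclei per 100 µm.** Counting "nuclei per 100 µm" along a side-view
line counts the single row of nuclei visible along that line. A strip
of *fixed* width w around the line collects λ·w nuclei per unit length
(λ = areal density) — linear in λ — whereas a manual row count scales
as √λ, because the visible row is one packing layer thick. The default
strip width is therefore adaptive: the median nearest-neighbour
distance of the supplied cells, i.e. the thickness of one nuclear row.
With it, quadrupling areal density doubles the linear count, exactly
the relationship that links areal density changes to linear counts.
A fixed `strip_width_um` remains available for counting within a
physical optical-section thickness.

**Section quantification.** ROI means use pixel centers inside the
polygon by the even-odd rule; Hoechst normalisation divides by the
Hoechst mean over the *identical* pixels, making the ratio invariant to
global intensity scaling. Per-cell quantification uses a disc of
default radius 5 µm (one nucleus at typical section magnification) and
summarises groups as mean ± sample SD (n − 1 denominator). ROIs are
JSON files — manual selections are recorded once and the arithmetic
reruns exactly.

# The synthetic colony generator

The generator is the package's source of ground truth, emulating the
study's imaging data closely enough that every estimator can be
validated without the original microscopy.

* **Geometry.** Colony diameters 80–1000 µm on a padded field; voxels
  default to 2 × 2 × 1 µm (512-format at 20×); 16-bit intensity scale
  (the acquisition bit depth is a package choice — source data report
  arbitrary units).
* **Cells.** Poisson-disc (dart-throwing) placement with minimum
  spacing max(0.7/√ρ, 5.5 µm): spacing scales with density ρ like an
  epithelium, and the 5.5 µm floor encodes that nuclei cannot overlap —
  densities violating it raise an infeasible-spec error. The default
  density of 5 cells / 1000 µm² (~12 µm spacing) represents an
  epiblast-like monolayer before densification; a four-fold increase
  (20 / 1000 µm²) is the packed 24 h regime and remains placeable.
* **Nuclei.** Anisotropic Gaussian blobs (σxy = 3 µm, σz = 2 µm)
  truncated at 3σ, additive where they overlap, peak 10 000 a.u.
  Monolayers sit at mid-stack; diameters ≤ 140 µm default to two cell
  layers and an optional annular ridge raises the local layer count
  (volcano-like height profiles).
* **Markers.** Domain models (uniform, center-high, edge-high,
  annulus) with logistic boundaries of tunable sharpness; each *cell*
  draws one true level at its radius — nuclear-localised staining —
  painted as a constant over the cell's blob support, nearest cell
  winning contested voxels. Salt-type misexpression swaps a cell's
  level with the stated probability.
* **Noise.** Additive background (optional planar tilt), shot-like
  noise with variance = `shot_scale` × mean, Gaussian read noise;
  clipped to [0, 65535] and quantised. With noise off, rendered marker
  intensities equal assigned levels exactly. Defaults (background 200,
  shot scale 2, read sigma 30) give mid-hundreds noise on a
  10 000-count signal, a realistic confocal regime.
* **Ground truth** records cell centroids, per-cell true levels, true
  boundary radii, colony center and the nuclear region — defined once
  as the **18% isophote** of the noise-free nuclear channel
  (Mahalanobis ~1.85σ for an isolated blob). That isophote is the
  generator's definition of "inside a nucleus" at this resolution; it
  marks the steep flank of the blob profile where an automatic
  intensity threshold places the nuclear surface, and it is the
  reference for the mask-fidelity requirement (voxel F1 ≥ 0.95
  noise-free).
* **Determinism.** One integer seed drives placement, misexpression
  and noise; the same spec and seed give bit-identical TIFFs. A time
  course shares the placement seed across timepoints and varies only
  level multipliers and boundary shifts, so fold changes are exact in
  truth.

What the generator does **not** emulate — and hence what passing tests
do not certify on real data: optical point-spread blur beyond the blob
shape itself, chromatic and stage registration error, intensity
attenuation with depth, autofluorescence structure, stitching seams of
tiled acquisitions, nuclear shape variability and mitotic figures, and
emergent (signalling-driven) domain formation — domains are prescribed,
not emergent. Small-colony 3D growth is approximated by stacking cell
layers, not by true aggregate morphology.

# Validation sizes and results

The test suite validates each stage on synthetic colonies where truth
is known, at sizes chosen to exercise the paper-scale geometry while
keeping a full run around three minutes on one CPU: oracle and
conservation checks on random small grids; flatness (inter-bin CV
< 5%) on a 1000 µm colony at 2 µm voxels; boundary recovery
(three domains, boundaries 250/400 µm, sharpness 15 µm) on
10 seeds × 5 colonies of 1000 µm at 4 µm voxels, recovered within
±10 µm (one bin) in every seed; a 2-fold central-marker reduction
recovered within 10%; a 30% double-positive fraction recovered within
2 percentage points from >10⁵ voxel pairs gated at the 0 hr 0.99
quantile; mask F1 ≥ 0.95 (noise-free) and centroid precision/recall
≥ 0.9 (default noise) on 500 µm colonies; lattice, Poisson-density and
volcano-ridge morphometrics; exact section arithmetic; and bit-level
pipeline determinism. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

# Known limitations

* The center estimate assumes a roughly complete mask (see the lever-
  arm formula above); it is not robust to losing a large sector.
* `recover_boundary()` assumes one dominant rise or fall; annular
  profiles need per-flank calls on the rising and falling channels.
* Otsu-based masking assumes a bimodal smoothed-intensity histogram;
  extremely sparse or saturated fields may need an external mask.
* Height uses mask extent, so it measures the nuclear layer span, not
  membrane-to-membrane colony thickness.
* HDF5 mask containers are not supported; masks persist as 32-bit
  float TIFF (round-trips at float32 precision, ~1e-7).
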