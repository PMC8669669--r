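---
title: "Methods: temporal projection imaging and mesh morphometry of CAM intravital video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal projection imaging and mesh morphometry of CAM intravital video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cammesh)
```

## The measurement problem

In transilluminated intravital video of the chick chorioallantoic membrane
(CAM), capillaries are nearly invisible in any single frame: the only
reliable optical signal is the *temporal fluctuation* of light absorbance as
red blood cells stream through the lumen. cammesh turns a short video
(seconds at ~50 fps) into three image products and a set of quantitative
descriptors:

1. a **vessel image** — the per-pixel temporal standard deviation (SD) of
   intensity, high wherever red cells modulate absorbance;
2. a **perfusion image** — the per-pixel cumulative amount of intensity
   change, a semi-quantitative relative flow map;
3. a **network segmentation** — vessel mask, 1-px centerline skeleton, and
   labeled avascular tissue islands, with morphometry (diameters, densities,
   island statistics) per field of view.

A landmark module tracks the area of user-marked quadrilateral test regions
across repeated scans, and a synthetic-scene generator provides ground truth
so that every stage is testable without recorded data.

## Motion correction

Frames are aligned by two-dimensional image correlation of a high-contrast
reference square. Each frame *t* is matched against the square's content in
frame *t − 1* at its last tracked position, searching integer shifts in a
window of radius `max_shift_px` around the previous displacement; the
displacement is accumulated and expressed relative to frame 0, and all
frames are shifted by the negative of their displacement.

Design points, in order of consequence:

* **Consecutive-frame matching.** Matching all frames against the frame-0
  patch fails whenever moving red-cell texture carries most of the patch
  variance: that texture decorrelates within a few frames, and the
  correlation peak collapses. Structure that persists over a single frame
  interval (tissue, vessel walls, illumination pattern) dominates the
  one-step correlation, so consecutive matching is robust. The price is that
  single-frame errors could accumulate; for integer displacements of rigid
  scenes recovery is exact, and the per-frame peak correlation is kept in
  the displacement trace for QC.
* **Integer shifts only.** Sub-pixel interpolation would smooth intensities
  and bias the SD statistic downward near edges; the paper's protocol aligns
  whole pixels and so does cammesh.
* **Zero-normalized cross-correlation (ZNCC)** makes the match insensitive
  to slow global illumination drift. Ties in the correlation peak are broken
  by the smallest `|d_row| + |d_col|`, then lexicographically — deterministic
  by construction.
* **Valid-region cropping.** After shifting, only the maximal rectangle
  covered by *every* frame is kept. Padding values of any kind would leak
  into the temporal statistics.
* A frame whose best correlation falls below `min_peak_corr` (default 0.3)
  aborts with an error naming the frame: this catches drift beyond the
  search radius or a lost reference.

The reference square is either user-supplied (`reference_square = c(row,
col, size)`, 0-based) or auto-selected as the stride-searched square of
maximal intensity SD. 256 px is the conventional size for full-resolution
recordings; any size that fits the frame is accepted so that small test
scenes can be processed identically.

## Temporal projections

For aligned frames \(I_t(x)\), \(t = 0..T-1\):

* **Vessel image:** \(\mathrm{SD}(x) = \sqrt{\tfrac1T \sum_t (I_t(x) -
  \bar I(x))^2}\). The *population* (divide-by-T) convention is used; the
  choice is a pure rescaling and is irrelevant after normalization, but it
  is fixed so oracle tests are exact. The SD reflects only the extent of
  intensity change, never its frequency — it is invariant to permuting the
  frames.
* **Perfusion image:** \(P(x) = \sum_t |I_{t+1}(x) - I_t(x)|\). Absolute
  successive differences are summed: a *signed* sum would telescope to
  \(I_{T-1} - I_0\) and discard the flow information entirely, so the
  absolute value is the only reading consistent with the intended
  amplitude-times-frequency interpretation. The witness pair — the pixel
  series (0, 0, 10, 10) versus (0, 10, 0, 10) — has equal SD (5) but
  perfusion values 10 versus 30, and is asserted in the tests.
* **Normalization** divides by the image maximum. The minimum is *not*
  subtracted: both statistics have a natural zero ("no change"), and the
  all-zero image maps to itself (with a warning). Normalized products are
  relative levels for one recording only — never absolute flow.
* **Pseudo-color**: a fixed 256-entry perceptually-ordered map
  (`grDevices::hcl.colors(256, "viridis")`, dark blue = low to yellow =
  high), deterministic across runs; each image is normalized to span the
  full range before mapping.

Both statistics need at least 2 frames; fewer is a validation error.

## Segmentation

The SD vessel image is segmented in four steps:

1. **Gaussian enhancement** (`gaussian_sigma_px`, default 1 px): separable
   convolution with reflective boundaries, implemented in-package so that
   mass is conserved and the boundary rule is exactly as stated.
2. **Double threshold**: the union of a global Otsu threshold (main
   vessels) and a local mean threshold `pixel > mean_w(pixel) −
   local_offset` over an odd window (`local_window_px`, default 51 px at the
   10× scale; `local_offset` default −0.02 on the unit-normalized image, i.e.
   the threshold sits just above the local mean). The union is always a
   pixelwise superset of the global-only mask under identical speck pruning
   (components < `min_speckle_px` are dropped). A flat image has no defined
   global threshold and yields an empty mask with a warning.
3. **Skeletonization**: iterative thinning that deletes only *simple*
   points (8-connected foreground / 4-connected background), in four
   directional subpasses with the candidate set frozen per subpass and
   simplicity re-checked at deletion time, protecting curve endpoints.
   Because every deletion is of a simple point, connected-component count
   and Euler number are preserved *exactly* — this invariant, not any
   particular thinning schedule, is the contract, and it is asserted against
   an independent flood-fill oracle on hundreds of random masks.
4. **Tissue islands**: avascular regions fully enclosed by vessel
   foreground, i.e. the holes of the mask (4-connected background not
   reaching the border; border-touching background is excluded because
   enclosure cannot be established). Two morphological passes with a disk of
   radius `morph_radius_px` clean the result: a *closing* of the vessel mask
   first seals hairline breaks in thin capillary walls (which would
   spuriously merge neighboring islands), then an *opening* of the holes
   removes ragged edges; islands below `min_island_area_px` are dropped.

Connectivity is one convention everywhere: 8-connected foreground,
4-connected background, for components, holes and the Euler number.

**Morphometry** per ROI: vessel area fraction; skeleton length density
(skeleton pixels per pixel², per µm when the pixel size is known); island
count and island-area mean/CV; vessel diameter sampled along the skeleton as
`2·EDT − 1` (EDT = Euclidean distance transform of the mask), excluding
skeleton pixels within one local radius of branch points to reduce junction
bias — the `−1` term makes a 3-px-wide bar measure 3 px rather than 4 under
the discrete EDT convention; and perfusion heterogeneity, the CV of
perfusion values over vessel pixels (scale-invariant, so either raw or
normalized perfusion may be passed). CVs are reported as missing when
undefined (fewer than 2 values); an empty skeleton produces a zero record
with a warning.

Defaults for the threshold and morphology parameters are calibrated on the
package's own simulator (phase-I renders, scanning sigma and offset against
mask Dice and island-count exactness) because the source protocol does not
state them; they are exposed in `analysis_config()` and in the TOML-style
config file.

## Area dynamics

Four landmarks per region (vessel junctions or branch points), re-identified
manually at each timepoint, define a quadrilateral test region. Its area is
the shoelace formula on the ordered corners (orientation-independent; a
self-intersecting order is rejected with a hint to reorder). The relative
area trace starts at exactly 1. Capillary density inside a quad restricts
the segmentation to the rasterized quad interior; rasterization uses a
pixel-center-inside, half-open even-odd rule so that quads tiling a region
partition its pixels exactly — making density additivity a testable
identity rather than an approximation.

## The synthetic scene generator

`generate_mesh_scene()` builds a jittered rectangular lattice of capillary
segments enclosing polygonal tissue islands — a "Voronoi-style" isotropic
mesh in the qualitative sense only; no claim is made that its geometry
matches measured CAM networks. Four presets encode the remodeling sequence
from isotropic mesh to established vessel:

| preset | mesh | islands in the pathway | flows |
|---|---|---|---|
| I | uniform capillaries (diameter CV ≈ 0.03) | full complement | homogeneous |
| II | one horizontal chain ×1.8 diameter | shrunken | ×3 in the pathway |
| III | chain merged into one wide channel | ≤ 2 residual "pillar" islands | ×6 channel, ×0.7 capillaries |
| IV | wider channel, no residual islands | none; flanking islands merge pairwise as shared walls regress | ×10 channel, ×0.4 capillaries |

The declining capillary flow factors in III/IV encode the observation that
relative capillary flow falls as flow concentrates in the maturing vessel;
the pairwise island merging in IV encodes island enlargement by capillary
rarefaction in adjacent regions.

`render_video()` renders red-cell passage as dark absorbance particles
advected along each segment at flow-scaled speed, with:

* per-particle contrast \(\propto (d_0/d)^{0.4}\) — inversely related to
  diameter, so the smallest vessels fluctuate most;
* particle count per segment \(\propto L \cdot d^{1.75} d_0^{0.25}\) — the
  optical column grows sub-quadratically with caliber (transmitted-light
  absorbance saturates), which also keeps wide-channel pixels away from
  0-intensity clipping that would truncate their fluctuations;
* counts drawn Poisson with a floor of `min(3, ceiling(lambda))` per
  segment: recorded fields of view are perfused ones, and a transiently
  empty capillary is indistinguishable from tissue in every statistic;
* per-segment flow direction randomized — a mesh with all flows in one
  direction would advect its whole texture coherently and bias
  consecutive-frame correlation;
* a *static* smoothed-noise texture field (`static_texture_sd`, default 8)
  emulating tissue structure and uneven illumination: constant over time, it
  anchors registration while being exactly invisible to the SD and
  cumulative-change statistics;
* zero-mean Gaussian flicker restricted to avascular tissue
  (`tissue_flicker_sd`, default 1.5) — the minimal model of the documented
  perfusion-image artifact (small positive perfusion values in avascular
  areas); sensor noise everywhere (`sensor_noise_sd`, default 2);
* scripted (not random-walk) global integer drift, so registration recovery
  is checked exactly, not statistically;
* intensities quantized to the 8-bit range [0, 255]; defaults of 200 frames
  at 50 fps mirror a 4-s recording.

Scenes are deterministic given their seed; renders are bit-identical given
scene plus parameters, and truth rasters (lumen mask, island labels,
drift script) are independent of the render seed.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: non-rigid tissue deformation and focus drift
(only rigid integer drift is modeled); rouleaux and pulsatile flow;
hierarchical arterial/venous trees beyond a single emergent channel;
vessel-wall optics; temporally correlated flicker. Results on real
recordings depend on those factors; the simulator establishes correctness of
the computation, not field performance.

## Pipeline and QC

`run_pipeline()` composes read → align → project → segment → measure and is
deterministic given inputs and config (all randomness lives in the simulator
seeds). The QC report carries the displacement trace, the parameters used,
and the fraction of total perfusion signal outside the vessel mask — the
operational indicator of the tissue-flicker artifact: zero in a noise-free
render with flicker off, strictly positive with flicker on.
`compare_timepoints()` reports per-ROI deltas and ratios only; ratios with a
zero baseline are missing values, and no inferential statistics are
computed. Stage caching was considered and rejected: the pipeline is
single-pass and deterministic, and cache state would add failure modes
without measurable benefit at these problem sizes.

Interfaces: multi-page TIFF and uncompressed 8-bit AVI in (a minimal RIFF
reader/writer is included; compressed AVI is rejected with a clear message);
8-bit PNG plus lossless 16-bit TIFF out for images, CSV with header for
tables, flat TOML-style `key = value` text for configs. All user-facing
coordinates are 0-based `(row, col)` with half-open intervals. A thin CLI
(`inst/cli/cammesh`) exposes `analyze`, `simulate` and `area` over these
functions.

## Problem sizes and numerical choices in the tests

The test suite exercises registration on 64×64×20 textured stacks with
drift up to ±4 px (exact recovery noise-free; ≥95/100 exact under sensor
noise), projections against brute-force oracles on 50 random small stacks at
1e−9, thinning topology on 200 random masks against an independent
flood-fill Euler oracle, and the full pipeline on five 512×512×100 phase-I
renders (mask Dice ≥ 0.80 against ground truth, exact island counts, and
per-island Jaccard around 0.9 at default noise). Phase-trend checks run at
256×256×60 per preset and seed; the perfusion-heterogeneity comparison
(phase IV vs I) uses 384×384 fields, where the emergent vessel occupies a
realistic minority of vessel pixels — in very small fields the channel
dominates the vessel-pixel population and compresses the CV. These sizes are
the package's chosen study conditions and are stated here so results are
interpreted at the scale they were established.

## Known limitations

* Rigid, integer, in-plane motion only; the tissue-flicker artifact is
  reported, not corrected — consistent with the upstream protocol's own
  caveat.
* Otsu assumes a bimodally distributed enhanced image; fields that are
  nearly all vessel or all tissue will degrade the global threshold (the
  local threshold and the QC trace are the guardrails).
* Diameters from `2·EDT − 1` are biased near junctions despite the
  branch-point exclusion, and quantized at ±1 px.
* Phase presets are static snapshots for testing descriptors; the package
  does not classify fields into phases, and no biological dynamics between
  phases are simulated.
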