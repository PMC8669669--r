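# cammesh

Quantitative image analysis of intravital video recordings of the chick
chorioallantoic membrane (CAM) microvasculature, for researchers studying
capillary-mesh remodeling and angiogenesis in transilluminated 2-D vascular
beds.

Single frames of such recordings show almost nothing: capillaries become
visible only through the light-absorbance fluctuations of passing red blood
cells. cammesh converts a short video (seconds at ~50 fps) into the two
temporal image products that make the network measurable, then extracts and
quantifies the vessel network:

* **Motion correction** — per-frame integer displacement of a high-contrast
  reference square by zero-normalized cross-correlation of consecutive
  frames, expressed relative to frame 0; frames are shifted back and cropped
  to the region covered by every frame.
* **Vessel (SD) image** — per-pixel temporal standard deviation
  `SD(x) = sqrt(mean_t (I_t(x) − mean(I(x)))²)`: high in perfused lumen, low
  in avascular tissue; invariant to frame order.
* **Perfusion image** — per-pixel cumulative intensity change
  `P(x) = sum_t |I_{t+1}(x) − I_t(x)|`: amplitude × frequency of change,
  a semi-quantitative relative flow map, rendered in pseudo-color.
* **Segmentation** — Gaussian enhancement, then the union of a global Otsu
  threshold and a local mean threshold; topology-preserving thinning to a
  1-px skeleton (component count and Euler number preserved exactly);
  tissue islands as the enclosed holes of the vessel mask, cleaned by
  closing/opening and an area filter.
* **Morphometry** — vessel area fraction, skeleton length density, island
  count and area statistics, vessel diameters (2·EDT − 1 along the skeleton,
  away from branch points), and perfusion heterogeneity per ROI.
* **Area dynamics** — shoelace area of four-landmark test regions tracked
  over repeated scans, plus capillary density inside each region.
* **Synthetic CAM scenes** — a ground-truthed generator (polygonal capillary
  mesh around tissue islands, red-cell particle advection, scripted drift,
  tissue flicker, sensor noise) with phase presets I–IV spanning isotropic
  mesh → preferential pathway → emergent vessel → established vessel, so the
  whole pipeline is testable end to end.

## Worked example

Simulate a phase-I (isotropic mesh) recording with ground truth, run the
full pipeline, and score the recovery:

```r
library(cammesh)

scene <- generate_mesh_scene(c(384, 384), phase_preset = "I", seed = 1)
rv    <- render_video(scene, render_params(n_frames = 100, seed = 2))

res <- run_pipeline(rv$stack, analysis_config())
res$morphometry
#>   roi_id area_fraction skel_len_density n_islands island_area_mean
#> 1    roi     0.2758247       0.05373806       121         648.9504
#>   island_area_cv diam_mean_px   diam_cv  perf_cv timepoint_h
#> 1      0.1064343     4.802266 0.1246313 0.513146          NA

scores <- truth_metrics(rv$truth, res$segmentation, trace = res$trace,
                        valid_region = res$valid_region)
sprintf("Dice %.3f | island count error %d | min island Jaccard %.2f",
        scores$dice, scores$island_count_error, min(scores$island_jaccard))
#> "Dice 0.862 | island count error 0 | min island Jaccard 0.92"
```

Reading the numbers: 27.6% of the field is vessel lumen; the skeleton packs
0.054 px of centerline per px² of tissue; all 121 tissue islands of the
generated mesh are recovered (count error 0), each overlapping its true
polygon with Jaccard ≥ 0.92; capillary diameters average 4.8 px with CV 0.12
(the generator draws them near 4 px, and the mask carries ~1 px of
threshold halo); the segmented lumen matches the rendered truth with Dice
0.86. `run_pipeline(..., out_dir = "out")` additionally writes the vessel and
perfusion images (8-bit PNG + lossless 16-bit TIFF), the pseudo-color
perfusion map, masks, skeleton, island labels, the displacement trace, the
morphometry CSV, a `qc.json` (including the fraction of perfusion signal
outside the vessel mask — the indicator of the tissue-flicker artifact), and
a manifest.

Real recordings enter through `read_stack()` (multi-page TIFF or
uncompressed AVI), landmark coordinates through `read_landmarks()` (CSV of
`timepoint_h, point_index, row, col`), and parameters through
`analysis_config()` or a flat TOML-style config file. A thin command-line
front end is installed at `inst/cli/cammesh`
(`cammesh analyze <video> --config cfg.toml --out DIR`,
`cammesh simulate --seed N --out DIR`, `cammesh area --landmarks pts.csv`).

See the methods vignette (`vignettes/cammesh-methods.Rmd`) for the models,
parameter semantics, simulator design, and known limitations.

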