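# dic4d

4D reconstruction and motion analysis of multicellular aggregates growing in
transparent 3D gels, from long-term time series of DIC (differential
interference contrast) optical sections.

Cells embedded in a basement-membrane gel multiply into aggregates that — in
tumorigenic preparations — move, deform, and coalesce over days to weeks.
Because DIC imaging carries no phototoxic load, the same field can be
optically sectioned (e.g. 150 sections through 1.5 mm at 10 µm steps) every
30 minutes for 17 days or longer. This package turns such recordings into
quantitative biology, for researchers studying aggregate coalescence,
3D motility, and the effects of perturbations (antibodies, drugs) on them:

* **Detection** — per-section segmentation of in-focus object regions by a
  local-complexity bitmap: the complexity at a pixel is the windowed
  population standard deviation of intensity, high on in-focus DIC
  structure; auto-thresholding by between-class variance, morphological
  cleanup, and window-bias compensation.
* **Reconstruction** — stacked detections become watertight faceted solids:
  the exact 0.5-level surface of the voxel occupancy field, adaptively
  merged where flat (fewer facets, identical volume), then vertex-smoothed
  with a shrink-compensated two-phase scheme. Manual outlines are
  beta-spline smoothed and meshed through the same route.
* **Tracking** — overlap-first frame linking, coalescence detection with an
  overlap threshold and a volume guard, slash-coded lineage identifiers
  (aggregates 6 and 7 coalesce into "6/7", which plus 5 becomes "5/6/7"),
  and field-edge entry/exit bookkeeping.
* **Quantification** — the per-timepoint 3D parameter suite: aggregate
  count, percent original aggregate number (edge-corrected
  100 · N(t)/N(t₀)), mean volume (µm³) by signed tetrahedra, mean surface
  complexity A / (π^(1/3) (6V)^(2/3)) (reciprocal sphericity, 1 for a
  sphere), and mean 3D centroid speed (µm/hr).
* **Phantoms** — a synthetic scene generator with exact ground truth
  (scripted growth, random walks, drifts, swirling "dervish" tracks,
  coalescence, field-edge traffic) rendered as DIC-like stacks, used for
  all validation.

## Worked example

Script a scene with two aggregates that coalesce at 150 min, render it, and
run the full chain:

```r
library(dic4d)

sc <- scene_script(
  objects = list(
    object_script(1, centroid = c(70, 128, 200), radius = 22),
    object_script(2, centroid = c(170, 128, 200), radius = 20,
                  merge_with = list(partner = 1, time = 150))),
  field_size = c(256, 256, 400), pixel_size = 4, z_step = 10,
  t_step = 30, duration = 270, seed = 11)

res <- run_pipeline(render_dic(build_scene(sc)))
res$tracking$events
#> # A tibble: 1 × 4
#>   time_min type  participants product
#>      <dbl> <chr> <chr>        <chr>
#> 1      120 merge 1+2          1/2
```

The tracker reports one coalescence, product lineage `1/2`, at 120 min —
one frame before the scripted fusion, when the approaching partners first
touch. The metric series shows the signature of a merge:

```r
res$metrics[c(1, 4, 5, 9), ]
#>   time_min n_aggregates pct_original mean_volume_um3 mean_complexity
#> 1        0            2          100          39608.            1.21
#> 4       90            2          100          40258.            1.20
#> 5      120            1           50         100229.            1.43
#> 9      240            1           50          97219.            1.21
```

The count halves, percent original drops to 50%, mean volume doubles (the
fused body carries both volumes), and surface complexity spikes at the
dumbbell-shaped moment of fusion before the product rounds up.
`autoplot(res$metrics)` draws the four-panel summary.

The fast, swirling, non-adherent cell type is modeled by a correlated
random walk:

```r
trk <- dervish_track(speed_range = c(10, 40), duration_hr = 18,
                     sampling_min = 30, seed = 1)
sp <- mean_speed(trk)
max(sp$speeds$speed_um_hr)   # 38.3 um/hr
sp$mean                      # 24.3 um/hr
```

A thin command-line wrapper lives at `inst/cli/dic4d`
(`dic4d phantom|run|metrics ...`), writing calibrated multi-page TIFFs,
PLY/OBJ meshes, CSV/JSON tables, and a hashed run manifest.

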