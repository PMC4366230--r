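---
title: "Methods: 4D reconstruction and motion analysis of gel-embedded aggregates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4D reconstruction and motion analysis of gel-embedded aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(dic4d)
```

## The measurement problem

Multicellular aggregates growing in a transparent 3D gel (e.g. a
basement-membrane matrix) can be followed for weeks by differential
interference contrast (DIC) optical sectioning: a motorized stage sweeps the
focal plane through the gel (a 1.5 mm column at 10 µm steps gives 150
sections in under a minute) and the sweep repeats every 30 minutes. DIC
imposes no phototoxic load, so the same field can be sectioned thousands of
times — 816 timepoints over 17 days at the default cadence, 122,400 sections
in all (`acquisition_plan()` does this arithmetic with the interval-count
convention, `floor(depth / step)` and `floor(duration / interval)`).

Turning those stacks into biology requires four stages, each a module of
this package:

1. **Per-section segmentation** (`complexity_map()`, `make_bitmap()`,
   `detect_stack()`): find the in-focus object regions in every optical
   section.
2. **3D reconstruction** (`group_slices()`, `skeleton_climb()`,
   `smooth_mesh()`, `contours_to_mesh()`): stack the per-section regions
   into watertight faceted solids.
3. **Tracking** (`link_frames()`, `detect_coalescence()`, `merge_ids()`,
   `classify_edge_events()`, `track_objects()`): follow each aggregate
   through time, detect coalescence, and book-keep the field edge.
4. **Quantification** (`centroid3d()`, `volume3d()`,
   `surface_complexity()`, `mean_speed()`, `percent_original()`,
   `summarize_metrics()`): the per-timepoint 3D parameter suite.

A fifth module, the phantom generator (`scene_script()`, `build_scene()`,
`render_dic()`), produces synthetic DIC-like 4D stacks with exact ground
truth; every quantitative claim the test suite makes is checked against
phantom truth or an independent brute-force oracle.

## In-focus detection: the complexity bitmap

In-focus DIC structure is characterized by strong local intensity
variability (bright/dark shear rims, granular cell texture), while
defocused structure and clean gel background are locally smooth. The
*complexity* statistic at a pixel is therefore the **population standard
deviation of the (2r+1)×(2r+1) intensity window** centered there
(default radius r = 2 px, reflect-padded borders). This is the simplest
statistic that is shift-equivariant, zero on constant images, and robust to
the sign structure of DIC shear; the test suite pins it, exactly, to a
brute-force double-loop evaluation.

Thresholding uses Otsu's between-class-variance criterion on a 256-bin
histogram, **pooled over all sections of a timepoint** (background variance
changes with depth, but one depth-spanning threshold per timepoint proved
stable) and floored at 4× the median pooled complexity. The floor matters:
on an object-free stack the complexity histogram is unimodal noise, and
unfloored Otsu would split it down the middle. When the criterion is flat
across an empty gap between modes the threshold is taken at the middle of
the maximizing plateau.

The binary map is then cleaned by morphological closing (disc radius 2 px),
hole filling, opening (radius 1 px), and a minimum-area filter (50 px²),
and finally **eroded by the complexity window radius**. The erosion undoes
a known bias: a window of radius r "sees" an in-focus rim from up to r
pixels away, so the raw super-threshold support is dilated by r. With the
compensation, detected volumes of phantom spheres at 2 µm/px land within
10% of the voxel truth across radii 20–40 µm.

## 3D reconstruction: exact occupancy surfaces with adaptive facet merging

Stacked bitmaps become a binary voxel volume on an anisotropic grid (the
lateral pixel and the z-step are carried separately and never resampled).
26-connected components become objects; pairs of voxels that touch only
along a grid edge are first bridged by filling one companion voxel, because
such contacts would pinch the surface into a non-manifold edge.

The surface of each object is the **exact 0.5-level set of the
piecewise-constant occupancy field** — the boundary quads of the voxel
union, triangulated with consistent outward orientation. This choice (over
an interpolated isosurface of the binary field) is deliberate: it makes the
enclosed mesh volume equal `voxel count × voxel volume` exactly, keeps a
single voxel a closed cube rather than a collapsed octahedron, and gives a
slab of one z-step thickness for single-section objects.

The adaptive step then **merges coplanar facets**: any vertex all of whose
incident triangles share a plane is removed and its planar link polygon
re-triangulated by ear clipping, with merged patches bounded to
`block_size` (default 4) cells in extent. The operation provably preserves
watertightness (the patch boundary is untouched) and the enclosed volume
(the patch stays in its plane), and strictly reduces the triangle count
wherever the surface is flat — on a voxelized 50 µm sphere at (2, 2, 10) µm
voxels it removes roughly 40% of the triangles. The unmerged per-cell
extraction (`unit_cell_surface()`) is kept as the reference route; tests
assert volume agreement within 2% (it is exact by construction) and
watertightness plus Euler characteristic 2 for every genus-0 phantom mesh.

Staircase aliasing, which would otherwise inflate any area-based shape
statistic, is removed by **shrink-compensated vertex smoothing** in the
two-phase λ/µ scheme (default 10 iterations, λ = 0.33, µ = −0.34): a
positive step toward the neighborhood mean followed by a slightly larger
negative step. Topology is untouched and the enclosed volume changes by
well under the 3% budget the tests enforce.

Manually traced outlines travel a parallel route: ingestion from a plain
CSV (`t, z, object, vertex_index, x_um, y_um`), equal-arc-length resampling
(default 2 µm), and closed periodic **beta-spline smoothing** with bias β1
(default 1) and tension β2 (default 0) — the defaults reduce to the uniform
cubic B-spline, the least surprising smoother; raising β2 pulls the curve
onto the traced polygon. Smoothed contours are rasterized per section,
missing intermediate sections are filled by linear interpolation of signed
distance fields, and the volume then flows through the same
reconstruction path. Filopodia are kept as open polylines and take no part
in meshing.

## Tracking and coalescence lineage

Aggregates move slowly relative to the 30-minute cadence, so linking is
**overlap-first**: greedy best-first assignment by descending voxel-overlap
fraction (relative to the predecessor), with a centroid-distance fallback
(gate 50 µm) for non-overlapping pairs. Unmatched objects become
entry/exit/merge candidates.

A coalescence is confirmed when at least two predecessors each overlap one
successor with fraction ≥ τ = 0.3 **and** the successor volume is at least
0.6× the summed predecessor volumes. The volume guard rejects brief
occlusions: a small body passing behind a larger one yields a successor far
smaller than the sum. Confirmed merges produce a slash-coded lineage
identifier — founders sorted numerically and joined, so 6 + 7 → "6/7" and
"6/7" + 5 → "5/6/7" — and the absorbed tracks end with status
`merged-away`.

Tracks that begin after the first frame with centroid within 20 µm of a
field face are entries; tracks that end (without merging) within the margin
are exits; appearances or disappearances away from the edge are flagged
anomalies rather than silently absorbed. A new track appearing within 10
frames and twice the gate of a recent off-track exit re-uses the exited
lineage id (the transient-exit convention). Splits are never emitted.

## The parameter suite

* **Centroid**: unweighted mean of occupied voxel centers (voxel route) or
  the volume-weighted tetrahedron centroid (mesh route); the two agree
  within half a voxel on phantoms.
* **Volume**: absolute signed sum of origin tetrahedra over the triangles
  of a watertight mesh.
* **Surface complexity**: reciprocal sphericity,
  `A / (π^(1/3) (6V)^(2/3))` — area relative to the equal-volume sphere.
  It is exactly 1 for a sphere (icosphere test: 1.00 ± 0.01), 1.2407 for a
  cube (closed form), dimensionless, scale-invariant, and rises with lobes,
  necks and protrusions. The isoperimetric inequality makes ≥ 1 − mesh
  tolerance an invariant, asserted for every phantom mesh.
* **Speed**: instantaneous 3D centroid displacement per interval at the
  native cadence, in µm/hr, with no pre-smoothing of centroids;
  merged-away intervals are excluded.
* **Percent original aggregate number**: `100 · N(t) / N(t0)`, where
  entered tracks count from their entry frame and founders that exit
  before contributing two frames are excluded from `N(t0)`. Ten founders
  and one two-way merge give 90%; ten founders and one entry give 110%.

`summarize_metrics()` assembles the per-timepoint table (count, percent
original, mean volume, mean complexity, mean speed) and `autoplot()` draws
the four-panel summary.

## The phantom generator: what it emulates, and what it does not

A scene script specifies the field (defaults: 446 × 335 µm by 1.5 mm, 10 µm
z-steps, 30-minute frames, 17 days), and objects as spheres with optional
low-order angular perturbation, growth rates in µm/hr, and one of four
motion models: stationary, Gaussian random walk, constant drift, or the
*dervish* — a correlated random walk whose per-step speeds are drawn
uniformly from a scripted range (default 10–40 µm/hr) with the heading
perturbed step to step, reproducing a fast swirling erratic path. All
randomness derives from the scene seed; identical scripts give
bit-identical masks and renderings.

Scripted coalescence is played as the biology suggests: partners drift from
their scripted positions into tangent contact over an approach window
(default 90 minutes), then fuse into a connected, volume-conserving body —
the partner spheres relocated about their volume-weighted centroid at
`contact_factor` (default 0.8) of the summed equivalent radii. A literal
union of distant spheres would be disconnected, and a same-center union
would halve the volume, tripping the tracker's own volume guard; neither
would be a meaningful test of coalescence detection.

Rendering is stylized, not physical optics: sections through an object get
a bipolar shear rim at the boundary plus granular interior texture,
sections at axial distance *d* get only a defocus ghost blurred with a
Gaussian of width `0.3 px/µm × d` and attenuated with distance, and the
stack receives additive Gaussian noise (σ = 0.02). The renderer supplies
exactly the property the detector consumes — a local-variance contrast
between in-focus structure and background of better than 3:1 — and nothing
more. Passing tests therefore demonstrate that the chain recovers scripted
geometry, events and kinematics from images with DIC-like contrast
statistics; they do not certify performance on real DIC physics
(shear-direction anisotropy, gel debris, illumination drift, aggregates
touching the field border at t0), nor segmentation of internal structure
within dense aggregates.

Three canned scenarios fix the study conditions used throughout the tests,
all at 64 × 64 × 40 voxels × 20 timepoints (4 µm/px): a coalescing field of
nine aggregates of which eight merge (`scenario_coalescence()`), a
non-coalescing growing control (`scenario_static()`), and a field-edge
scenario with thirteen initial aggregates, three exits and two entries
(`scenario_edge_events()`). Object radii (18–20 µm) and spacings (≥ 96 µm
center-to-center) were chosen once from the detector's measured resolving
behavior: two rendered spheres whose surfaces approach closer than ~32 µm
at 4 µm/px are segmented as one body, so scripted non-partners must stay
beyond that distance, and scripted partners cross it within about one frame
of their merge time.

## Numerical choices and degenerate inputs

* Counting conventions are interval counts at both axes; a plan whose step
  exceeds its depth (or interval its duration) is rejected.
* Voxel arrays are `(ny, nx, nz)`; physical x runs along columns. Mesh
  vertices lie on voxel corners (so slabs are exactly one z-step thick);
  meshes are right-handed with outward orientation, in µm.
* Partial z-stacks are rejected at TIFF ingestion (page count must equal
  `n_z × n_t` from the calibration sidecar), not zero-padded.
* Empty scenes, empty bitmaps, and single-contour stacks are legal inputs
  with well-defined outputs; empty meshes, zero-volume meshes,
  non-watertight inputs to smoothing/volume, and self-intersecting
  contours raise errors.
* Ear clipping during facet merging skips candidates whose link polygon is
  pinched or whose re-triangulation would produce degenerate or flipped
  triangles; such vertices simply stay.
* Tie-breaks: greedy linking processes overlap pairs in descending
  fraction order; the Otsu plateau takes its middle bin; lineage founders
  sort numerically, with non-numeric labels after all numeric ones.

## Validation scale

The full suite (324 assertions) runs in under three minutes on one CPU:
phantom scenes at 64 × 64 × 40 × 20, spheres to r = 50 µm at (2, 2, 10) µm
voxels for mesh checks, and ≤ 64 × 64 images for the exact brute-force
complexity oracle. These sizes were chosen so every oracle can be computed
by enumeration while remaining a faithful miniature of the acquisition
geometry (same z-step, cadence, and object-to-voxel ratios).

## Known limitations

* The detector's resolving distance (~8 px between surfaces) bounds how
  close two aggregates may approach before they are reported as one;
  recovered merge times can precede scripted fusion by one frame when
  partners touch during their approach.
* Entry and exit timestamps carry detection latency: an object entering at
  the field face is logged when its in-field cross-sections first survive
  the minimum-area filter, one to two frames after first voxel contact.
* Surface complexity of small objects (radius ≲ 5 px) retains a staircase
  residual of order 0.2 after smoothing; contrasts between conditions are
  meaningful, absolute values for tiny objects are not.
* Probe and facilitator cells have no quantitative motion model here;
  protrusions enter only as manually traced outlines and polylines.
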