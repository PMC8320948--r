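---
title: "Segmenting and modelling the nuclear envelope in SBF-SEM stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and modelling the nuclear envelope in SBF-SEM stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nesegment)
```

## The problem

Serial block-face scanning electron microscopy images a resin-embedded
cell volume as a stack of aligned 2D micrographs, typically 300 slices
of 2000 x 2000 pixels at 10 x 10 x 50 nm per cropped cell. The nuclear
envelope (NE) — the double membrane bounding the nucleus — appears as a
thin dark band. Hand delineation of one cell takes tens of hours;
`nesegment` automates it without training data by exploiting three
stable intensity properties of these images:

1. one cell of interest sits at the centre of the cropped volume,
   possibly surrounded by fragments of neighbouring cells;
2. the NE is darker than both the nucleoplasm and the cytoplasm;
3. the resin background is brighter than any cellular structure.

## Per-slice candidate detection

Each slice passes through a fixed pipeline
(`smooth_slice` → `detect_edges` → `dilate_edges` →
`label_superpixels` → `filter_superpixels`):

* **Low-pass filtering.** A normalized 7 x 7 Gaussian of sigma 2 px
  (border replicated) suppresses acquisition noise. These values suit
  10 nm pixels; they are exposed in `seg_params()`.
* **Canny edges.** Gradients (Sobel on a sigma-1 smoothed copy),
  non-maximum suppression, and hysteresis. The high threshold is derived
  from the gradient-magnitude histogram by Otsu's method with
  low = 0.4 x high. Two numerical guards matter in volume work: the
  thresholds are derived once on the central slice and applied as
  *absolute* values to every slice (`canny_reference`), so slices
  without membrane edges do not have their thresholds adapt down to
  texture; and a floor of 10 grey-levels/px on the strong threshold
  (`canny_min_grad`) keeps flat resin-only slices edge-free.
* **Edge dilation.** A disk of radius 5 px — about one NE width at this
  pixel size — reconnects membrane edge fragments that break where the
  envelope intensity varies. The element is an exact Euclidean disk.
* **Superpixels.** The 8-connected components of the pixels *not*
  covered by the dilated edges. Size is unrestricted: the background is
  one giant superpixel. (These are connectivity superpixels, not
  compactness-constrained SLIC ones.)
* **Filtering.** Superpixels touching the image border (background,
  cytoplasm, neighbouring-cell fragments — in a cropped single-cell
  volume all of these reach the frame) are dropped; superpixels below
  `min_region_fraction` (default 0.1%) of the slice area are dropped;
  holes are filled via background connectivity; outlines are closed with
  a disk of radius 5.
* **Boundary restoration.** Edge dilation eats a `dilate_radius` margin
  into every region, and the detected inner-envelope edge sits one
  envelope width inside the true nuclear boundary, so accepted
  candidates are finally grown by `grow_radius = dilate_radius + 5` px.
  Without this step the segmentation would be biased ~10 px inward,
  which is negligible at a 1000 px nuclear radius but not at phantom
  scale.

The stage list some descriptions of this pipeline include under
"distance transforms" is realized here through background-connectivity
hole filling; no separate distance-transform smoothing is applied, and
the stated post-conditions are met without it.

## Volumetric propagation

Near the poles the nuclear cross-section fragments into disjoint
islands; deciding which islands are nucleus requires 3D context, exactly
as a human scrolls through neighbouring slices. `segment_volume` seeds
at the central slice (`floor(n_d/2)`), where the nuclear region is
single, centred and largest (`select_central_region`: largest area, ties
to the most central), then sweeps up and down. A candidate is accepted
iff it overlaps the accepted region of the nearest already-processed
slice (`propagate`; >= 1 shared voxel by default, a minimum overlap
fraction is exposed). The reference is the nearest non-empty accepted
slice toward the centre rather than strictly the adjacent one, so a
single failed slice does not truncate the nucleus; after `max_gap = 3`
consecutive empty slices the sweep stops in that direction. What happens
after many overlap-free slices is not otherwise specified by the
procedure this implements; the gap rule is this package's choice.

The NE is extracted as the slice-wise inner boundary (mask pixels with a
4-neighbour outside), matching how 2D ground truth is drawn; a full 3D
boundary would additionally label the flat polar caps.

## Alignment

Rigid inter-slice jumps (e.g. an external vibration during acquisition)
are found by scanning consecutive pairs with `detect_shift` and
reported when the shift magnitude reaches 5 px — well below a genuine
artefact, well above stage jitter. Estimation is phase correlation at
integer precision; because full spectral whitening is fragile in two
opposite regimes (per-pixel noise dominating high frequencies, or
structural change between cross-sections dominating low ones), two
phase-correlation variants propose candidates — one with a Gaussian
low-pass weight on the cross-power spectrum, one computed on mildly
smoothed slices — and the candidate (including the null shift) with the
best spatial overlap correlation wins. Correction translates all later
slices back, filling vacated borders with the slice median (a neutral
stand-in for resin; the choice is immaterial to the similarity metrics).

## Evaluation metrics

`jaccard` is TP/(TP+FP+FN) — deliberately excluding true negatives, so
slices dominated by background are scored strictly; it is undefined
(`NA`, with a warning) when both masks are empty. `hausdorff` is the
symmetric Hausdorff distance between boundary pixel sets in Euclidean
pixel units, computed in-plane per slice; "mean Hausdorff distance"
always means the mean over slices of the per-slice value, not the
modified/average Hausdorff distance. `evaluate_volume` applies both per
slice over an inclusive range, excludes slices where both masks are
empty from the means, and reports Hausdorff only where both boundaries
exist. Boundary pixels (not filled regions) enter the Hausdorff
distance; for convex sections the two coincide, for concave ones the
boundary version is the stricter reading.

## The spheroid shape model

`fit_spheroid` centres a sphere (in physical nm coordinates; an
anisotropic spheroid in voxel units on a 10 x 10 x 50 nm grid) at the
nucleus centroid with radius solving (4/3) pi r^3 = nucleus volume. No
further pose optimization is performed — the centroid *is* the
adjustment. Axis ratios are configurable but default to a sphere, which
matches near-spherical nuclei.

`ray_distances` casts rays on an equirectangular longitude-latitude grid
(default 360 x 180 = 1 degree) from the centre, sampling every half
in-plane pixel, and records `(distance to the outermost NE crossing) -
(distance to the spheroid surface)`, positive outside. Using the
*outermost* crossing renders invaginations as valleys instead of gaps;
rays that never meet the nucleus are flagged `NA`, never silently zero.
Values are reported in in-plane pixel units (10 nm each); axial
distances are converted by the physical voxel size. Summary statistics
(`surface_metrics`: mean, population SD, range, and the fraction of grid
pixels within one SD above/below the mean) are computed on the raw grid
without solid-angle weighting — the per-grid-pixel ratios are defined on
the map, not on the sphere — and `correlate_metrics` reports Pearson
correlations of the spheroid Jaccard index against them.
`hela_surface_table()` ships the published reference metrics for the
seven EMPIAR-10094 HeLa nuclei; across them the JI-sigma correlation is
strongly negative (a nucleus closer to its spheroid has a smoother
surface).

## The phantom generator

`generate_phantom` renders everything the pipeline consumes with exact
ground truth. The nucleus is a radially perturbed ellipsoid: inside iff
the normalized radius is below `1 + a f(v) - notch(v)`, with `f` a
band-limited random field on the sphere (a seeded sum of von
Mises-Fisher bumps, normalized to unit maximum — only smoothness and
amplitude control matter, so no spherical-harmonic machinery is used)
and the notch a trench across the upper pole that makes near-pole
cross-sections split into disjoint islands. Default conditions: a
256 x 256 x 60 stack at 10 x 10 x 50 nm, nucleus semi-axes 100 px
in-plane and 24 slices axially (physically near-spherical), intensities
background 200 > nucleoplasm 140 > cytoplasm 120 > envelope 60
(enforcing the segmenter's assumptions), a 5 px envelope band, Gaussian
noise of sigma 6, and four dark border-touching clutter fragments per
stack. The cytoplasm fills a cell column that overruns all four image
borders, as real cropped volumes do, and carries a texture that persists
across slices (organelles span many 50 nm steps) with post-blur SD ~7 —
strong enough that consecutive slices correlate as real data do, weak
enough that texture gradients stay below the membrane-driven Canny
thresholds. Clutter fragments stay two envelope widths clear of the
nucleus: they belong to *other* cells, and letting them touch the NE
would create a contrast configuration (envelope 60 against clutter 80)
that the intensity assumptions above exclude.

What the phantom does not emulate: organelle interiors (nucleoli,
mitochondria) that produce internal edges, charging/curtaining SEM
artefacts, staining gradients across the block, and partial-volume
blur between slices. Passing on phantoms therefore demonstrates the
pipeline's logic (edge-based region formation, propagation, metrics,
shape model) under the stated intensity assumptions, not robustness to
every real-world artefact.

`generate_cohort` produces cells differing only in deformation
amplitude, all sharing one seed and hence one perturbation field, so
irregularity increases strictly along the ladder — the construction the
monotonicity checks (spheroid JI falling, surface sigma rising, their
anticorrelation) rely on. Cohort phantoms default to an isotropic 96^3
grid so spheroid rasterization error stays out of those comparisons.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline on a
256 x 256 x 60 phantom (the default generator conditions), the notched
scenario on 192 x 192 x 48, alignment on 160 x 160 x 24, and the cohort
on seven 96^3 cells — sizes at which every geometric property under test
(relative boundary error ~1%, multi-slice islands, sub-threshold
jitter) is well expressed while a complete run stays in the minutes
range. Ties in non-maximum suppression keep both neighbours (`>=`
comparisons) so ridges are never dropped; component labels are numbered
in first-pixel order for determinism; all randomness flows through one
seed per generator call (`withr::with_seed`, leaving the caller's RNG
state untouched).

## Known limitations

* One nucleus per cropped volume; no multi-cell instance segmentation.
* Translation-only alignment; rotations and non-rigid drift are out of
  scope.
* The per-slice envelope is a 2D boundary; polar caps are not labelled
  as envelope in 3D.
* Accuracy degrades at the nuclear poles where cross-sections become
  small and fragmented — central slices are the reliable band, and
  sub-100-px polar islands can fall below detectability.
* Surface statistics are unweighted map statistics; high-latitude
  regions are over-represented relative to their solid angle.
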