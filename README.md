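# nesegment

Unsupervised segmentation and shape modelling of the nuclear envelope
(NE) in serial block-face scanning electron microscopy (SBF-SEM) stacks
of single cells, with a seeded phantom generator for fully reproducible
testing. Written for microscopists and image analysts who need an
automatic, training-free alternative to hand delineation of the nucleus
in cropped single-cell volumes (typically 2000 x 2000 x 300 voxels at
10 x 10 x 50 nm), such as the HeLa cell volumes of the public
EMPIAR-10094 dataset.

## Method

The segmenter relies on three image properties: the resin background is
brighter than any cellular structure, the NE is darker than both the
nucleoplasm it encloses and the surrounding cytoplasm, and the nucleus
is a single connected 3D body even where its 2D cross-sections are
disjoint.

Per slice: Gaussian low-pass (7 x 7, sigma 2) -> Canny edges -> dilation
with a disk of radius 5 px (about one NE width, reconnecting edge
fragments) -> *superpixels* as the 8-connected components of the
non-edge pixels -> morphological filtering (drop border-touching and
small superpixels, fill holes, close jagged outlines, restore the
boundary eaten by edge dilation). Per volume: the sweep seeds on the
central slice (largest, single, centred nuclear cross-section) and
propagates up and down; a candidate region on the next slice is kept iff
it overlaps the accepted region of the nearest processed slice, so
disjoint polar islands that connect through lower slices are retained
while clutter from neighbouring cells is discarded. The NE is the
slice-wise inner boundary of the accepted nucleus.

Evaluation against ground truth uses the Jaccard index
`JI = TP / (TP + FP + FN)` and the symmetric Hausdorff distance
`d_H(A, B) = max{ sup_a inf_b d(a,b), sup_b inf_a d(a,b) }`, both per
slice.

For shape analysis the nucleus is modelled against a spheroid of equal
volume centred at its centroid (a sphere in physical nm coordinates).
Rays cast from the centre on a longitude-latitude grid record the signed
distance from the spheroid surface to the outermost NE crossing
(positive outside). The resulting 2D map is summarized by its mean,
population standard deviation, range and the pixel ratios within one
standard deviation of the mean; the Jaccard index between nucleus and
spheroid measures how spherical the NE is, and anticorrelates with the
surface sigma across cells.

Inter-slice displacement artefacts (rigid jumps from e.g. microscope
vibration) are detected by phase correlation between consecutive slices
and corrected by translating all later slices back.

## Worked example

```r
library(nesegment)

# a 256 x 256 x 60 phantom cell with exact ground truth
ph  <- generate_phantom(phantom_params(seed = 7))
nuc <- segment_volume(ph$stack)
nuc
#> NucleusVolume: 974474 voxels over slices 7-54 (central slice 30)

jaccard(nuc$mask, ph$nucleus)
#> [1] 0.9563096

ev <- evaluate_volume(nuc, ph$nucleus, slice_range = c(15, 45))
c(ev$mean_jaccard, ev$mean_hausdorff)
#> [1] 0.9721219 1.9157087

sph <- fit_spheroid(nuc, ph$stack$voxel_size)
map <- ray_distances(nuc, sph, n_lon = 90, n_lat = 45,
                     voxel_size = ph$stack$voxel_size)
surface_metrics(map, nuc, sph, ph$stack$voxel_size)
#>   volume_um3 ji_spheroid  mean_mu std_sigma range_ ratio_above ratio_below
#> 1    4.87237   0.8658264 3.117244  8.039524   27.5   0.1644444   0.3874074
```

The segmentation recovers 96% of the true nucleus volumetrically and
97% per slice over the central half of the stack, with a mean Hausdorff
distance under 2 px; the fitted spheroid reports the nuclear volume in
um^3 and a spheroid Jaccard index of 0.87 (this phantom is nearly
spheroidal; strongly lobed nuclei score lower).

A thin command-line wrapper with `align`, `segment-volume`, `evaluate`,
`model-surface`, `make-phantom` and `run` subcommands ships in
`inst/cli/nesegment.R`.

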