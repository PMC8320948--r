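#' Segmentation parameters
#'
#' Parameters of the per-slice candidate detection pipeline. The defaults
#' are the values the method was developed with on 10 nm/pixel SBF-SEM
#' slices: a 7 x 7 Gaussian low-pass of sigma 2 removes acquisition
#' noise, and edges are dilated with a disk of radius 5 pixels --
#' comparable to the width of the nuclear envelope (50-100 nm) -- to
#' close gaps caused by intensity variation within the envelope itself.
#'
#' @param gauss_size odd kernel size (pixels) of the low-pass filter.
#' @param gauss_sigma standard deviation (pixels) of the low-pass filter.
#' @param canny_sigma Gaussian sigma used inside the Canny detector.
#' @param canny_low,canny_high hysteresis thresholds in \[0, 1\];
#'   `NA` (default) derives the high threshold from the gradient
#'   histogram by Otsu's method, with low = 0.4 * high.
#' @param canny_min_grad absolute gradient floor (grey levels per pixel)
#'   for strong edges, so flat resin-only slices yield no spurious noise
#'   contours; see [canny()].
#' @param canny_scale reference gradient magnitude the thresholds refer
#'   to; `NA` uses each slice's own maximum. [segment_volume()] fills
#'   `canny_low`/`canny_high`/`canny_scale` from its central slice (via
#'   [canny_reference()]) when they are `NA`, so one set of absolute
#'   thresholds governs the whole volume.
#' @param dilate_radius disk radius (pixels) for edge dilation.
#' @param min_region_fraction superpixels smaller than this fraction of
#'   the slice area are discarded.
#' @param close_radius disk radius (pixels) of the final morphological
#'   closing that smooths jagged region outlines.
#' @param grow_radius disk radius (pixels) by which accepted candidate
#'   regions are grown at the end of [segment_slice()]. Edge dilation
#'   eats a margin of `dilate_radius` into every region and the detected
#'   inner-envelope edge sits one envelope width inside the true nuclear
#'   boundary; growing by their sum restores the boundary to the outer
#'   envelope surface. Default `dilate_radius + 5`.
#' @param min_overlap_fraction minimum fraction of a candidate's area
#'   that must overlap the reference region during slice-to-slice
#'   propagation; 0 keeps any candidate with at least one shared voxel.
#' @param max_gap maximum number of consecutive candidate-free (or
#'   overlap-free) slices the volumetric sweep tolerates before it stops
#'   in that direction.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(gauss_size = 7L, gauss_sigma = 2, canny_sigma = 1,
                       canny_low = NA, canny_high = NA, canny_scale = NA,
                       canny_min_grad = 10,
                       dilate_radius = 5L, min_region_fraction = 0.001,
                       close_radius = 5L,
                       grow_radius = dilate_radius + 5L,
                       min_overlap_fraction = 0, max_gap = 3L) {
  p <- list(gauss_size = as.integer(gauss_size), gauss_sigma = gauss_sigma,
            canny_sigma = canny_sigma, canny_low = canny_low,
            canny_high = canny_high, canny_scale = canny_scale,
            canny_min_grad = canny_min_grad,
            dilate_radius = as.integer(dilate_radius),
            min_region_fraction = min_region_fraction,
            close_radius = as.integer(close_radius),
            grow_radius = as.integer(grow_radius),
            min_overlap_fraction = min_overlap_fraction,
            max_gap = as.integer(max_gap))
  if (p$gauss_size < 3L || p$gauss_size %% 2L == 0L)
    stop("gauss_size must be an odd integer >= 3")
  if (p$gauss_sigma <= 0 || p$canny_sigma <= 0)
    stop("gauss_sigma and canny_sigma must be positive")
  if (p$dilate_radius < 1L) stop("dilate_radius must be >= 1")
  if (p$min_region_fraction < 0 || p$min_region_fraction >= 1)
    stop("min_region_fraction must be in [0, 1)")
  if (p$min_overlap_fraction < 0 || p$min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in [0, 1]")
  class(p) <- "seg_params"
  p
}

# exact Euclidean disk: pixels whose centre lies within `radius`
disk_brush <- function(radius) {
  x <- -radius:radius
  (outer(x^2, x^2, "+") <= radius^2) * 1
}

#' Gaussian low-pass filtering of a slice
#'
#' Convolution with a normalized `gauss_size` x `gauss_size` Gaussian
#' kernel; borders are handled by replication.
#'
#' @param image numeric matrix.
#' @inheritParams seg_params
#' @return Smoothed numeric matrix of the same shape.
#' @export
smooth_slice <- function(image, gauss_size = 7L, gauss_sigma = 2) {
  if (gauss_size %% 2L == 0L) stop("gauss_size must be odd")
  conv2_replicate(image, gaussian_kernel(gauss_size, gauss_sigma))
}

#' Detect intensity edges in a slice
#'
#' Runs the Canny detector (see [canny()]) with the thresholds configured
#' in `params`. The abrupt intensity change at the nuclear envelope
#' relative to cytoplasm and nucleoplasm produces closed or nearly closed
#' edge chains along the membrane.
#'
#' @param image numeric matrix (typically the output of [smooth_slice()]).
#' @param params a [seg_params()] object.
#' @return Logical edge mask.
#' @export
detect_edges <- function(image, params = seg_params()) {
  canny(image, sigma = params$canny_sigma,
        low = params$canny_low, high = params$canny_high,
        mag_scale = params$canny_scale, min_grad = params$canny_min_grad)
}

#' Dilate an edge mask
#'
#' Morphological dilation with a disk structuring element, used to
#' connect edge fragments of the envelope that are disjoint because of
#' intensity variation within the membrane.
#'
#' @param edges logical matrix.
#' @param dilate_radius disk radius in pixels.
#' @return Logical matrix; a superset of `edges`.
#' @export
dilate_edges <- function(edges, dilate_radius = 5L) {
  stopifnot(is.logical(edges))
  if (!any(edges)) return(edges)
  EBImage::dilate(edges * 1, disk_brush(as.integer(dilate_radius))) > 0
}

#' Label superpixels
#'
#' Superpixels here are the 8-connected components of the pixels *not*
#' covered by the dilated edge mask; their size is unrestricted, so a
#' single superpixel may cover the whole background.
#'
#' @param dilated_edges logical matrix.
#' @return A list of class `superpixel_image`: `labels` (integer matrix,
#'   0 on edge pixels, 1..K elsewhere) and `K` (component count).
#' @export
label_superpixels <- function(dilated_edges) {
  stopifnot(is.logical(dilated_edges))
  labels <- label_components(!dilated_edges)
  structure(list(labels = labels, K = max(labels)),
            class = "superpixel_image")
}

fill_holes <- function(mask) EBImage::fillHull(mask * 1) > 0

close_mask <- function(mask, radius) {
  if (radius < 1L || !any(mask)) return(mask)
  EBImage::closing(mask * 1, disk_brush(as.integer(radius))) > 0
}

#' Filter superpixels into candidate nuclear regions
#'
#' Cleans the superpixel set: superpixels touching the image boundary
#' (background, cytoplasm of the cell of interest, fragments of
#' neighbouring cells) are removed, superpixels smaller than
#' `min_region_fraction` of the slice area are removed, interior holes of
#' the survivors are filled, and jagged outlines are smoothed by a
#' morphological closing.
#'
#' @param sp a `superpixel_image` from [label_superpixels()].
#' @param params a [seg_params()] object.
#' @return List of logical candidate masks (possibly empty), pairwise
#'   disjoint, none touching the slice boundary.
#' @export
filter_superpixels <- function(sp, params = seg_params()) {
  stopifnot(inherits(sp, "superpixel_image"))
  labels <- sp$labels
  d <- dim(labels)
  if (sp$K == 0L) return(list())
  border_labels <- unique(c(labels[1, ], labels[d[1], ],
                            labels[, 1], labels[, d[2]]))
  min_area <- params$min_region_fraction * prod(d)
  areas <- tabulate(labels, nbins = sp$K)
  out <- list()
  for (k in seq_len(sp$K)) {
    if (k %in% border_labels || areas[k] < min_area) next
    m <- labels == k
    m <- close_mask(fill_holes(m), params$close_radius)
    out[[length(out) + 1L]] <- m
  }
  out
}

grow_mask <- function(mask, radius) {
  if (radius < 1L || !any(mask)) return(mask)
  fill_holes(EBImage::dilate(mask * 1, disk_brush(as.integer(radius))) > 0)
}

#' Segment one slice into candidate nuclear regions
#'
#' The full per-slice pipeline: Gaussian low-pass, Canny edge detection,
#' edge dilation, superpixel labelling of the edge complement, and
#' morphological filtering. Surviving candidates are finally grown by
#' `grow_radius` (see [seg_params()]) to place their outline back on the
#' outer envelope surface. Deterministic for fixed parameters.
#'
#' @param image numeric matrix, 8-bit greyscale slice.
#' @param params a [seg_params()] object.
#' @return List of logical candidate masks, largest first.
#' @export
segment_slice <- function(image, params = seg_params()) {
  sm <- smooth_slice(image, params$gauss_size, params$gauss_sigma)
  edges <- detect_edges(sm, params)
  dil <- dilate_edges(edges, params$dilate_radius)
  sp <- label_superpixels(dil)
  cands <- filter_superpixels(sp, params)
  cands <- lapply(cands, grow_mask, radius = params$grow_radius)
  cands[order(-vapply(cands, sum, numeric(1)))]
}
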