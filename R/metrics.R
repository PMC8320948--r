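#' Pixel confusion counts
#'
#' Counts true positives (nuclear pixels segmented as nucleus), true
#' negatives, false positives and false negatives between a segmentation
#' and its ground truth.
#'
#' @param seg,gt logical arrays of identical shape.
#' @return Named list `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(seg, gt) {
  stopifnot(is.logical(seg), is.logical(gt))
  if (!identical(dim(seg), dim(gt)))
    stop("segmentation and ground truth have different shapes")
  list(TP = sum(seg & gt), TN = sum(!seg & !gt),
       FP = sum(seg & !gt), FN = sum(!seg & gt))
}

#' Jaccard similarity index
#'
#' `JI = TP / (TP + FP + FN)`, the intersection over union of two binary
#' masks. True negatives are deliberately excluded, which makes the index
#' strict on slices dominated by background. When both masks are empty
#' the index is undefined and `NA` is returned with a warning.
#'
#' @inheritParams confusion_counts
#' @return A number in \[0, 1\], or `NA` when undefined.
#' @export
jaccard <- function(seg, gt) {
  cc <- confusion_counts(seg, gt)
  denom <- cc$TP + cc$FP + cc$FN
  if (denom == 0) {
    warning("both masks empty: Jaccard index undefined")
    return(NA_real_)
  }
  cc$TP / denom
}

# directed sup-inf distance from points A to points B (n x 2 matrices)
directed_hausdorff <- function(A, B) {
  # process A in chunks to bound the distance-matrix size
  step <- max(1L, 2e6 %/% nrow(B))
  worst <- 0
  for (i0 in seq(1L, nrow(A), by = step)) {
    ii <- i0:min(i0 + step - 1L, nrow(A))
    d2 <- outer(A[ii, 1], B[, 1], "-")^2 + outer(A[ii, 2], B[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

#' Hausdorff distance between two point sets
#'
#' The symmetric Hausdorff distance: the maximum over both curves of the
#' Euclidean distance from a point to its nearest neighbour on the other
#' curve, in pixel units.
#'
#' @param boundary_a,boundary_b point sets: n x 2 numeric matrices of
#'   (row, col) coordinates, or logical matrices whose `TRUE` pixels are
#'   used.
#' @return Non-negative distance in pixels.
#' @export
hausdorff <- function(boundary_a, boundary_b) {
  as_points <- function(x) {
    if (is.logical(x)) x <- which(x, arr.ind = TRUE)
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
  A <- as_points(boundary_a)
  B <- as_points(boundary_b)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("Hausdorff distance is undefined for an empty point set")
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}

#' Evaluate a volumetric segmentation against ground truth
#'
#' Computes, slice by slice, the Jaccard index of the nucleus masks and
#' the Hausdorff distance of the envelope boundaries, plus their means
#' over an inclusive slice range. Slices where both masks are empty carry
#' no information and are excluded from the means; the Hausdorff distance
#' is reported only where both boundaries are non-empty.
#'
#' @param seg a `NucleusVolume` from [segment_volume()], or a 3D logical
#'   mask (the envelope is then derived with [extract_envelope()]).
#' @param gt 3D logical ground-truth nucleus mask on the same grid.
#' @param slice_range integer (lo, hi), inclusive; defaults to the full
#'   stack.
#' @return A list: `per_slice`, a data frame with `slice`, `jaccard`,
#'   `hausdorff`; `mean_jaccard`; `mean_hausdorff`; `slice_range`.
#' @export
evaluate_volume <- function(seg, gt, slice_range = NULL) {
  seg_mask <- as_nucleus_mask(seg)
  stopifnot(is.logical(gt))
  if (!identical(dim(seg_mask), dim(gt)))
    stop("segmentation and ground truth have different shapes")
  seg_env <- if (inherits(seg, "NucleusVolume")) seg$envelope
             else extract_envelope(seg_mask)
  gt_env <- extract_envelope(gt)
  nd <- dim(gt)[3]
  if (is.null(slice_range)) slice_range <- c(1L, nd)
  stopifnot(slice_range[1] <= slice_range[2],
            slice_range[1] >= 1L, slice_range[2] <= nd)
  slices <- slice_range[1]:slice_range[2]

  ji <- hd <- rep(NA_real_, length(slices))
  for (i in seq_along(slices)) {
    k <- slices[i]
    s <- seg_mask[, , k]
    g <- gt[, , k]
    if (any(s) || any(g)) ji[i] <- suppressWarnings(jaccard(s, g))
    se <- seg_env[, , k]
    ge <- gt_env[, , k]
    if (any(se) && any(ge)) hd[i] <- hausdorff(se, ge)
  }
  list(
    per_slice = data.frame(slice = slices, jaccard = ji, hausdorff = hd),
    mean_jaccard = mean(ji, na.rm = TRUE),
    mean_hausdorff = mean(hd, na.rm = TRUE),
    slice_range = slice_range
  )
}
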