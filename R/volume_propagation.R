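#' Select the nuclear region on the central slice
#'
#' The volumetric sweep is seeded on the central slice of the cropped
#' cell, where the nuclear cross-section is assumed to be single,
#' centrally positioned and of largest diameter. The largest candidate is
#' selected; area ties are broken by the smallest centroid distance to
#' the image centre.
#'
#' @param candidates list of logical candidate masks from
#'   [segment_slice()].
#' @param slice_shape integer (rows, cols) of the slice.
#' @return The selected logical mask.
#' @export
select_central_region <- function(candidates, slice_shape) {
  if (length(candidates) == 0L)
    stop("no candidate region on the central slice: no nucleus found")
  areas <- vapply(candidates, sum, numeric(1))
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    centre <- (slice_shape + 1) / 2
    d2 <- vapply(best, function(i) {
      ij <- which(candidates[[i]], arr.ind = TRUE)
      sum((colMeans(ij) - centre)^2)
    }, numeric(1))
    best <- best[which.min(d2)]
  }
  candidates[[best[1]]]
}

#' Propagate accepted nuclear regions to a neighbouring slice
#'
#' Implements the slice-to-slice rule used to recover disjoint nuclear
#' cross-sections: a candidate region on the current slice is kept when
#' it overlaps the accepted nuclear region of the already-processed
#' neighbouring slice, and discarded otherwise.
#'
#' @param accepted_prev logical mask, the union of regions accepted on
#'   the reference slice.
#' @param candidates list of logical candidate masks on the current
#'   slice.
#' @param min_overlap_fraction minimum overlapping fraction of a
#'   candidate's area; the default 0 keeps candidates sharing at least
#'   one voxel.
#' @return Logical mask, the union of the kept candidates (all `FALSE`
#'   when none overlaps).
#' @export
propagate <- function(accepted_prev, candidates, min_overlap_fraction = 0) {
  out <- accepted_prev & FALSE
  for (cand in candidates) {
    ov <- sum(cand & accepted_prev)
    keep <- if (min_overlap_fraction > 0)
      ov >= min_overlap_fraction * sum(cand) && ov > 0
    else ov > 0
    if (keep) out <- out | cand
  }
  out
}

#' Extract the nuclear envelope from a nucleus mask
#'
#' The envelope is the inner morphological boundary computed slice-wise:
#' mask pixels with at least one 4-neighbour (within the slice) outside
#' the mask. Pixels on the image border count as boundary.
#'
#' @param mask logical matrix or 3D logical array.
#' @return Logical array of the same shape marking boundary pixels.
#' @export
extract_envelope <- function(mask) {
  stopifnot(is.logical(mask))
  slice_boundary <- function(m) {
    inner <- shift_mat(m, 1L, 0L, FALSE) & shift_mat(m, -1L, 0L, FALSE) &
      shift_mat(m, 0L, 1L, FALSE) & shift_mat(m, 0L, -1L, FALSE)
    m & !inner
  }
  if (is.matrix(mask)) return(slice_boundary(mask))
  out <- mask
  for (k in seq_len(dim(mask)[3])) out[, , k] <- slice_boundary(mask[, , k])
  out
}

#' Segment the nucleus of a whole stack
#'
#' Runs [segment_slice()] on every slice, seeds the nucleus with
#' [select_central_region()] on the central slice, and sweeps upward and
#' downward applying [propagate()]. The propagation reference is the
#' nearest slice toward the centre with a non-empty accepted region, so a
#' single failed slice does not truncate the nucleus; after `max_gap`
#' consecutive empty slices the sweep stops in that direction. The
#' envelope is extracted from the accepted mask with
#' [extract_envelope()].
#'
#' @param stack an [image_stack()] (aligned; see [correct_shift()]).
#' @param params a [seg_params()] object.
#' @param central_slice index of the seeding slice; defaults to
#'   `floor(n_d / 2)`.
#' @param verbose print per-slice progress.
#' @return An object of class `NucleusVolume`: `mask` and `envelope` (3D
#'   logical arrays), `central_slice`, and `log`, a data frame with the
#'   per-slice candidate count and accepted area.
#' @export
segment_volume <- function(stack, params = seg_params(),
                           central_slice = NULL, verbose = FALSE) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack)
  nd <- d[3]
  if (is.null(central_slice)) central_slice <- max(1L, nd %/% 2L)
  stopifnot(central_slice >= 1L, central_slice <= nd)

  # fix the Canny thresholds on the central slice for the whole volume
  if (is.na(params$canny_scale) &&
      (is.na(params$canny_low) || is.na(params$canny_high))) {
    ref <- canny_reference(
      smooth_slice(stack$voxels[, , central_slice],
                   params$gauss_size, params$gauss_sigma),
      params$canny_sigma
    )
    if (is.na(params$canny_high)) params$canny_high <- ref$high
    if (is.na(params$canny_low))
      params$canny_low <- 0.4 * params$canny_high
    params$canny_scale <- ref$scale
  }

  cands <- vector("list", nd)
  for (k in seq_len(nd)) {
    cands[[k]] <- segment_slice(stack$voxels[, , k], params)
    if (verbose)
      message(sprintf("slice %d: %d candidate(s)", k, length(cands[[k]])))
  }

  mask <- array(FALSE, d)
  mask[, , central_slice] <-
    select_central_region(cands[[central_slice]], d[1:2])

  sweep_dir <- function(mask, idx_seq) {
    gap <- 0L
    ref <- central_slice
    for (k in idx_seq) {
      acc <- propagate(mask[, , ref], cands[[k]],
                       params$min_overlap_fraction)
      if (any(acc)) {
        mask[, , k] <- acc
        ref <- k
        gap <- 0L
      } else {
        gap <- gap + 1L
        if (gap > params$max_gap) break
      }
    }
    mask
  }
  if (central_slice < nd)
    mask <- sweep_dir(mask, (central_slice + 1L):nd)
  if (central_slice > 1L)
    mask <- sweep_dir(mask, (central_slice - 1L):1L)

  structure(list(
    mask = mask,
    envelope = extract_envelope(mask),
    central_slice = central_slice,
    log = data.frame(
      slice = seq_len(nd),
      n_candidates = vapply(cands, length, integer(1)),
      accepted_area = apply(mask, 3, sum)
    )
  ), class = "NucleusVolume")
}

#' @export
print.NucleusVolume <- function(x, ...) {
  occ <- which(apply(x$mask, 3, any))
  cat(sprintf(
    "NucleusVolume: %d voxels over slices %s (central slice %d)\n",
    sum(x$mask),
    if (length(occ)) paste(range(occ), collapse = "-") else "none",
    x$central_slice
  ))
  invisible(x)
}

# accept either a NucleusVolume or a bare logical array
as_nucleus_mask <- function(x) {
  if (inherits(x, "NucleusVolume")) return(x$mask)
  stopifnot(is.logical(x))
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}
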