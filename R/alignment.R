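#' Detect the rigid translation between two slices
#'
#' Estimates the integer translation that maps `slice_a` onto `slice_b`
#' by phase correlation: the normalized cross-power spectrum of the two
#' slices has a delta peak at the translation. Sub-pixel refinement is
#' not performed; block-face acquisition artefacts are whole-pixel jumps.
#'
#' @param slice_a,slice_b numeric matrices of identical dimensions.
#' @return Integer vector `(d_rows, d_cols)`: `slice_b` is `slice_a`
#'   translated `d_rows` down and `d_cols` right. Shifts are reported in
#'   `(-n/2, n/2]` per axis.
#' @details Two phase-correlation variants propose candidate shifts: one
#'   with a Gaussian low-pass weight on the normalized cross-power
#'   spectrum (robust when the shared structure is coarse) and one on
#'   mildly smoothed slices (robust when fine shared texture carries the
#'   alignment). Each candidate, plus the null shift, is then scored by
#'   the spatial normalized cross-correlation of the overlapping region
#'   and the best-scoring shift is returned.
#' @export
detect_shift <- function(slice_a, slice_b) {
  stopifnot(is.matrix(slice_a), is.matrix(slice_b),
            all(dim(slice_a) == dim(slice_b)))
  if (sd(slice_a) == 0 || sd(slice_b) == 0)
    stop("constant slice: translation is undefined")
  d <- dim(slice_a)

  pc_peak <- function(a, b, lowpass_sigma = 0) {
    cross <- fft(b - mean(b)) * Conj(fft(a - mean(a)))
    mag <- Mod(cross)
    mag[mag < .Machine$double.eps] <- 1
    cps <- cross / mag
    if (lowpass_sigma > 0) {
      freq2 <- function(n) {
        k <- pmin(0:(n - 1), n - (0:(n - 1)))
        (k / n)^2
      }
      cps <- cps * exp(-2 * pi^2 * lowpass_sigma^2 *
                         outer(freq2(d[1]), freq2(d[2]), "+"))
    }
    corr <- Re(fft(cps, inverse = TRUE))
    peak <- arrayInd(which.max(corr), dim(corr)) - 1L
    as.integer(ifelse(peak > d / 2, peak - d, peak))
  }

  # correlation of the overlap after applying shift s to slice_a
  ncc <- function(s) {
    ra <- max(1L, 1L - s[1]):min(d[1], d[1] - s[1])
    ca <- max(1L, 1L - s[2]):min(d[2], d[2] - s[2])
    if (length(ra) < 8L || length(ca) < 8L) return(-Inf)
    x <- slice_a[ra, ca]
    y <- slice_b[ra + s[1], ca + s[2]]
    if (sd(x) == 0 || sd(y) == 0) return(-Inf)
    cor(as.vector(x), as.vector(y))
  }

  sm <- function(m) smooth_slice(m, 9L, 1)
  cands <- unique(list(
    pc_peak(slice_a, slice_b, lowpass_sigma = 1),
    pc_peak(sm(slice_a), sm(slice_b)),
    c(0L, 0L)
  ))
  scores <- vapply(cands, ncc, numeric(1))
  cands[[which.max(scores)]]
}

# translate a matrix by (dr, dc), filling vacated pixels with `fill`
translate_slice <- function(m, dr, dc, fill) {
  d <- dim(m)
  if (abs(dr) >= d[1] || abs(dc) >= d[2])
    stop("shift exceeds slice dimensions")
  out <- matrix(fill, d[1], d[2])
  src_r <- seq_len(d[1]) - dr
  src_c <- seq_len(d[2]) - dc
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Scan a stack for inter-slice displacement artefacts
#'
#' Runs [detect_shift()] on every consecutive slice pair and reports the
#' pairs whose shift magnitude reaches `threshold`. Each record gives the
#' index of the first slice *after* the discontinuity, i.e. the slice
#' from which a correction should be applied.
#'
#' @param stack an [image_stack()] with at least two slices.
#' @param threshold minimum Euclidean shift magnitude, in pixels, for a
#'   pair to be reported. Acquisition jitter is well below the default of
#'   5; genuine displacement artefacts are well above it.
#' @return A data frame with columns `slice_index`, `d_rows`, `d_cols`
#'   (zero rows when the stack is clean).
#' @export
detect_discontinuity <- function(stack, threshold = 5) {
  stopifnot(inherits(stack, "ImageStack"), n_slices(stack) >= 2L)
  recs <- list()
  for (k in seq_len(n_slices(stack) - 1L)) {
    s <- detect_shift(stack$voxels[, , k], stack$voxels[, , k + 1L])
    if (sqrt(sum(s^2)) >= threshold) {
      recs[[length(recs) + 1L]] <-
        data.frame(slice_index = k + 1L, d_rows = s[1], d_cols = s[2])
    }
  }
  if (length(recs) == 0L)
    return(data.frame(slice_index = integer(), d_rows = integer(),
                      d_cols = integer()))
  do.call(rbind, recs)
}

#' Correct a displacement artefact
#'
#' Translates every slice from `slice_index` onward by the negated shift
#' so that the stack is aligned with the slices before the discontinuity.
#' Vacated border pixels are filled with the slice median, which
#' approximates the resin background without inventing structure.
#'
#' @param stack an [image_stack()].
#' @param record one row of the data frame returned by
#'   [detect_discontinuity()] (or any list with `slice_index`, `d_rows`,
#'   `d_cols`).
#' @return The corrected [image_stack()].
#' @export
correct_shift <- function(stack, record) {
  stopifnot(inherits(stack, "ImageStack"))
  k <- as.integer(record$slice_index)
  dr <- as.integer(record$d_rows)
  dc <- as.integer(record$d_cols)
  stopifnot(k >= 1L, k <= n_slices(stack))
  vox <- stack$voxels
  for (s in k:n_slices(stack)) {
    m <- vox[, , s]
    fill <- median(m)
    if (is.integer(m)) fill <- as.integer(round(fill))
    vox[, , s] <- translate_slice(m, -dr, -dc, fill = fill)
  }
  image_stack(vox, stack$voxel_size)
}
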