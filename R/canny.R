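# Canny edge detection and 8-connected component labelling.
#
# No installed package exposes a Canny detector for plain matrices, so the
# standard procedure (Gaussian derivative, non-maximum suppression,
# double-threshold hysteresis) is implemented here on top of EBImage
# filtering primitives.

# normalized square Gaussian kernel, closed form
gaussian_kernel <- function(size, sigma) {
  stopifnot(size >= 3, size %% 2 == 1, sigma > 0)
  r <- (size - 1) / 2
  x <- -r:r
  k <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# 2D convolution with border replication
conv2_replicate <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}

# shift a matrix by (dr, dc) padding with `fill`; used for neighbour tests
shift_mat <- function(m, dr, dc, fill = 0) {
  translate_slice(m, dr, dc, fill)
}

#' Label 8-connected components
#'
#' Labels the 8-connected components of a logical matrix. Connectivity is
#' resolved exactly (via the pixel adjacency graph), unlike 4-connected
#' flood fills which split regions touching only at corners.
#'
#' @param mask logical matrix.
#' @return Integer matrix of the same shape: 0 outside `mask`, and
#'   1..K inside, one label per component.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  id <- matrix(NA_integer_, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  edges <- list()
  # unique neighbour offsets for 8-connectivity
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    a <- id
    b <- shift_mat(id, off[1], off[2], fill = NA_integer_)
    keep <- !is.na(a) & !is.na(b)
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(a[keep], b[keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  # renumber components in first-pixel (column-major) order for determinism
  lab[idx] <- match(comp, unique(comp))
  lab
}

# Otsu threshold on a numeric vector, 256-bin histogram
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(256L, 1L + as.integer((x - rng[1]) / diff(rng) * 256)),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

#' Canny edge detection
#'
#' The standard Canny procedure: Gaussian smoothing at `sigma`, Sobel
#' gradients, non-maximum suppression along the quantized gradient
#' direction, and hysteresis thresholding (weak-edge components are kept
#' only when they contain a strong pixel). When thresholds are not given,
#' the high threshold is derived from the gradient-magnitude histogram by
#' Otsu's method and the low threshold is 0.4 times the high one.
#'
#' @param image numeric matrix (greyscale).
#' @param sigma standard deviation, in pixels, of the detector's own
#'   Gaussian smoothing.
#' @param low,high hysteresis thresholds on gradient magnitude, as
#'   fractions of the reference magnitude in \[0, 1\]; `NA` selects them
#'   automatically.
#' @param mag_scale reference gradient magnitude that `low`/`high` are
#'   fractions of; `NA` (default) uses the maximum magnitude of this
#'   image. Passing the scale of a reference slice makes the thresholds
#'   absolute and comparable across the slices of one volume.
#' @param min_grad absolute gradient-magnitude floor (grey levels per
#'   pixel) below which no pixel counts as a strong edge; keeps the
#'   automatic thresholds from latching onto noise on essentially flat
#'   images. 0 disables the floor.
#' @return Logical matrix of edge pixels.
#' @export
canny <- function(image, sigma = 1, low = NA, high = NA, mag_scale = NA,
                  min_grad = 0) {
  g <- canny_gradient(image, sigma)
  if (is.null(g)) return(matrix(FALSE, nrow(image), ncol(image)))
  mag <- g$mag
  nms <- g$nms

  mmax <- if (is.na(mag_scale)) max(mag) else mag_scale
  if (is.na(high)) high <- otsu_threshold(mag[nms] / mmax)
  if (is.na(low)) low <- 0.4 * high
  strong <- nms & mag >= pmax(high * mmax, min_grad)
  weak <- nms & mag >= low * mmax
  if (!any(strong)) return(strong)

  lab <- label_components(weak)
  keep <- unique(lab[strong])
  weak & matrix(lab %in% keep, nrow(lab), ncol(lab))
}

# gradient magnitude and non-maximum-suppression mask; NULL when the
# image is constant
canny_gradient <- function(image, sigma) {
  stopifnot(is.matrix(image))
  if (sd(image) == 0) return(NULL)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  sm <- conv2_replicate(image, gaussian_kernel(size, sigma))
  sobel <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # varies along cols
  gr <- conv2_replicate(sm, t(sobel))  # d/d(row)
  gc <- conv2_replicate(sm, sobel)    # d/d(col)
  mag <- sqrt(gr^2 + gc^2)
  if (max(mag) == 0) return(NULL)

  # non-maximum suppression: quantize gradient direction into 4 sectors
  ang <- atan2(gr, gc)            # angle of the gradient vector
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: gradient ~horizontal (col) -> compare left/right, etc.
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    n1 <- shift_mat(mag, o[1], o[2], 0)
    n2 <- shift_mat(mag, -o[1], -o[2], 0)
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }
  list(mag = mag, nms = nms & mag > 0)
}

#' Derive Canny thresholds from a reference slice
#'
#' Computes the gradient-magnitude scale of a reference slice and the
#' Otsu-derived high threshold (low = 0.4 * high) on it. Fixing these for
#' a whole volume, as [segment_volume()] does with its central slice,
#' keeps slices without strong membrane edges from having their
#' thresholds adapt down to texture gradients.
#'
#' @param image numeric matrix, the reference slice (already low-pass
#'   filtered in the pipeline).
#' @param sigma Canny smoothing sigma.
#' @return List with `low`, `high` (fractions of `scale`) and `scale`
#'   (the reference gradient magnitude).
#' @export
canny_reference <- function(image, sigma = 1) {
  g <- canny_gradient(image, sigma)
  if (is.null(g)) stop("reference slice is constant: no gradient scale")
  scale <- max(g$mag)
  high <- otsu_threshold(g$mag[g$nms] / scale)
  list(low = 0.4 * high, high = high, scale = scale)
}
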