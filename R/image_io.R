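#' Image stacks
#'
#' An `ImageStack` is a 3D greyscale volume: an integer array of
#' intensities in \[0, 255\] indexed `(row, col, slice)` together with the
#' physical voxel size `(dx, dy, dz)` in nm. Single slices are stored as
#' one-slice volumes.
#'
#' @param voxels numeric array, 2D (a single slice) or 3D; values must lie
#'   in \[0, 255\].
#' @param voxel_size numeric length-3, voxel edge lengths in nm. Defaults
#'   to the SBF-SEM acquisition spacing of 10 x 10 x 50 nm.
#' @return An object of class `ImageStack` with elements `voxels` (3D
#'   array) and `voxel_size`.
#' @export
image_stack <- function(voxels, voxel_size = DEFAULT_VOXEL_SIZE) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 2D or 3D array")
  if (anyNA(voxels) || min(voxels) < 0 || max(voxels) > 255)
    stop("intensities must lie in [0, 255]")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(
    list(voxels = voxels, voxel_size = as.numeric(voxel_size)),
    class = "ImageStack"
  )
}

#' @export
dim.ImageStack <- function(x) dim(x$voxels)

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "ImageStack: %d x %d x %d voxels, voxel size (%g, %g, %g) nm\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

n_slices <- function(stack) dim(stack$voxels)[3]

# sort filenames by the first integer they contain, falling back to
# lexicographic order when no number is present
order_slice_files <- function(files) {
  num <- suppressWarnings(as.numeric(sub(
    ".*?(\\d+)(?!.*\\d).*", "\\1", basename(files), perl = TRUE
  )))
  if (anyNA(num)) order(basename(files)) else order(num, basename(files))
}

# one page as read by tiff::readTIFF -> 8-bit integer matrix
page_to_8bit <- function(page) {
  if (length(dim(page)) == 3L) page <- page[, , 1L]  # first channel
  if (is.double(page) && max(page) <= 1 && min(page) >= 0) {
    page <- page * 255
  }
  rng <- range(page)
  if (rng[2] > 255 || rng[1] < 0) {  # >8-bit input: min-max stretch
    page <- if (rng[2] > rng[1]) (page - rng[1]) / (rng[2] - rng[1]) * 255
            else page * 0
  }
  matrix(as.integer(round(page)), nrow(page), ncol(page))
}

#' Read a TIFF slice stack
#'
#' Reads a volume stored either as a directory of single-channel TIFF
#' files (one slice per file, ordered by the number embedded in each file
#' name) or as one multipage TIFF. Inputs of bit depth greater than 8 are
#' min-max rescaled to \[0, 255\].
#'
#' @param path directory containing `.tif`/`.tiff` slice files, or the
#'   path of a multipage TIFF file.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size = DEFAULT_VOXEL_SIZE) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no TIFF files found in ", path)
    files <- files[order_slice_files(files)]
    pages <- lapply(files, function(f) page_to_8bit(tiff::readTIFF(f)))
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, page_to_8bit)
  } else {
    stop("path does not exist: ", path)
  }
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("slices have inconsistent dimensions")
  vox <- array(0L, c(dims[[1]], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]]
  image_stack(vox, voxel_size)
}

#' Write a TIFF slice stack
#'
#' Writes an [image_stack()] as 8-bit single-channel TIFF. If `path` ends
#' in `.tif`/`.tiff` a multipage file is written, otherwise `path` is
#' created as a directory of files `slice_0001.tif`, `slice_0002.tif`, ...
#'
#' @param stack an [image_stack()].
#' @param path output file or directory.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  pages <- lapply(seq_len(n_slices(stack)),
                  function(k) stack$voxels[, , k] / 255)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(pages)) {
      tiff::writeTIFF(pages[[k]],
                      file.path(path, sprintf("slice_%04d.tif", k)),
                      bits.per.sample = 8L)
    }
  }
  invisible(path)
}

#' Crop a cell sub-volume around a centroid
#'
#' Extracts the sub-volume of the requested size centred on a manually
#' selected cell centroid, as used to isolate one cell from a full
#' acquisition. Windows extending beyond the stack are clipped; the
#' realized extents are reported in the `"crop_window"` attribute.
#'
#' @param stack an [image_stack()].
#' @param centroid integer (row, col, slice), 1-based, inside the stack.
#' @param size integer (height, width, depth) of the requested window.
#' @return An [image_stack()] holding the (possibly clipped) sub-volume,
#'   with attribute `crop_window`, a list with the realized `lo`/`hi`
#'   indices in the parent stack and a logical `clipped`.
#' @export
crop_cell <- function(stack, centroid, size) {
  stopifnot(inherits(stack, "ImageStack"),
            length(centroid) == 3L, length(size) == 3L, all(size >= 1))
  d <- dim(stack)
  centroid <- as.integer(round(centroid))
  if (any(centroid < 1L) || any(centroid > d))
    stop("centroid lies outside the stack")
  lo <- centroid - as.integer(ceiling(size / 2)) + 1L
  hi <- lo + as.integer(size) - 1L
  lo_c <- pmax(lo, 1L)
  hi_c <- pmin(hi, d)
  out <- image_stack(
    stack$voxels[lo_c[1]:hi_c[1], lo_c[2]:hi_c[2], lo_c[3]:hi_c[3],
                 drop = FALSE],
    stack$voxel_size
  )
  attr(out, "crop_window") <- list(lo = lo_c, hi = hi_c,
                                   clipped = any(lo_c != lo | hi_c != hi))
  out
}

#' Read and write binary masks
#'
#' Masks are stored as 8-bit TIFF with values 0 (background) and 255
#' (foreground), one slice per file in a directory or as a multipage
#' file, mirroring [read_stack()]/[write_stack()].
#'
#' @param mask logical matrix or 3D logical array.
#' @param path file or directory path.
#' @return `read_mask()` returns a logical array (3D; a single-slice file
#'   yields one slice). `write_mask()` returns `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.logical(mask)) stop("'mask' must be logical")
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  write_stack(image_stack(array(ifelse(mask, 255L, 0L), dim(mask))), path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  stack <- read_stack(path)
  stack$voxels > 127L
}
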