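test_that("Gaussian kernel matches the closed form and normalizes", {
  k <- nesegment:::gaussian_kernel(7L, 2)
  expect_equal(sum(k), 1, tolerance = 1e-9)
  # direct evaluation of exp(-(x^2+y^2)/(2 sigma^2)), normalized
  x <- -3:3
  ref <- exp(-outer(x^2, x^2, "+") / (2 * 4))
  ref <- ref / sum(ref)
  expect_equal(k, ref, tolerance = 1e-12)

  # unit impulse reproduces the kernel
  img <- matrix(0, 15, 15)
  img[8, 8] <- 1
  out <- smooth_slice(img, 7L, 2)
  expect_equal(out[5:11, 5:11], ref, tolerance = 1e-12)
})

test_that("smoothing preserves constants and rejects even kernel sizes", {
  img <- matrix(77, 20, 20)
  expect_equal(smooth_slice(img, 7L, 2), img)
  expect_error(smooth_slice(img, 6L, 2), "odd")
  expect_error(seg_params(gauss_size = 4L), "odd")
})

test_that("Canny finds canonical edges and nothing on flat images", {
  expect_false(any(canny(matrix(5, 30, 30), 1)))

  # vertical step edge -> edge line at the step column (+/- 1)
  step <- matrix(100, 40, 40)
  step[, 21:40] <- 30
  e <- canny(step, 1)
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_true(all(cols %in% 19:22))
  expect_equal(length(unique(which(e, arr.ind = TRUE)[, 1])), 40L)

  # dark disk on bright background -> thin ring within 2 px of the circle
  n <- 101
  r2 <- outer((1:n - 51)^2, (1:n - 51)^2, "+")
  disk <- matrix(200, n, n)
  disk[r2 <= 30^2] <- 60
  e <- canny(disk, 1)
  pts <- which(e, arr.ind = TRUE)
  dist <- sqrt((pts[, 1] - 51)^2 + (pts[, 2] - 51)^2)
  expect_true(all(abs(dist - 30) <= 2))
  # the ring is closed: one component covering all directions
  expect_equal(max(label_components(e)), 1L)
  ang <- atan2(pts[, 1] - 51, pts[, 2] - 51)
  expect_gt(length(unique(round(ang, 1))), 60)
})

test_that("edge dilation is an exact Euclidean-disk dilation", {
  empty <- matrix(FALSE, 20, 20)
  expect_identical(dilate_edges(empty, 5L), empty)

  single <- matrix(FALSE, 21, 21)
  single[11, 11] <- TRUE
  out <- dilate_edges(single, 5L)
  ref <- outer((1:21 - 11)^2, (1:21 - 11)^2, "+") <= 25
  expect_identical(out, ref)
  expect_true(all(out[single]))  # superset of the input

  # two fragments separated by an 8-px gap fuse at radius 5
  frag <- matrix(FALSE, 30, 30)
  frag[15, 5:10] <- TRUE
  frag[15, 19:24] <- TRUE
  expect_equal(max(label_components(frag)), 2L)
  expect_equal(max(label_components(dilate_edges(frag, 5L))), 1L)
})

test_that("superpixels are the 8-connected components of the edge complement", {
  none <- matrix(FALSE, 12, 12)
  sp <- label_superpixels(none)
  expect_equal(sp$K, 1L)
  expect_true(all(sp$labels == 1L))

  wall <- matrix(FALSE, 12, 12)
  wall[, 6] <- TRUE
  expect_equal(label_superpixels(wall)$K, 2L)

  # random edge mask against a brute-force flood-fill oracle
  flood_fill_components <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    nxt <- 0L
    for (start in which(mask)) {
      if (lab[start] != 0L) next
      nxt <- nxt + 1L
      queue <- start
      lab[start] <- nxt
      while (length(queue)) {
        pix <- queue[1]
        queue <- queue[-1]
        i <- (pix - 1L) %% nrow(mask) + 1L
        j <- (pix - 1L) %/% nrow(mask) + 1L
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di
          jj <- j + dj
          if (ii < 1 || jj < 1 || ii > nrow(mask) || jj > ncol(mask)) next
          q <- (jj - 1L) * nrow(mask) + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
    lab
  }
  set.seed(14)
  edges <- matrix(runif(400) < 0.35, 20, 20)
  got <- label_superpixels(edges)$labels
  want <- flood_fill_components(!edges)
  # same partition up to label numbering
  expect_equal(max(got), max(want))
  for (k in seq_len(max(want))) {
    expect_equal(length(unique(got[want == k])), 1L)
  }
  # partition property: labels and edges tile the slice
  expect_true(all((got > 0) != edges))
})

test_that("superpixel filtering drops border and small regions, fills holes", {
  p <- seg_params(min_region_fraction = 0.01, close_radius = 1L)
  lab <- matrix(0L, 40, 40)
  lab[10:30, 10:30] <- 1L       # central region with a hole
  lab[15:20, 15:20] <- 0L
  lab[1:5, 35:40] <- 2L         # touches the border
  lab[35, 35] <- 3L             # too small (1 px < 16 px)
  sp <- structure(list(labels = lab, K = 3L), class = "superpixel_image")
  out <- filter_superpixels(sp, p)
  expect_equal(length(out), 1L)
  expect_true(all(out[[1]][15:20, 15:20]))  # hole filled
  d <- dim(out[[1]])
  expect_false(any(out[[1]][1, ]) || any(out[[1]][d[1], ]) ||
                 any(out[[1]][, 1]) || any(out[[1]][, d[2]]))
})

test_that("segment_slice finds the nuclear region on easy slices", {
  ph <- small_phantom()
  k <- 20L
  cands <- segment_slice(ph$stack$voxels[, , k])
  expect_equal(length(cands), 1L)
  expect_gte(jaccard(cands[[1]], ph$nucleus[, , k]), 0.9)

  # pure background slice: constant plus faint noise
  set.seed(8)
  bg <- matrix(pmin(255, pmax(0, round(200 + rnorm(128^2, 0, 2)))), 128, 128)
  expect_equal(length(segment_slice(bg)), 0L)
})

test_that("a slice with two ring-bounded regions yields two candidates", {
  ph <- notched_phantom()
  ncomp <- vapply(seq_len(dim(ph$nucleus)[3]),
                  function(k) max(label_components(ph$nucleus[, , k])),
                  integer(1))
  k <- which(ncomp >= 2L)[1]
  cands <- segment_slice(ph$stack$voxels[, , k])
  expect_gte(length(cands), 2L)
})

test_that("segment_slice is deterministic and candidates are disjoint", {
  ph <- small_phantom()
  img <- ph$stack$voxels[, , 14]
  a <- segment_slice(img)
  b <- segment_slice(img)
  expect_identical(a, b)

  p <- seg_params()
  sm <- smooth_slice(img, p$gauss_size, p$gauss_sigma)
  sp <- label_superpixels(dilate_edges(detect_edges(sm, p), p$dilate_radius))
  cands <- filter_superpixels(sp, p)
  if (length(cands) > 1L) {
    overlap <- Reduce(`+`, lapply(cands, function(m) m * 1))
    expect_lte(max(overlap), 1)
  }
  for (m in cands) {
    d <- dim(m)
    expect_false(any(m[1, ]) || any(m[d[1], ]) ||
                   any(m[, 1]) || any(m[, d[2]]))
  }
})
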