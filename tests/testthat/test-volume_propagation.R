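mk <- function(dim, rows, cols) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  m
}

test_that("central-region selection prefers size, then centrality", {
  shp <- c(50L, 50L)
  small <- mk(shp, 2:11, 2:11)          # 100 px, off-centre
  big <- mk(shp, 10:40, 10:40)          # ~1000 px
  expect_identical(select_central_region(list(small, big), shp), big)
  expect_identical(select_central_region(list(big), shp), big)

  # equal areas: the centred one wins
  centred <- mk(shp, 21:30, 21:30)
  corner <- mk(shp, 1:10, 1:10)
  expect_identical(select_central_region(list(corner, centred), shp), centred)
  expect_error(select_central_region(list(), shp), "no nucleus")
})

test_that("propagation keeps exactly the overlapping candidates", {
  shp <- c(30L, 30L)
  prev <- mk(shp, 10:20, 10:20)
  inside <- mk(shp, 12:18, 12:18)
  outside <- mk(shp, 25:29, 25:29)
  touching <- mk(shp, 19:24, 19:24)

  expect_identical(propagate(prev, list(inside)), inside)
  expect_false(any(propagate(prev, list(outside))))
  got <- propagate(prev, list(inside, outside, touching))
  expect_identical(got, inside | touching)

  # per-candidate overlap-count oracle
  for (cand in list(inside, outside, touching)) {
    kept <- any(propagate(prev, list(cand)))
    expect_equal(kept, sum(cand & prev) > 0)
  }

  # minimum-overlap fraction discards marginal overlaps
  expect_false(any(propagate(prev, list(touching),
                             min_overlap_fraction = 0.5)))
})

test_that("envelope extraction matches a 4-neighbour scan", {
  disk <- mk(c(50L, 50L), 1, 1) & FALSE
  r2 <- outer((1:50 - 25)^2, (1:50 - 25)^2, "+")
  disk <- r2 <= 20^2
  env <- extract_envelope(disk)
  pts <- which(env, arr.ind = TRUE)
  dist <- sqrt((pts[, 1] - 25)^2 + (pts[, 2] - 25)^2)
  expect_true(all(dist > 18.5 & dist <= 20))
  expect_false(any(extract_envelope(matrix(FALSE, 10, 10))))

  set.seed(3)
  blob <- matrix(runif(900) < 0.4, 30, 30)
  blob <- EBImage::closing(blob * 1, nesegment:::disk_brush(2L)) > 0
  got <- extract_envelope(blob)
  # oracle: mask pixels with a 4-neighbour outside the mask (image
  # border counts as outside)
  ref <- blob
  for (i in seq_len(30)) for (j in seq_len(30)) {
    if (!blob[i, j]) { ref[i, j] <- FALSE; next }
    nb <- c(
      if (i > 1) blob[i - 1, j] else FALSE,
      if (i < 30) blob[i + 1, j] else FALSE,
      if (j > 1) blob[i, j - 1] else FALSE,
      if (j < 30) blob[i, j + 1] else FALSE
    )
    ref[i, j] <- !all(nb)
  }
  expect_identical(got, ref)
})

test_that("segment_volume recovers a phantom nucleus accurately", {
  ph <- small_phantom()
  nuc <- small_segmentation()
  expect_s3_class(nuc, "NucleusVolume")
  expect_gte(jaccard(nuc$mask, ph$nucleus), 0.9)

  # envelope voxels lie inside the mask and on its 2D boundary
  expect_true(all(nuc$mask[nuc$envelope]))
  expect_identical(nuc$envelope, extract_envelope(nuc$mask))

  # determinism of the full sweep
  again <- segment_volume(ph$stack)
  expect_identical(again$mask, nuc$mask)
})

test_that("the accepted mask never contains pixels outside the candidates", {
  ph <- small_phantom()
  nuc <- small_segmentation()
  for (k in c(12L, 20L, 28L)) {
    cands <- segment_slice(ph$stack$voxels[, , k])
    union <- Reduce(`|`, cands, matrix(FALSE, 160, 160))
    expect_false(any(nuc$mask[, , k] & !union))
  }
})

test_that("disjoint islands connected through lower slices are retained", {
  ph <- notched_phantom()
  nuc <- notched_segmentation()
  ncomp <- vapply(seq_len(dim(ph$nucleus)[3]),
                  function(k) max(label_components(ph$nucleus[, , k])),
                  integer(1))
  split_slices <- which(ncomp >= 2L)
  expect_gte(length(split_slices), 1L)
  for (k in split_slices) {
    lab <- label_components(ph$nucleus[, , k])
    for (l in seq_len(max(lab))) {
      expect_gt(sum(nuc$mask[, , k] & lab == l), 0)
    }
  }
})

test_that("an empty central slice aborts the volume sweep", {
  set.seed(21)
  flatish <- array(
    as.integer(pmin(255, pmax(0, round(200 + rnorm(128 * 128 * 5, 0, 2))))),
    c(128L, 128L, 5L)
  )
  expect_error(segment_volume(image_stack(flatish)), "no nucleus")
})
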