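iso <- c(10, 10, 10)

test_that("the fitted spheroid matches centroid and volume", {
  ball <- ball_mask(c(80L, 80L, 80L), c(40, 40, 40), 30)
  sph <- fit_spheroid(ball, iso)
  expect_equal(sph$centre, c(40, 40, 40), tolerance = 0.01)
  expect_equal(sph$semi_axes, rep(30, 3), tolerance = 0.01)
  expect_gte(spheroid_jaccard(ball, sph), 0.95)

  # centroid equivariance under translation
  moved <- ball_mask(c(80L, 80L, 80L), c(50, 45, 42), 30)
  sph2 <- fit_spheroid(moved, iso)
  expect_equal(sph2$centre - sph$centre, c(10, 5, 2), tolerance = 0.02)

  # ellipsoid 40 x 30 x 20 semi-axes: radius = (40*30*20)^(1/3)
  d <- c(100L, 100L, 60L)
  q <- outer(outer(((1:100 - 50) / 40)^2, ((1:100 - 50) / 30)^2, "+"),
             ((1:60 - 30) / 20)^2, "+")
  ell <- q <= 1
  sph3 <- fit_spheroid(ell, iso)
  expect_equal(sph3$semi_axes[1], (40 * 30 * 20)^(1 / 3), tolerance = 0.02)

  expect_error(fit_spheroid(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("rasterized spheroid volume is conserved within 1%", {
  for (shape in list(ball_mask(c(70L, 70L, 70L), c(35, 35, 36), 25),
                     small_phantom()$nucleus)) {
    vs <- if (is.logical(shape) && dim(shape)[1] == 70) iso else c(10, 10, 50)
    sph <- fit_spheroid(shape, vs)
    ratio <- sum(rasterize_spheroid(sph, dim(shape))) / sum(shape)
    expect_lt(abs(ratio - 1), 0.01)
  }
})

test_that("spheroid Jaccard equals the nested-ball volume ratio", {
  d <- c(90L, 90L, 90L)
  r <- 25
  ball <- ball_mask(d, c(45, 45, 45), r)
  # force a spheroid of twice the volume, concentric
  big <- fit_spheroid(ball, iso)
  big$semi_axes <- big$semi_axes * 2^(1 / 3)
  big$semi_axes_nm <- big$semi_axes_nm * 2^(1 / 3)
  expect_equal(spheroid_jaccard(ball, big), 0.5, tolerance = 0.02)
})

test_that("ray map of a ball against its own spheroid is flat at zero", {
  ball <- ball_mask(c(80L, 80L, 80L), c(40, 40, 40), 28)
  sph <- fit_spheroid(ball, iso)
  map <- ray_distances(ball, sph, n_lon = 72L, n_lat = 36L, voxel_size = iso)
  expect_equal(map$n_missing, 0L)
  expect_lte(max(abs(map$grid)), 1)
  expect_lte(abs(mean(map$grid)), 1)
})

test_that("concentric offset shows up as a constant positive altitude", {
  ball <- ball_mask(c(90L, 90L, 90L), c(45, 45, 45), 30)
  sph <- fit_spheroid(ball, iso)
  sph$semi_axes <- rep(25, 3)         # force a smaller model sphere
  sph$semi_axes_nm <- rep(250, 3)
  map <- ray_distances(ball, sph, n_lon = 72L, n_lat = 36L, voxel_size = iso)
  expect_true(all(abs(map$grid - 5) <= 1))
})

test_that("a polar notch appears as a valley in the surface map", {
  ph <- notched_phantom()
  sph <- fit_spheroid(ph$nucleus, ph$stack$voxel_size)
  map <- ray_distances(ph$nucleus, sph, n_lon = 90L, n_lat = 45L,
                       voxel_size = ph$stack$voxel_size)
  # deepest valley in the notched upper-polar band, clearly negative
  upper <- map$grid[, map$lat > 0.5]
  expect_lt(min(upper, na.rm = TRUE), -10)
})

test_that("surface metrics summarize the altitude grid", {
  as_map <- function(grid) structure(
    list(grid = grid, lon = numeric(nrow(grid)), lat = numeric(ncol(grid)),
         n_missing = sum(is.na(grid))),
    class = "SurfaceMap"
  )
  ball <- ball_mask(c(60L, 60L, 60L), c(30, 30, 30), 20)
  sph <- fit_spheroid(ball, iso)

  flat <- surface_metrics(as_map(matrix(0, 10, 5)), ball, sph, iso)
  expect_equal(flat$mean_mu, 0)
  expect_equal(flat$std_sigma, 0)
  expect_equal(flat$range_, 0)

  const <- surface_metrics(as_map(matrix(3.5, 10, 5)), ball, sph, iso)
  expect_equal(const$mean_mu, 3.5)
  expect_equal(const$std_sigma, 0)

  m <- surface_metrics(as_map(matrix(c(-2, -1, 1, 2), 2, 2)), ball, sph, iso)
  expect_equal(m$mean_mu, 0)
  expect_equal(m$range_, 4)
  expect_equal(m$std_sigma, sqrt(2.5))
  expect_equal(m$volume_um3, sum(ball) * 1000 / 1e9)

  expect_error(surface_metrics(as_map(matrix(NA_real_, 4, 4)), ball, sph,
                               iso), "no valid rays")
})

test_that("metric correlations behave on toy and degenerate input", {
  toy <- data.frame(ji_spheroid = c(0.5, 0.6, 0.7, 0.8),
                    mean_mu = c(1, 2, 3, 4),
                    std_sigma = c(8, 6, 4, 2),
                    range_ = c(5, 5, 5, 5))
  expect_warning(cors <- correlate_metrics(toy), "zero-variance")
  expect_equal(unname(cors["cor_ji_mu"]), 1)
  expect_equal(unname(cors["cor_ji_sigma"]), -1)
  expect_true(is.na(cors["cor_ji_range"]))
  expect_error(correlate_metrics(toy[1:2, ]))
})

test_that("the reference HeLa table has the expected layout", {
  tab <- hela_surface_table()
  expect_equal(nrow(tab), 7L)
  expect_true(all(c("volume_um3", "ji_spheroid", "mean_mu", "std_sigma",
                    "range_", "ratio_above", "ratio_below") %in% names(tab)))
  expect_true(all(tab$ji_spheroid > 0 & tab$ji_spheroid < 1))
  expect_true(all(diff(tab$volume_um3) > 0))
})
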