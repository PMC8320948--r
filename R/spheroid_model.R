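#' Fit an equal-volume spheroid to a segmented nucleus
#'
#' The model surface is a sphere in physical (nm) coordinates with the
#' same volume as the nucleus, centred at the nucleus centroid. On the
#' anisotropic SBF-SEM grid (10 x 10 x 50 nm voxels) the sphere appears
#' as a spheroid in voxel units. Axis ratios other than 1 may be supplied
#' for generality.
#'
#' @param nucleus a `NucleusVolume` or 3D logical mask.
#' @param voxel_size numeric length-3, voxel edges in nm.
#' @param axis_ratio numeric length-3 relative semi-axis ratios in
#'   physical units; the default `c(1, 1, 1)` is a sphere.
#' @return An object of class `Spheroid`: `centre` (voxel coordinates,
#'   1-based), `semi_axes` (voxel units), `semi_axes_nm`, `volume_um3`
#'   (nucleus volume) and `voxel_size`.
#' @export
fit_spheroid <- function(nucleus, voxel_size = DEFAULT_VOXEL_SIZE,
                         axis_ratio = c(1, 1, 1)) {
  mask <- as_nucleus_mask(nucleus)
  n <- sum(mask)
  if (n == 0L) stop("empty nucleus mask")
  ijk <- which(mask, arr.ind = TRUE)
  centre <- colMeans(ijk)
  v_nm3 <- n * prod(voxel_size)
  # (4/3) pi r^3 prod(axis_ratio) = volume
  r <- (3 * v_nm3 / (4 * pi * prod(axis_ratio)))^(1 / 3)
  semi_nm <- r * axis_ratio
  structure(list(
    centre = unname(centre),
    semi_axes = unname(semi_nm / voxel_size),
    semi_axes_nm = unname(semi_nm),
    volume_um3 = v_nm3 / 1e9,
    voxel_size = as.numeric(voxel_size)
  ), class = "Spheroid")
}

#' @export
print.Spheroid <- function(x, ...) {
  cat(sprintf(
    "Spheroid: centre (%.1f, %.1f, %.1f) vox, semi-axes (%.1f, %.1f, %.1f) vox, volume %.2f um^3\n",
    x$centre[1], x$centre[2], x$centre[3],
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$volume_um3
  ))
  invisible(x)
}

#' Rasterize a spheroid onto a voxel grid
#'
#' @param spheroid a `Spheroid` from [fit_spheroid()].
#' @param dim integer length-3 grid dimensions.
#' @return 3D logical mask of voxels whose centres lie inside the
#'   spheroid.
#' @export
rasterize_spheroid <- function(spheroid, dim) {
  r <- (seq_len(dim[1]) - spheroid$centre[1]) / spheroid$semi_axes[1]
  c_ <- (seq_len(dim[2]) - spheroid$centre[2]) / spheroid$semi_axes[2]
  s <- (seq_len(dim[3]) - spheroid$centre[3]) / spheroid$semi_axes[3]
  q <- outer(outer(r^2, c_^2, "+"), s^2, "+")
  q <= 1
}

#' Jaccard index between a nucleus and its model spheroid
#'
#' With an equal-volume spheroid this index measures how spherical the
#' nuclear envelope is, not segmentation accuracy: 1 for a perfect
#' (rasterized) sphere, lower for lobed or invaginated nuclei.
#'
#' @param nucleus a `NucleusVolume` or 3D logical mask.
#' @param spheroid a `Spheroid`; defaults to [fit_spheroid()] of
#'   `nucleus`.
#' @param voxel_size voxel edges in nm (used when fitting the default
#'   spheroid).
#' @return Jaccard index in \[0, 1\].
#' @export
spheroid_jaccard <- function(nucleus, spheroid = NULL,
                             voxel_size = DEFAULT_VOXEL_SIZE) {
  mask <- as_nucleus_mask(nucleus)
  if (is.null(spheroid)) spheroid <- fit_spheroid(mask, voxel_size)
  jaccard(mask, rasterize_spheroid(spheroid, dim(mask)))
}

#' Ray-traced signed distances from the spheroid to the envelope
#'
#' Casts rays from the spheroid centre on an equirectangular
#' longitude-latitude grid. Along each ray the *outermost* crossing of
#' the nucleus surface is found (so invaginations appear as valleys, not
#' gaps) and the signed distance `(distance to envelope) - (distance to
#' spheroid surface)` is recorded: positive where the envelope lies
#' outside the spheroid. Distances are measured in physical units and
#' reported in in-plane pixel equivalents. Rays that never meet the
#' nucleus are `NA`.
#'
#' @param nucleus a `NucleusVolume` or 3D logical mask.
#' @param spheroid a `Spheroid`; defaults to [fit_spheroid()] of
#'   `nucleus`.
#' @param n_lon,n_lat angular grid resolution (longitude x latitude).
#' @param voxel_size voxel edges in nm.
#' @return An object of class `SurfaceMap`: `grid`, an `n_lon` x `n_lat`
#'   matrix of signed distances in in-plane pixels (`NA` = missing ray),
#'   plus `lon`, `lat` (radians) and `n_missing`.
#' @export
ray_distances <- function(nucleus, spheroid = NULL, n_lon = 360L,
                          n_lat = 180L, voxel_size = DEFAULT_VOXEL_SIZE) {
  mask <- as_nucleus_mask(nucleus)
  if (!any(mask)) stop("empty nucleus mask")
  if (is.null(spheroid)) spheroid <- fit_spheroid(mask, voxel_size)
  vs <- spheroid$voxel_size
  d <- dim(mask)
  ctr <- spheroid$centre

  lon <- (seq_len(n_lon) - 0.5) / n_lon * 2 * pi
  lat <- (seq_len(n_lat) - 0.5) / n_lat * pi - pi / 2
  ang <- expand.grid(lon = lon, lat = lat)
  # physical direction components: x along rows, y along cols, z along slices
  vx <- cos(ang$lat) * cos(ang$lon)
  vy <- cos(ang$lat) * sin(ang$lon)
  vz <- sin(ang$lat)

  # physical distance from the centre to the farthest grid corner
  corners <- expand.grid(r = c(1, d[1]), c = c(1, d[2]), s = c(1, d[3]))
  tmax <- sqrt(max(((corners$r - ctr[1]) * vs[1])^2 +
                   ((corners$c - ctr[2]) * vs[2])^2 +
                   ((corners$s - ctr[3]) * vs[3])^2))
  step <- min(vs) / 2
  ts <- seq(step / 2, tmax, by = step)

  G <- nrow(ang)
  t_ne <- rep(NA_real_, G)
  # march outward; the last hit along each ray is the outermost crossing
  for (t in ts) {
    rr <- as.integer(round(ctr[1] + t * vx / vs[1]))
    cc <- as.integer(round(ctr[2] + t * vy / vs[2]))
    ss <- as.integer(round(ctr[3] + t * vz / vs[3]))
    ok <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2] &
          ss >= 1L & ss <= d[3]
    if (!any(ok)) next
    lin <- (ss[ok] - 1L) * (d[1] * d[2]) + (cc[ok] - 1L) * d[1] + rr[ok]
    hit <- mask[lin]
    t_ne[which(ok)[hit]] <- t
  }

  # spheroid surface distance along each ray (sphere: constant radius)
  a <- spheroid$semi_axes_nm
  t_sph <- 1 / sqrt((vx / a[1])^2 + (vy / a[2])^2 + (vz / a[3])^2)

  grid <- matrix((t_ne - t_sph) / vs[1], n_lon, n_lat)
  structure(list(grid = grid, lon = lon, lat = lat,
                 n_missing = sum(is.na(grid))),
            class = "SurfaceMap")
}

#' @export
print.SurfaceMap <- function(x, ...) {
  cat(sprintf(
    "SurfaceMap: %d x %d (lon x lat), %d missing ray(s), range [%.1f, %.1f] px\n",
    nrow(x$grid), ncol(x$grid), x$n_missing,
    suppressWarnings(min(x$grid, na.rm = TRUE)),
    suppressWarnings(max(x$grid, na.rm = TRUE))
  ))
  invisible(x)
}

#' Summary metrics of a nuclear surface map
#'
#' Condenses the signed-distance surface into the metrics used to
#' characterise nuclear shape: the mean and population standard
#' deviation of the altitudes, their range (highest peak to deepest
#' valley), and the fraction of grid pixels falling within one standard
#' deviation above and below the mean (a peak of a given height may be a
#' thin spike or a plateau; the ratios tell these apart). The nuclear
#' volume (um^3) and the Jaccard index against the spheroid are included.
#'
#' @param map a `SurfaceMap` from [ray_distances()].
#' @param nucleus a `NucleusVolume` or 3D logical mask.
#' @param spheroid a `Spheroid`; defaults to [fit_spheroid()] of
#'   `nucleus`.
#' @param voxel_size voxel edges in nm.
#' @return One-row data frame with columns `volume_um3`, `ji_spheroid`,
#'   `mean_mu`, `std_sigma`, `range_`, `ratio_above`, `ratio_below`.
#' @export
surface_metrics <- function(map, nucleus, spheroid = NULL,
                            voxel_size = DEFAULT_VOXEL_SIZE) {
  stopifnot(inherits(map, "SurfaceMap"))
  v <- map$grid[!is.na(map$grid)]
  if (length(v) == 0L) stop("surface map has no valid rays")
  mask <- as_nucleus_mask(nucleus)
  if (is.null(spheroid)) spheroid <- fit_spheroid(mask, voxel_size)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))  # population SD
  data.frame(
    volume_um3 = spheroid$volume_um3,
    ji_spheroid = spheroid_jaccard(mask, spheroid),
    mean_mu = mu,
    std_sigma = sigma,
    range_ = diff(range(v)),
    ratio_above = mean(v > mu & v <= mu + sigma),
    ratio_below = mean(v < mu & v >= mu - sigma)
  )
}

#' Correlate spherical similarity with surface statistics
#'
#' Pearson correlations between the spheroid Jaccard index and each of
#' the surface statistics across a set of cells. A nucleus closer to a
#' spheroid (higher JI) has a smoother surface, so JI is expected to
#' anticorrelate with sigma and range.
#'
#' @param table data frame with at least columns `ji_spheroid`,
#'   `mean_mu`, `std_sigma`, `range_` (one row per cell, >= 3 rows), as
#'   returned by [surface_metrics()] or [hela_surface_table()].
#' @return Named numeric vector `cor_ji_mu`, `cor_ji_sigma`,
#'   `cor_ji_range` (`NA` with a warning for a zero-variance column).
#' @export
correlate_metrics <- function(table) {
  need <- c("ji_spheroid", "mean_mu", "std_sigma", "range_")
  stopifnot(all(need %in% names(table)), nrow(table) >= 3L)
  one <- function(col) {
    if (sd(table$ji_spheroid) == 0 || sd(table[[col]]) == 0) {
      warning("zero-variance column: correlation undefined")
      return(NA_real_)
    }
    cor(table$ji_spheroid, table[[col]])
  }
  c(cor_ji_mu = one("mean_mu"),
    cor_ji_sigma = one("std_sigma"),
    cor_ji_range = one("range_"))
}

#' Reference surface metrics for seven HeLa nuclei
#'
#' Published surface-modelling metrics for the seven HeLa cell nuclei of
#' the public SBF-SEM dataset EMPIAR-10094 (300 slices of 2000 x 2000
#' pixels per cell, 10 x 10 x 50 nm voxels): nuclear volume, Jaccard
#' index against the equal-volume spheroid, and the mean, standard
#' deviation and range of the ray-traced surface altitudes, with the
#' pixel ratios one standard deviation above and below the mean.
#'
#' @return Data frame with seven rows and columns `volume_um3`,
#'   `ji_spheroid`, `mean_mu`, `std_sigma`, `range_`, `ratio_above`,
#'   `ratio_below`.
#' @export
hela_surface_table <- function() {
  data.frame(
    volume_um3 = c(393, 442, 454, 487, 502, 580, 600),
    ji_spheroid = c(0.5538, 0.6610, 0.6989, 0.7084, 0.6643, 0.5991, 0.5801),
    mean_mu = c(-23.424, -17.018, -11.013, -16.467, -27.290, -27.882, -29.894),
    std_sigma = c(142.47, 105.11, 96.968, 98.528, 116.11, 135.57, 163.80),
    range_ = c(681, 517, 553, 577, 544, 703, 894),
    ratio_above = c(0.16, 0.13, 0.12, 0.15, 0.13, 0.19, 0.17),
    ratio_below = c(0.19, 0.18, 0.17, 0.15, 0.19, 0.18, 0.15)
  )
}
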