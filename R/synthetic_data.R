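#' Phantom parameters
#'
#' Parameters of the seeded SBF-SEM phantom generator. A phantom emulates
#' one cropped cell: bright homogeneous resin background, darker textured
#' cytoplasm filling a cylindrical cell column that extends past the
#' image borders, a thin dark nuclear envelope around a mid-grey
#' nucleoplasm, dark clutter fragments from neighbouring cells touching
#' the image border, additive Gaussian noise, and (optionally) a rigid
#' inter-slice shift artefact. The nucleus is a radially perturbed
#' ellipsoid; an explicit polar notch of configurable depth and width
#' carves a trench across the upper pole so near-pole slices contain
#' disjoint cross-sections, as real nuclei do.
#'
#' Intensities must satisfy the assumptions the segmenter relies on: the
#' background is brighter than any cellular structure and the envelope is
#' darker than the nucleoplasm and cytoplasm.
#'
#' @param shape integer (n_h, n_w, n_d) stack dimensions.
#' @param voxel_size voxel edges (dx, dy, dz) in nm.
#' @param nucleus_radius in-plane nucleus semi-axis, voxels.
#' @param nucleus_z_radius nucleus semi-axis along the stack, slices.
#' @param deform_amplitude maximum relative radial perturbation of the
#'   nuclear surface (0 = perfect ellipsoid).
#' @param notch_depth depth of the polar notch, in-plane voxels (0
#'   disables it).
#' @param notch_width half-width of the notch trench, in-plane voxels.
#' @param background_intensity,cytoplasm_intensity,nucleoplasm_intensity,envelope_intensity
#'   grey levels (0-255) of the four tissue classes.
#' @param envelope_thickness radial thickness of the rendered envelope
#'   band, in-plane voxels.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param clutter_count number of dark border-touching fragments of
#'   neighbouring cells per stack.
#' @param cell_radius radius of the cytoplasm column, voxels; the default
#'   (70% of the slice side) makes the cell overrun all four image
#'   borders, as cropped single-cell volumes do.
#' @param shift_artifact `NULL`, or a list `(slice_index, d_rows,
#'   d_cols)`: all slices from `slice_index` on are rigidly translated.
#' @param seed integer seed; identical parameters and seed give a
#'   bitwise-identical phantom.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(256L, 256L, 60L),
                           voxel_size = c(10, 10, 50),
                           nucleus_radius = 100,
                           nucleus_z_radius = 24,
                           deform_amplitude = 0.05,
                           notch_depth = 0, notch_width = 16,
                           background_intensity = 200,
                           cytoplasm_intensity = 120,
                           nucleoplasm_intensity = 140,
                           envelope_intensity = 60,
                           envelope_thickness = 5,
                           noise_sigma = 6,
                           clutter_count = 4L,
                           cell_radius = NULL,
                           shift_artifact = NULL,
                           seed = 1L) {
  if (is.null(cell_radius)) cell_radius <- 0.7 * min(shape[1:2])
  p <- list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
            nucleus_radius = nucleus_radius,
            nucleus_z_radius = nucleus_z_radius,
            deform_amplitude = deform_amplitude,
            notch_depth = notch_depth, notch_width = notch_width,
            background_intensity = background_intensity,
            cytoplasm_intensity = cytoplasm_intensity,
            nucleoplasm_intensity = nucleoplasm_intensity,
            envelope_intensity = envelope_intensity,
            envelope_thickness = envelope_thickness,
            noise_sigma = noise_sigma,
            clutter_count = as.integer(clutter_count),
            cell_radius = cell_radius,
            shift_artifact = shift_artifact,
            seed = as.integer(seed))
  if (!(p$background_intensity > p$nucleoplasm_intensity &&
        p$nucleoplasm_intensity > p$envelope_intensity))
    stop("intensity ordering violated: need background > nucleoplasm > envelope")
  if (p$cytoplasm_intensity >= p$background_intensity ||
      p$cytoplasm_intensity <= p$envelope_intensity)
    stop("cytoplasm intensity must lie between envelope and background")
  if (p$envelope_thickness < 1) stop("envelope_thickness must be >= 1")
  if (p$deform_amplitude < 0 || p$deform_amplitude >= 0.5)
    stop("deform_amplitude must be in [0, 0.5)")
  class(p) <- "phantom_params"
  p
}

# smooth band-limited random field on the sphere of directions:
# a sum of von Mises-Fisher bumps, normalized to max |f| = 1
random_sphere_field <- function(vx, vy, vz, n_bumps = 12L, kappa = 8) {
  u <- matrix(rnorm(3L * n_bumps), n_bumps, 3L)
  u <- u / sqrt(rowSums(u^2))
  coef <- rnorm(n_bumps)
  f <- 0
  for (i in seq_len(n_bumps)) {
    f <- f + coef[i] *
      exp(kappa * (vx * u[i, 1] + vy * u[i, 2] + vz * u[i, 3] - 1))
  }
  m <- max(abs(f))
  if (m > 0) f / m else f
}

#' Generate a synthetic SBF-SEM phantom with ground truth
#'
#' Renders the phantom described by [phantom_params()] and returns the
#' image stack together with exact ground-truth masks. The nucleus is the
#' set of voxels whose normalized ellipsoidal radius lies below a
#' direction-dependent surface radius `1 + deform_amplitude * f(v) -
#' notch(v)` where `f` is a smooth seeded random field on the sphere and
#' `notch` is a trench across the upper pole. The ground-truth envelope
#' is [extract_envelope()] of the ground-truth nucleus.
#'
#' @param params a [phantom_params()] object.
#' @return List with elements `stack` (an [image_stack()]), `nucleus` and
#'   `envelope` (3D logical ground-truth masks) and `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  withr::with_seed(p$seed, {
    d <- p$shape
    ctr <- (d + 1) / 2
    rr <- (seq_len(d[1]) - ctr[1]) / p$nucleus_radius
    cc <- (seq_len(d[2]) - ctr[2]) / p$nucleus_radius
    ss <- (seq_len(d[3]) - ctr[3]) / p$nucleus_z_radius
    QR <- array(rr, d)
    QC <- array(rep(cc, each = d[1]), d)
    QS <- array(rep(ss, each = d[1] * d[2]), d)
    rho <- sqrt(QR^2 + QC^2 + QS^2)
    rho0 <- rho
    rho0[rho0 == 0] <- 1
    vx <- QR / rho0
    vy <- QC / rho0
    vz <- QS / rho0

    f <- if (p$deform_amplitude > 0) random_sphere_field(vx, vy, vz) else 0

    depression <- 0
    if (p$notch_depth > 0) {
      # trench along the meridian plane containing the row axis,
      # acting on the upper pole only
      d_plane <- abs(vy) * p$nucleus_radius
      w_polar <- pmax(0, (vz - 0.35) / 0.65)
      depression <- (p$notch_depth / p$nucleus_radius) *
        exp(-(d_plane / p$notch_width)^2) * w_polar
    }

    surf <- 1 + p$deform_amplitude * f - depression
    nucleus <- rho <= surf
    inner <- rho <= surf - p$envelope_thickness / p$nucleus_radius

    # cytoplasm column through the whole stack, overrunning the borders
    in_plane_r2 <- outer((seq_len(d[1]) - ctr[1])^2,
                         (seq_len(d[2]) - ctr[2])^2, "+")
    cell2d <- in_plane_r2 <= p$cell_radius^2
    cell <- array(cell2d, d)

    img <- array(p$background_intensity, d)
    # cytoplasm texture: persistent across slices (organelles span many
    # 50 nm steps) and clearly weaker than the membrane contrast
    tex <- matrix(rnorm(prod(d[1:2]), 0, 40), d[1], d[2])
    tex <- conv2_replicate(tex, gaussian_kernel(9L, 1.5))
    img[cell] <- p$cytoplasm_intensity + array(tex, d)[cell]
    img[nucleus] <- p$nucleoplasm_intensity
    img[nucleus & !inner] <- p$envelope_intensity

    # dark fragments of neighbouring cells, centred on the image border;
    # they belong to other cells, so they stay clear of this nucleus
    if (p$clutter_count > 0L) {
      margin <- 2 * p$envelope_thickness + 2
      for (i in seq_len(p$clutter_count)) {
        side <- sample(4L, 1L)
        pos <- runif(1, 0.1, 0.9)
        cen <- switch(side,
          c(1, pos * d[2]), c(d[1], pos * d[2]),
          c(pos * d[1], 1), c(pos * d[1], d[2]))
        rad <- runif(1, 0.06, 0.12) * min(d[1:2])
        z0 <- sample(d[3], 1L)
        zr <- sample(3:8, 1L)
        blob2d <- outer((seq_len(d[1]) - cen[1])^2,
                        (seq_len(d[2]) - cen[2])^2, "+") <= rad^2
        for (k in max(1L, z0 - zr):min(d[3], z0 + zr)) {
          near_nuc <- if (any(nucleus[, , k]))
            grow_mask(nucleus[, , k], margin)
          else nucleus[, , k]
          sl <- img[, , k]
          sl[blob2d & !near_nuc] <- p$envelope_intensity + 20
          img[, , k] <- sl
        }
      }
    }

    if (p$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, p$noise_sigma)
    img <- array(as.integer(pmin(255, pmax(0, round(img)))), d)

    if (!is.null(p$shift_artifact)) {
      sa <- p$shift_artifact
      for (k in sa$slice_index:d[3]) {
        img[, , k] <- translate_slice(img[, , k], sa$d_rows, sa$d_cols,
                                      fill = as.integer(p$background_intensity))
        nucleus[, , k] <- translate_slice(nucleus[, , k], sa$d_rows,
                                          sa$d_cols, fill = FALSE)
      }
    }

    list(stack = image_stack(img, p$voxel_size),
         nucleus = nucleus,
         envelope = extract_envelope(nucleus),
         params = p)
  })
}

#' Generate a cohort of phantoms along a deformation ladder
#'
#' Produces `n_cells` phantoms that differ only in their deformation
#' amplitude, emulating a set of cells ranging from nearly spheroidal to
#' strongly lobed. All cells share the same seeded perturbation field so
#' that shape irregularity increases strictly along the ladder, which is
#' what downstream monotonicity checks (spheroid Jaccard index falling,
#' surface sigma rising) require. Cohort phantoms default to a compact
#' isotropic grid, which keeps spheroid rasterization effects small.
#'
#' @param n_cells number of cells (>= 2).
#' @param amplitude_ladder strictly increasing deformation amplitudes,
#'   one per cell.
#' @param seed integer seed shared by all cells.
#' @param base_params a [phantom_params()] object providing every other
#'   parameter.
#' @return List of `n_cells` phantom triples (see [generate_phantom()]).
#' @export
generate_cohort <- function(n_cells = 7L,
                            amplitude_ladder = seq(0.04, 0.34,
                                                   length.out = n_cells),
                            seed = 1L,
                            base_params = phantom_params(
                              shape = c(96L, 96L, 96L),
                              voxel_size = c(10, 10, 10),
                              nucleus_radius = 32,
                              nucleus_z_radius = 32,
                              noise_sigma = 4,
                              clutter_count = 0L
                            )) {
  stopifnot(n_cells >= 2L, length(amplitude_ladder) == n_cells,
            all(diff(amplitude_ladder) > 0))
  lapply(seq_len(n_cells), function(i) {
    p <- base_params
    p$deform_amplitude <- amplitude_ladder[i]
    p$seed <- as.integer(seed)
    generate_phantom(p)
  })
}
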