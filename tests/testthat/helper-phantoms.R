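# Shared phantom fixtures, generated once per test session and cached.
# Seeds and geometries are fixed so every run sees identical data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# moderate-size phantom for module-level tests
small_phantom <- function() fixture("small", function() {
  generate_phantom(phantom_params(
    shape = c(160L, 160L, 40L), nucleus_radius = 60,
    nucleus_z_radius = 16, seed = 3
  ))
})

small_segmentation <- function() fixture("small_seg", function() {
  segment_volume(small_phantom()$stack)
})

# study-scale phantom: the default generator conditions
study_phantom <- function() fixture("study", function() {
  generate_phantom(phantom_params(seed = 7))
})

study_segmentation <- function() fixture("study_seg", function() {
  segment_volume(study_phantom()$stack)
})

# phantom whose nucleus splits into two islands near the upper pole
notched_phantom <- function() fixture("notched", function() {
  generate_phantom(phantom_params(
    shape = c(192L, 192L, 48L), nucleus_radius = 72,
    nucleus_z_radius = 18, notch_depth = 36, notch_width = 14, seed = 5
  ))
})

notched_segmentation <- function() fixture("notched_seg", function() {
  segment_volume(notched_phantom()$stack)
})

# stack with an injected rigid displacement artefact mid-stack
shifted_phantom <- function(seed = 2L) fixture(paste0("shifted", seed), function() {
  generate_phantom(phantom_params(
    shape = c(160L, 160L, 24L), nucleus_radius = 56,
    nucleus_z_radius = 20,
    shift_artifact = list(slice_index = 13L, d_rows = 11L, d_cols = 20L),
    seed = seed
  ))
})

# the same phantom without the artefact (identical RNG stream)
unshifted_phantom <- function(seed = 2L) fixture(paste0("unshifted", seed), function() {
  generate_phantom(phantom_params(
    shape = c(160L, 160L, 24L), nucleus_radius = 56,
    nucleus_z_radius = 20, seed = seed
  ))
})

cohort_phantoms <- function() fixture("cohort", function() {
  generate_cohort(7L, seed = 3)
})

cohort_metrics <- function() fixture("cohort_metrics", function() {
  do.call(rbind, lapply(cohort_phantoms(), function(ph) {
    sph <- fit_spheroid(ph$nucleus, ph$stack$voxel_size)
    map <- ray_distances(ph$nucleus, sph, n_lon = 90L, n_lat = 45L,
                         voxel_size = ph$stack$voxel_size)
    surface_metrics(map, ph$nucleus, sph, ph$stack$voxel_size)
  }))
})

# voxelized ball mask on an isotropic grid
ball_mask <- function(dim, centre, radius) {
  r2 <- outer(outer((seq_len(dim[1]) - centre[1])^2,
                    (seq_len(dim[2]) - centre[2])^2, "+"),
              (seq_len(dim[3]) - centre[3])^2, "+")
  r2 <= radius^2
}
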