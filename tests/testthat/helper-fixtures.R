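# Shared fixture builders.  Unit tests run on reduced geometries (smaller
# grids, coarser tilt increments) so each file stays fast; the acceptance
# tests use the full study geometry and cache their runs across test blocks.

# a centred sphere phantom
fix_sphere <- function(diameter = 20, voxel = 1, n = 48, seed = 1) {
  make_sphere_phantom(particle_spec("sphere", diameter = diameter, seed = seed),
                      voxel, c(n, n, n))
}

# acquisition with fewer angles for unit tests
fix_params <- function(..., increment = 2) {
  acquisition_params(increment = increment, ...)
}

# noise-free projection of a small sphere field
fix_sphere_series <- function(n_spheres = 3, diameter = 16, grid = 64,
                              seed = 5, params = fix_params(dose = 0, jitter_max = 0)) {
  specs <- lapply(seq_len(n_spheres),
                  function(i) particle_spec("sphere", diameter = diameter,
                                            seed = seed + i))
  field <- rasterize_field(specs, 1, rep(grid, 3), 5, seed = seed)
  list(field = field,
       series = suppressWarnings(project_series(field$volume, params)))
}

# cache for the expensive end-to-end acceptance runs, shared across blocks
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_t1 <- function() {
  if (is.null(.acceptance_cache$t1))
    .acceptance_cache$t1 <- simulate_material(default_config(), seeds = 1:10)
  .acceptance_cache$t1
}

acceptance_t2 <- function() {
  if (is.null(.acceptance_cache$t2)) {
    cfg <- default_config()
    cfg$phantom$diameter_range <- c(16, 24)
    .acceptance_cache$t2 <- simulate_material(cfg, seeds = 1:10)
  }
  .acceptance_cache$t2
}
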