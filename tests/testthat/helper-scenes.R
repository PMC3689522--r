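# Shared geometry and memoised synthetic scenes for the test suite. The
# generator is seeded, so every helper is deterministic.

std_geom <- function(beam = c(100, 100), distance = 150, sense = 1L)
  experiment_geometry(wavelength = 1.0, distance = distance,
                      beam_centre = beam, spindle_sense = sense)

.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- force(expr)
  .scene_cache[[key]]
}

# the standard orthorhombic two-image study scene
ortho_scene <- function(seed = 1, noise = 0.03, cell = c(50, 60, 70, 90, 90, 90),
                        ...) {
  generate_spots(synthetic_scene(crystal(cell), std_geom(),
                                 noise_sigma_mm = noise, seed = seed, ...))
}

cached_ortho <- function(seed = 1)
  cached(paste0("ortho", seed), ortho_scene(seed))

# truth basis of crystal k in a generated scene
truth_basis <- function(gen, cell, k = 1L)
  gen$orientations[[k]] %*% basis_from_cell(cell)

expect_cell_close <- function(cell, target, len_tol_frac = 0.005,
                              ang_tol_deg = 0.3) {
  expect_lt(max(abs(cell[1:3] - target[1:3]) / target[1:3]), len_tol_frac)
  expect_lt(max(abs(cell[4:6] - target[4:6])), ang_tol_deg)
}
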