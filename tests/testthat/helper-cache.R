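## Session-level cache so expensive PDE solves are shared across test files.
.pf_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .pf_cache))
    assign(key, force(expr), envir = .pf_cache)
  get(key, envir = .pf_cache)
}

## Reduced-length channel for unit tests (acceptance uses the full default);
## still >= 10x the largest semi-major axis used here.
test_geom <- function() channel_geometry(height = 250e-6, length = 1.2e-3)

fld_empty <- function() cached("empty", solve_channel_flow(
  channel_geometry(height = 254e-6, length = 1e-3),
  fluid_properties(), mesh = mesh_spec(5e-6)))

fld_solid40 <- function() cached("solid40", solve_channel_flow(
  test_geom(), fluid_properties(), nodule_geometry(a = 40e-6),
  solid_nodule(), mesh_spec(4e-6)))

fld_porous40 <- function() cached("porous40", solve_channel_flow(
  test_geom(), fluid_properties(), nodule_geometry(a = 40e-6),
  porous_properties(), mesh_spec(4e-6)))

## Small synthetic scene shared by image-pipeline tests.
small_spec <- function(seed = 3L, ...) scene_spec(
  grid_rows = 2L, grid_cols = 2L, tile_px = 128L, n_planes = 4L,
  nodule_count = 12L, seed = seed, ...)

small_planted <- function() cached("small_planted", plant_nodules(small_spec()))

small_params <- function() cached("small_params",
  do.call(calibrate_threshold, calibration_images(small_spec())))
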