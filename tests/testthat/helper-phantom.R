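# Shared fixtures: a small, fast valve phantom (quarter-scale murine
# geometry, coarse voxels) generated once per test run, plus its measured
# pipeline output. Everything is generated in code; no files are stored.

.fixture_env <- new.env(parent = emptyenv())

mini_params <- function(voxel_size = 6, tilt = 10, ...) {
  args <- list(wall_radius_at_ANL = 260, wall_radius_at_STJ = 230,
               valve_height_true = 210, leaflet_thickness_true = 24,
               belly_sag_depth = 40, free_edge_mid_height = -15,
               tilt_angle_true = tilt, voxel_size = voxel_size,
               wall_thickness = 30)
  args[names(list(...))] <- list(...)
  do.call(valve_phantom_params, args)
}

mini_phantom <- function() {
  if (is.null(.fixture_env$phantom)) {
    .fixture_env$phantom <- generate_valve_phantom(mini_params())
  }
  .fixture_env$phantom
}

mini_measurement <- function() {
  if (is.null(.fixture_env$measurement)) {
    .fixture_env$measurement <- measure_gqoi(mini_phantom()$volume,
                                             sample_id = "mini", tvp = 10)
  }
  .fixture_env$measurement
}

mini_surface <- function(leaflet = "left") {
  key <- paste0("surface_", leaflet)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- fit_leaflet_surface(mini_phantom()$volume,
                                               mini_measurement()$landmarks,
                                               leaflet)
  }
  .fixture_env[[key]]
}

# tiny labeled volume with hand-placed labels for brute-force oracles
toy_volume <- function() {
  g <- array(0L, c(12, 12, 8))
  g[2:11, 2:3, 1:8] <- 1L          # "wall" slab
  g[3:6, 4:6, 2:5] <- 2L           # leaflet A
  g[7:10, 4:6, 2:5] <- 3L          # leaflet B touching A at x = 6/7
  g[3:10, 7:9, 2:4] <- 4L          # leaflet C touching A and B
  valve_volume(g, voxel_size = 2)
}
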