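# Landmark detection: commissures, edge chains, planes.

test_that("adjacency scans match a brute-force voxel oracle", {
  v <- toy_volume()
  d <- dim(v$grid)
  for (pair in list(c(2L, 3L), c(2L, 4L), c(3L, 1L))) {
    expect_identical(sort(valvemorph:::cpp_adjacency(v$grid, d, pair[1], pair[2])),
                     brute_adjacency(v$grid, pair[1], pair[2]))
  }
})

test_that("missing leaflet label raises a landmark error", {
  v <- toy_volume()
  g <- array(as.integer(v$grid), dim(v$grid))
  g[g == 4L] <- 0L
  v2 <- valve_volume(g, v$voxel_size)
  expect_error(find_commissures(v2), "absent")
})

test_that("phantom commissures are recovered within two voxels", {
  ph <- mini_phantom()
  comm <- find_commissures(ph$volume)
  truth <- ph$truth$landmarks$commissures
  for (i in 1:3) {
    expect_lt(sqrt(sum((comm[i, ] - truth[i, ])^2)),
              2.5 * ph$params$voxel_size)
  }
})

test_that("edge chains respect the wall-adjacency contract", {
  ph <- mini_phantom()
  v <- ph$volume
  m <- mini_measurement()
  d <- dim(v$grid)
  wall_idx <- valvemorph:::cpp_which_label(v$grid, d, 1L)
  wall_xyz <- valvemorph:::voxel_coords(v, wall_idx)
  for (leaf in c("anterior", "left", "right")) {
    chart <- m$landmarks$charts[[leaf]]
    # basal nodes sit inside the wall-crossing band (within about half a
    # leaflet thickness of wall voxel centers); interior free nodes stay at
    # least 2 voxels clear of the wall
    interior_b <- chart$basal_attachment[-c(1, nrow(chart$basal_attachment)), ]
    d_b <- apply(interior_b, 1, function(p) {
      sqrt(min(colSums((t(wall_xyz) - p)^2)))
    })
    expect_lt(stats::median(d_b),
              ph$params$leaflet_thickness_true / 2 + 2 * v$voxel_size)
    interior_f <- chart$free_edge[-c(1, nrow(chart$free_edge)), ]
    d_f <- apply(interior_f, 1, function(p) {
      sqrt(min(colSums((t(wall_xyz) - p)^2)))
    })
    expect_gt(min(d_f), 2 * v$voxel_size)
    # both chains start and end at the leaflet's commissures
    cm <- valvemorph:::leaflet_commissures()[[leaf]]
    comm <- m$landmarks$commissures
    expect_lt(sqrt(sum((chart$free_edge[1, ] - comm[cm[1], ])^2)), 1e-9)
    expect_lt(sqrt(sum((chart$basal_attachment[nrow(chart$basal_attachment), ] -
                          comm[cm[2], ])^2)), 1e-9)
  }
})

test_that("plane through three canonical points has the closed-form normal", {
  pl <- plane_through_points(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(abs(sum(pl$normal * rep(1 / sqrt(3), 3))), 1, tolerance = 1e-12)
  expect_equal(plane_distance(pl, c(1 / 3, 1 / 3, 1 / 3)), 0, tolerance = 1e-12)
  expect_error(plane_through_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "degenerate")
})

test_that("recovered planes reproduce the phantom tilt", {
  m <- mini_measurement()
  tr <- mini_phantom()$truth
  expect_lt(abs(tilt_angle(m$landmarks$anl, m$landmarks$stj) -
                  tr$gqoi$beta_deg), 1)
  # untilted phantom: parallel ANL and STJ normals
  p0 <- mini_params(tilt = 0, voxel_size = 8, leaflet_thickness_true = 30)
  ph0 <- generate_valve_phantom(p0)
  m0 <- measure_gqoi(ph0$volume, thickness = FALSE)
  expect_lt(tilt_angle(m0$landmarks$anl, m0$landmarks$stj), 1)
})

test_that("valve height is the mean commissure distance", {
  anl <- valve_plane(c(0, 0, 0), c(0, 0, 1))
  comm <- rbind(c(0, 0, 700), c(10, 0, 700), c(0, 10, 700))
  expect_equal(valve_height(comm, anl), 700)
  comm2 <- rbind(c(0, 0, 600), c(1, 0, 700), c(0, 1, 800))
  expect_equal(valve_height(comm2, anl), 700)
})

test_that("tilt angle is symmetric in normal orientation", {
  a <- valve_plane(c(0, 0, 0), c(0, 0, 1))
  b <- valve_plane(c(0, 0, 0), c(sin(10 * pi / 180), 0, cos(10 * pi / 180)))
  expect_equal(tilt_angle(a, b), 10, tolerance = 1e-9)
  b$normal <- -b$normal
  expect_equal(tilt_angle(a, b), 10, tolerance = 1e-9)
  expect_equal(tilt_angle(a, a), 0)
})
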