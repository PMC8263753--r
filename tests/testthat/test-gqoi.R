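# Geometric quantities of interest: normalization, perimeter, thickness,
# invariances.

test_that("gqoi normalization is exact and validated", {
  r <- assemble_gqoi("s", 10,
                     L_FE = c(anterior = 1347.3, left = 1600, right = 1620),
                     L_BA = c(anterior = 1900, left = 2280, right = 2260),
                     H = 650, w = 19, L_gamma = 4646, beta_deg = 10)
  expect_equal(round(r$L_FE_bar[["anterior"]], 2), 0.29)
  expect_equal(r$L_FE_bar * r$L_gamma, r$L_FE)
  expect_equal(r$L_gamma / r$L_gamma, 1)
  expect_error(assemble_gqoi("s", 10, r$L_FE, r$L_BA, 650, 19, -1, 10),
               "normalization")
})

test_that("perimeter of in-plane circular basal curves is 2*pi*r", {
  anl <- valve_plane(c(0, 0, 0), c(0, 0, 1))
  r <- 740
  arcs <- lapply(0:2, function(k) {
    th <- seq(2 * pi * k / 3, 2 * pi * (k + 1) / 3, length.out = 40)
    fit_curve_and_length(cbind(r * cos(th), r * sin(th), 0))
  })
  names(arcs) <- c("anterior", "right", "left")
  vp <- valve_perimeter(arcs, anl)
  expect_lt(abs(vp$L_gamma - 2 * pi * r) / (2 * pi * r), 0.005)
  # idempotence: re-projecting the projected contour changes nothing
  vp2 <- valve_perimeter(lapply(arcs, function(cv) {
    fit_curve_and_length(valvemorph:::project_onto_plane(anl, cv$nodes))
  }), anl)
  expect_equal(vp$L_gamma, vp2$L_gamma, tolerance = 1e-9)
})

test_that("disordered basal chains fail with a topology error", {
  anl <- valve_plane(c(0, 0, 0), c(0, 0, 1))
  arcs <- lapply(c(0, 3, 1), function(k) {  # second arc far away
    th <- seq(k, k + 1, length.out = 20)
    fit_curve_and_length(cbind(3000 * cos(th), 3000 * sin(th), 0))
  })
  names(arcs) <- c("anterior", "right", "left")
  expect_error(valve_perimeter(arcs, anl), "topology")
})

test_that("thickness recovers a uniform slab within half a voxel", {
  # freestanding tilted slab, measured through the distance-transform ridge
  h <- 1
  t_true <- 6.8
  g <- array(0L, c(48, 48, 48))
  idx <- which(g == 0L, arr.ind = TRUE)
  n <- c(sin(0.35), 0.2, cos(0.35)); n <- n / sqrt(sum(n^2))
  s <- (idx[, 1] - 24) * n[1] + (idx[, 2] - 24) * n[2] + (idx[, 3] - 24) * n[3]
  g[abs(s) <= t_true / 2] <- 2L
  gr <- as.raw(g); dim(gr) <- dim(g)
  ms <- valvemorph:::cpp_midsurface(gr, dim(g), 2L, 0.5)
  est <- 2 * stats::median(ms$dist_vox) * h + 0.35 * h
  expect_lt(abs(est - t_true), 0.5)
})

test_that("phantom thickness is recovered within one voxel", {
  m <- mini_measurement()
  tr <- mini_phantom()$truth
  h <- mini_phantom()$params$voxel_size
  expect_lt(abs(m$gqoi$w - tr$gqoi$w), h)
  # different seeds agree within 10% (belly thickness is near-uniform)
  t2 <- leaflet_thickness(mini_phantom()$volume, m$landmarks, seed = 99L)
  expect_lt(abs(t2$thickness_um - m$gqoi$w) / m$gqoi$w, 0.1)
})

test_that("dimensional gQOIs scale with the valve, normalized ones do not", {
  # same phantom at double scale and double voxel: identical grid, so the
  # voxel pipeline sees a rescaled world
  p1 <- mini_params(voxel_size = 8, leaflet_thickness_true = 30)
  p2 <- p1
  for (f in c("wall_radius_at_ANL", "wall_radius_at_STJ", "valve_height_true",
              "leaflet_thickness_true", "belly_sag_depth",
              "free_edge_mid_height", "wall_thickness", "voxel_size")) {
    p2[[f]] <- p1[[f]] * 2
  }
  m1 <- measure_gqoi(generate_valve_phantom(p1)$volume, tvp = 10, seed = 5L)
  m2 <- measure_gqoi(generate_valve_phantom(p2)$volume, tvp = 10, seed = 5L)
  vox <- p2$voxel_size
  expect_lt(abs(m2$gqoi$L_gamma - 2 * m1$gqoi$L_gamma), vox)
  expect_lt(abs(m2$gqoi$H - 2 * m1$gqoi$H), vox)
  expect_lt(abs(m2$gqoi$L_FE[["left"]] - 2 * m1$gqoi$L_FE[["left"]]), vox)
  expect_lt(abs(m2$gqoi$H_bar - m1$gqoi$H_bar), vox / m1$gqoi$L_gamma)
  expect_lt(abs(m2$gqoi$beta_deg - m1$gqoi$beta_deg), 1)
})

test_that("gQOIs are invariant to a rigid motion of the valve", {
  p1 <- mini_params(voxel_size = 8, leaflet_thickness_true = 30)
  p2 <- mini_params(voxel_size = 8, leaflet_thickness_true = 30,
                    axis_origin = c(311, -207, 95),
                    axis_direction = c(0.3, -0.4, 0.866))
  m1 <- measure_gqoi(generate_valve_phantom(p1)$volume, tvp = 10,
                     thickness = FALSE)
  m2 <- measure_gqoi(generate_valve_phantom(p2)$volume, tvp = 10,
                     thickness = FALSE)
  vox <- 8
  for (f in c("L_gamma", "H")) {
    expect_lt(abs(m1$gqoi[[f]] - m2$gqoi[[f]]), vox)
  }
  # edge lengths sum voxel-level differences along the whole chain, so a
  # rotated resampling can move them by a couple of voxel equivalents
  for (leaf in c("anterior", "left", "right")) {
    expect_lt(abs(m1$gqoi$L_FE[[leaf]] - m2$gqoi$L_FE[[leaf]]), 2 * vox)
    expect_lt(abs(m1$gqoi$L_BA[[leaf]] - m2$gqoi$L_BA[[leaf]]), 2 * vox)
  }
  expect_lt(abs(m1$gqoi$beta_deg - m2$gqoi$beta_deg), 1.5)
})

test_that("records flatten into a tidy per-leaflet table", {
  m <- mini_measurement()
  tb <- gqoi_to_tibble(m$gqoi)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$L_FE_bar * tb$L_gamma_um, tb$L_FE_um)
})
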