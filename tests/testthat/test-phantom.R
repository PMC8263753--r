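# Synthetic valve generator: parameter validation, ground-truth geometry,
# reproducibility, and the statistical structure of fiber and series
# generators.

test_that("phantom parameters enforce their invariants", {
  expect_error(valve_phantom_params(leaflet_thickness_true = -1), "length")
  expect_error(valve_phantom_params(tilt_angle_true = 35), "tilt")
  expect_error(valve_phantom_params(leaflet_scale = c(anterior = 1.4, left = 1,
                                                      right = 1)), "scale")
  expect_error(valve_phantom_params(voxel_size = 10,
                                    leaflet_thickness_true = 19),
               "resolution")
})

test_that("untilted symmetric phantom has parallel planes and beta = 0", {
  p <- mini_params(tilt = 0,
                   leaflet_scale = c(anterior = 1, left = 1, right = 1))
  tr <- phantom_ground_truth(p)
  expect_lt(abs(tr$gqoi$beta_deg), 1e-6)
  expect_lt(acos(min(1, abs(sum(tr$landmarks$anl$normal *
                                  tr$landmarks$stj$normal)))), 1e-6)
})

test_that("ground-truth perimeter approaches the closed form for a cylinder", {
  # equal radii at ANL and rim: the basal dips reach the ANL circle of
  # radius r, so the projected contour is close to (and bounded by) 2*pi*r
  p <- mini_params(tilt = 0)
  p$wall_radius_at_STJ <- p$wall_radius_at_ANL
  tr <- phantom_ground_truth(p)
  r <- p$wall_radius_at_ANL
  expect_lt(abs(tr$gqoi$L_gamma - 2 * pi * r) / (2 * pi * r), 0.02)
})

test_that("murine preset at 10 mmHg matches the reported scale", {
  tr <- phantom_ground_truth(murine_pv_preset(tvp = 10))
  expect_gte(tr$gqoi$L_gamma, 4400)
  expect_lte(tr$gqoi$L_gamma, 4900)
  expect_gte(tr$gqoi$w, 18)
  expect_lte(tr$gqoi$w, 20)
  # anterior asymmetry: anterior leaflet smaller than left/right
  expect_lt(tr$gqoi$L_FE[["anterior"]], tr$gqoi$L_FE[["left"]])
  expect_lt(tr$gqoi$L_BA[["anterior"]], tr$gqoi$L_BA[["right"]])
})

test_that("free edges are shorter than basal attachments on phantoms", {
  for (tvp in c(10, 20, 30)) {
    tr <- phantom_ground_truth(murine_pv_preset(tvp = tvp))
    expect_true(all(tr$gqoi$L_FE < tr$gqoi$L_BA))
  }
  tr <- phantom_ground_truth(mini_params())
  expect_true(all(tr$gqoi$L_FE < tr$gqoi$L_BA))
})

test_that("phantom voxelization is bit-reproducible", {
  p <- mini_params(voxel_size = 8, leaflet_thickness_true = 30)
  a <- generate_valve_phantom(p)
  b <- generate_valve_phantom(p)
  expect_identical(a$volume$grid, b$volume$grid)
})

test_that("fiber generator obeys its distributional contracts", {
  expect_error(generate_fiber_set(c(0, 0, 1), -1, 10), "kappa")
  # degenerate concentration: all axes equal the mean axis
  fs <- generate_fiber_set(c(0, 0, 1), 1e9, 50, seed = 3)
  expect_true(all(abs(fs$direction[, 3] - 1) < 1e-12))
  # kappa = 0: mean resultant length of axial second moment ~ isotropic
  # axial directions folded to a hemisphere are not mean-zero; the uniform
  # axial law is characterized by second-moment eigenvalues of 1/3 each
  fs0 <- generate_fiber_set(c(0, 0, 1), 0, 1e5, seed = 4)
  ev <- eigen(crossprod(fs0$direction) / nrow(fs0$direction))$values
  expect_true(all(abs(ev - 1 / 3) < 3 / sqrt(1e5) * 3))
  # diameters: >= 90% within [80, 100] nm for mean 90, sd 5
  fs9 <- generate_fiber_set(c(0, 0, 1), 50, 1e4, diameter_mean_nm = 90,
                            diameter_sd_nm = 5, seed = 5)
  expect_gte(mean(fs9$diameter_nm >= 80 & fs9$diameter_nm <= 100), 0.9)
  # determinism
  expect_identical(generate_fiber_set(c(1, 0, 0), 20, 100, seed = 11),
                   generate_fiber_set(c(1, 0, 0), 20, 100, seed = 11))
})

test_that("gqoi series generator produces the requested line", {
  s <- generate_gqoi_series(0.38, -0.002, 0, seed = 1)
  expect_equal(s$value[s$tvp_mmHg == 10], rep(0.36, 3))
  expect_equal(s$value[s$tvp_mmHg == 20], rep(0.34, 5))
  expect_equal(s$value[s$tvp_mmHg == 30], rep(0.32, 3))
  # noiseless series is recovered exactly by the regression layer
  fit <- fit_linear_vs_tvp(s)
  expect_equal(fit$slope, -0.002, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.38, tolerance = 1e-12)
})

test_that("simulated series recover the true slope on average", {
  slopes <- vapply(1:200, function(s) {
    ser <- generate_gqoi_series(0.4, -0.002, 0.01,
                                n_per_tvp = c(`10` = 30, `20` = 50, `30` = 30),
                                seed = s)
    fit_linear_vs_tvp(ser)$slope
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) + 0.002), 2 * mc_se + 1e-12)
})
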