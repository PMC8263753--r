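# B-spline basis, surface fitting, evaluation, and cross-section
# normalization.

test_that("basis functions form a partition of unity", {
  set.seed(7)
  for (cfg in list(c(3, 8), c(2, 5), c(1, 4))) {
    U <- open_knots(cfg[2], cfg[1])
    u <- c(0, 1, runif(1000))
    M <- bspline_basis(u, U, cfg[1])
    expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
    expect_true(all(M >= -1e-12))
  }
})

test_that("single-span quadratic basis matches Bernstein values", {
  U <- open_knots(3, 2)  # one Bezier span
  expect_equal(as.numeric(bspline_basis(0.5, U, 2)), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
})

test_that("constant control net yields a constant surface", {
  ctrl <- array(rep(c(3, -2, 7), each = 20), c(4, 5, 3))
  surf <- leaflet_nurbs(ctrl, p = 3, q = 3)
  set.seed(1)
  pts <- evaluate_surface(surf, runif(50), runif(50))
  expect_lt(max(abs(sweep(pts, 2, c(3, -2, 7)))), 1e-10)
})

test_that("evaluation matches the naive Cox-de Boor recursion", {
  set.seed(11)
  ctrl <- array(rnorm(8 * 8 * 3, sd = 500), c(8, 8, 3))
  surf <- leaflet_nurbs(ctrl, p = 3, q = 3)
  xi <- c(0, 1, runif(98)); eta <- c(1, 0, runif(98))
  fast <- evaluate_surface(surf, xi, eta)
  for (k in seq_along(xi)) {
    slow <- naive_surface_point(surf, xi[k], eta[k])
    expect_lt(max(abs(fast[k, ] - slow)) / max(1, max(abs(slow))), 1e-10)
  }
})

test_that("surface tangent matches finite differences", {
  set.seed(12)
  ctrl <- array(rnorm(6 * 6 * 3, sd = 300), c(6, 6, 3))
  surf <- leaflet_nurbs(ctrl, p = 3, q = 3)
  for (k in 1:20) {
    xi <- runif(1, 0.05, 0.95); eta <- runif(1, 0.05, 0.95)
    an <- surface_tangent_xi(surf, xi, eta)
    dd <- 1e-6
    fd <- (evaluate_surface(surf, xi + dd, eta) -
             evaluate_surface(surf, xi - dd, eta)) / (2 * dd)
    expect_lt(max(abs(an - fd)) / max(1, max(abs(fd))), 1e-5)
  }
})

test_that("fitting reproduces representable surfaces exactly", {
  # bilinear patch is inside the cubic spline space
  set.seed(3)
  xi <- runif(500); eta <- runif(500)
  pts <- cbind(1000 * xi, 800 * eta, 100 + 200 * xi * eta)
  surf <- fit_surface(pts, list(xi = xi, eta = eta), lambda = 0)
  expect_lt(attr(surf, "rms_residual"), 1e-6)
  # corner interpolation with a linear 2x2 net recovers the quad corners
  quad <- cbind(c(0, 1, 0, 1) * 500, c(0, 0, 1, 1) * 300, 0)
  s2 <- fit_surface(quad, list(xi = c(0, 1, 0, 1), eta = c(0, 0, 1, 1)),
                    p = 1, q = 1, n = 2, m = 2, lambda = 0)
  expect_equal(matrix(s2$control, 4, 3), quad, tolerance = 1e-9)
})

test_that("fit residual does not increase with control net size", {
  ph <- mini_phantom()
  m <- mini_measurement()
  ms <- extract_mid_surface(ph$volume, "left")
  par <- parametrize_points(ms$points, m$landmarks, "left", strict = FALSE)
  rms <- vapply(c(4, 6, 8), function(nn) {
    attr(fit_surface(ms$points, par, n = nn, m = nn, leaflet_id = "left"),
         "rms_residual")
  }, numeric(1))
  expect_true(all(diff(rms) < 1e-6))
})

test_that("mid-surface extraction finds the slab center", {
  g <- array(0L, c(30, 30, 30))
  g[4:27, 4:27, 10:15] <- 2L  # slab z in [10, 15], 6 voxels thick
  v <- valve_volume(g, voxel_size = 2)
  ms <- extract_mid_surface(v, "anterior")
  # slab interior (away from the lateral rim, where the ridge follows the
  # rim's own medial axis): centers within half a voxel of the mid-plane,
  # i.e. one of the two central layers of this even-layer slab
  interior <- ms$points[, 1] > 16 & ms$points[, 1] < 44 &
    ms$points[, 2] > 16 & ms$points[, 2] < 44
  zc <- ms$points[interior, 3]
  expect_lt(max(abs(zc - 24)), 1.1)
  expect_gte(nrow(ms$points), 100)
})

test_that("parametrization maps landmarks to chart corners", {
  m <- mini_measurement()
  for (leaf in c("anterior", "left")) {
    par5 <- parametrize_points(rbind(m$landmarks$P5[leaf, ]), m$landmarks,
                               leaf, strict = FALSE)
    par4 <- parametrize_points(rbind(m$landmarks$P4[leaf, ]), m$landmarks,
                               leaf, strict = FALSE)
    expect_lt(abs(par5$eta), 0.12)
    expect_gt(par4$eta, 0.88)
    expect_lt(abs(par4$xi - 0.5), 0.15)
    cm <- valvemorph:::leaflet_commissures()[[leaf]]
    parc <- parametrize_points(m$landmarks$commissures[cm, ], m$landmarks,
                               leaf, strict = FALSE)
    expect_equal(parc$xi, c(0, 1), tolerance = 0.02)
  }
})

test_that("phantom chart azimuth is recovered accurately", {
  ph <- mini_phantom()
  m <- mini_measurement()
  geom <- valvemorph:::phantom_geometry(ph$params)
  xi_true <- seq(0.05, 0.95, length.out = 19)
  pts <- geom$leaves$left$S_world(xi_true, rep(0.5, 19))
  par <- parametrize_points(pts, m$landmarks, "left", strict = FALSE)
  # tolerance: chart accuracy is limited by the ~1-voxel commissure
  # placement at this coarse test resolution (6 um voxels, 230 um radius)
  expect_lt(max(abs(par$xi - xi_true)), 0.035)
})

test_that("fitted phantom surfaces are accurate to about a voxel", {
  ph <- mini_phantom()
  surf <- mini_surface("left")
  expect_lt(attr(surf, "rms_residual"), 1.1 * ph$params$voxel_size)
  geom <- valvemorph:::phantom_geometry(ph$params)
  gg <- expand.grid(xi = seq(0, 1, by = 0.02), eta = seq(0, 1, by = 0.02))
  S <- geom$leaves$left$S_world(gg$xi, gg$eta)
  sub <- seq(1, nrow(gg), by = 9)
  pred <- evaluate_surface(surf, gg$xi[sub], gg$eta[sub])
  dp <- apply(pred, 1, function(pt) sqrt(min(colSums((t(S) - pt)^2))))
  expect_lt(stats::median(dp), ph$params$voxel_size)
})

test_that("cross-sections honor their defining constraints", {
  m <- mini_measurement()
  ph <- mini_phantom()
  surf <- mini_surface("left")
  cs <- central_cross_sections(surf, m$landmarks)
  # r2's free end sits near P4
  endpt <- cs$r2$eval(cs$r2$param[length(cs$r2$param)])
  expect_lt(sqrt(sum((endpt - m$landmarks$P4["left", ])^2)),
            3 * ph$params$voxel_size)
  # c2 and r2 intersect
  c2s <- cs$c2$eval(seq(0, cs$c2$param[length(cs$c2$param)], length.out = 300))
  r2s <- cs$r2$eval(seq(0, cs$r2$param[length(cs$r2$param)], length.out = 300))
  dmin <- min(apply(r2s, 1, function(p) min(colSums((t(c2s) - p)^2))))
  expect_lt(sqrt(dmin), ph$params$voxel_size)
})

test_that("normalized sections span their canonical ranges", {
  anl <- valve_plane(c(0, 0, 0), c(0, 0, 1))
  # semicircular arc in a vertical plane, base on the ANL plane
  th <- seq(0, pi, length.out = 101)
  arc <- fit_curve_and_length(cbind(500 * cos(th), 0, 500 * sin(th)))
  cs <- normalize_cross_section(arc, anl, c(0, 0, 1), "circumferential")
  expect_equal(range(cs$samples$abscissa), c(-1, 1), tolerance = 1e-9)
  expect_equal(max(cs$samples$h_bar), 1, tolerance = 0.01)
  expect_lt(abs(cs$samples$abscissa[which.max(cs$samples$h_bar)]), 0.05)
  # curve inside the ANL plane has h = 0 everywhere
  flat <- fit_curve_and_length(cbind(seq(0, 900, length.out = 40),
                                     100 * sin(seq(0, 3, length.out = 40)), 0))
  cf <- normalize_cross_section(flat, anl, c(0, 0, 1), "radial")
  expect_equal(range(cf$samples$abscissa), c(0, 1), tolerance = 1e-9)
  expect_lt(max(abs(cf$samples$h_bar)), 1e-9)
  # near-vertical-line input fails
  vert <- fit_curve_and_length(cbind(1e-9 * (1:20), 0,
                                     seq(0, 500, length.out = 20)))
  expect_error(normalize_cross_section(vert, anl, c(0, 0, 1), "radial"),
               "degenerate")
})

test_that("averaging cross-sections is exact for duplicates and mirrors", {
  anl <- valve_plane(c(0, 0, 0), c(0, 0, 1))
  th <- seq(0, pi, length.out = 101)
  arc <- fit_curve_and_length(cbind(500 * cos(th), 0, 500 * sin(th)))
  cs <- normalize_cross_section(arc, anl, c(0, 0, 1), "circumferential",
                                tvp = 10)
  avg <- average_cross_sections(list(cs, cs))
  expect_true(all(avg$samples$h_bar_sd == 0))
  expect_equal(avg$samples$h_bar_mean,
               approx(cs$samples$abscissa, cs$samples$h_bar,
                      avg$samples$abscissa, rule = 2)$y,
               tolerance = 1e-9)
  mirror <- cs
  mirror$samples$h_bar <- -mirror$samples$h_bar
  avg2 <- average_cross_sections(list(cs, mirror))
  expect_lt(max(abs(avg2$samples$h_bar_mean)), 1e-12)
  other <- cs; other$tvp <- 20
  expect_error(average_cross_sections(list(cs, other)), "grouping")
})

test_that("NURBS surfaces survive a JSON round trip", {
  surf <- mini_surface("left")
  path <- tempfile(fileext = ".json")
  write_leaflet_nurbs(surf, path)
  back <- read_leaflet_nurbs(path)
  expect_equal(back$control, surf$control, tolerance = 1e-12)
  expect_equal(back$U, surf$U)
  set.seed(2)
  xi <- runif(20); eta <- runif(20)
  expect_equal(evaluate_surface(back, xi, eta),
               evaluate_surface(surf, xi, eta), tolerance = 1e-12)
})
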