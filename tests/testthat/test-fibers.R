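# Fiber frames, spherical angles, orientation and diameter statistics.

test_that("rigid transforms apply and invert correctly", {
  fs <- generate_fiber_set(c(0, 0, 1), 30, 200, seed = 8)
  idT <- rigid_transform(diag(3), c(0, 0, 0), "sem", "sem")
  expect_equal(apply_transform(fs, idT)$direction, fs$direction)
  # 90 degree rotation about x maps (0,0,1) to (0,-1,0), folded to (0,1,0)
  Rx <- valvemorph:::rotation_about_axis(c(1, 0, 0), pi / 2)
  one <- fiber_set(matrix(0, 1, 3), matrix(c(0, 0, 1), 1), 90, 5, "sem")
  out <- apply_transform(one, rigid_transform(Rx, c(0, 0, 0), "sem", "uct"))
  expect_equal(drop(out$direction), c(0, 1, 0), tolerance = 1e-12)
  expect_identical(out$frame, "uct")
  # round trip: T then T^-1 restores the original set
  T1 <- rigid_transform(valvemorph:::rotation_about_axis(c(1, 2, 3), 0.83),
                        c(120, -40, 60), "sem", "uct")
  back <- apply_transform(apply_transform(fs, T1), invert_transform(T1))
  expect_lt(max(abs(back$centroid - fs$centroid)), 1e-9)
  expect_lt(max(abs(back$direction - fs$direction)), 1e-9)
  expect_error(apply_transform(out, T1), "frame")
})

test_that("spherical angles follow the axial convention", {
  expect_equal(as.numeric(spherical_angles(c(0, 0, 1))), c(0, 0))
  expect_equal(as.numeric(spherical_angles(c(1, 0, 0))), c(90, 0))
  expect_equal(as.numeric(spherical_angles(c(0, 0, -1)))[1], 0)
  expect_error(spherical_angles(c(0, 0, 0)), "domain")
  ang <- spherical_angles(spherical_to_cartesian(65, 149))
  expect_equal(as.numeric(ang), c(65, 149), tolerance = 1e-6)
})

test_that("orientation summary recovers known axes", {
  # perfect alignment
  ref <- c(1, 0, 0)
  aligned <- fiber_set(matrix(0, 50, 3),
                       matrix(rep(ref, each = 50), 50), rep(90, 50),
                       rep(5, 50), "uct")
  os <- orientation_summary(aligned, ref)
  expect_equal(os$alignment_angle_deg, 0)
  expect_equal(sum(os$theta_hist$count == 50), 1)
  expect_equal(sum(os$theta_hist$count), 50)
  # concentrated set about a known axis
  mu <- valvemorph:::unitize(c(0.4, -0.7, 0.59))
  fs <- generate_fiber_set(mu, 50, 5000, seed = 21)
  os2 <- orientation_summary(fs, mu)
  expect_lt(os2$alignment_angle_deg, 2)
  expect_equal(sum(os2$theta_hist$count), 5000)
  expect_equal(sum(os2$phi_hist$count), 5000)
  # isotropic axial set: second-moment eigenvalues each 1/3
  fs0 <- generate_fiber_set(c(0, 0, 1), 0, 1e4, seed = 22)
  os0 <- orientation_summary(fs0, c(0, 0, 1))
  expect_true(all(abs(os0$second_moment_eigenvalues - 1 / 3) < 0.03))
})

test_that("summaries are invariant to the axial fold and equivariant to rotation", {
  fs <- generate_fiber_set(c(0.2, 0.5, 0.84), 25, 500, seed = 31)
  ref <- valvemorph:::unitize(c(1, 1, 0))
  base <- orientation_summary(fs, ref)
  # flip a random subset of representatives: outputs identical
  set.seed(5)
  flip <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  dirs <- fs$direction
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  flipped <- fiber_set(fs$centroid, dirs, fs$diameter_nm, fs$length_um,
                       fs$frame)
  os_f <- orientation_summary(flipped, ref)
  expect_identical(os_f$theta_hist, base$theta_hist)
  expect_identical(os_f$phi_hist, base$phi_hist)
  expect_equal(os_f$alignment_angle_deg, base$alignment_angle_deg)
  # rotation equivariance of the alignment angle
  Q <- valvemorph:::rotation_about_axis(c(2, -1, 4), 1.23)
  rot <- apply_transform(fs, rigid_transform(Q, c(0, 0, 0), fs$frame, "rot"))
  os_r <- orientation_summary(rot, drop(Q %*% ref))
  expect_lt(abs(os_r$alignment_angle_deg - base$alignment_angle_deg), 1e-9)
})

test_that("diameter summary counts and bins conserve mass", {
  fs <- fiber_set(matrix(0, 4, 3), matrix(rep(c(0, 0, 1), each = 4), 4),
                  c(90, 90, 90, 90), rep(5, 4), "uct")
  ds <- diameter_summary(fs)
  expect_equal(ds$fraction_in_range, 1)
  expect_equal(sum(ds$hist$count), 4)
  fs2 <- generate_fiber_set(c(0, 0, 1), 10, 1e4, diameter_mean_nm = 90,
                            diameter_sd_nm = 5, seed = 41)
  ds2 <- diameter_summary(fs2)
  expect_gte(ds2$fraction_in_range, 0.9)
  expect_equal(sum(ds2$hist$count), 1e4)
  expect_error(diameter_summary(fs2, bin_width_nm = 0), "parameter")
})

test_that("fiber sets and transforms survive file round trips", {
  fs <- generate_fiber_set(c(0, 1, 0), 15, 64, seed = 51)
  fp <- tempfile(fileext = ".csv")
  write_fiber_csv(fs, fp)
  back <- read_fiber_csv(fp)
  expect_equal(back$direction, fs$direction, tolerance = 1e-12)
  expect_equal(back$diameter_nm, fs$diameter_nm, tolerance = 1e-12)
  T1 <- rigid_transform(valvemorph:::rotation_about_axis(c(0, 1, 1), 0.4),
                        c(10, 20, 30), "sem", "uct")
  tp <- tempfile(fileext = ".json")
  write_transform_json(T1, tp)
  T2 <- read_transform_json(tp)
  expect_equal(T2$rotation, T1$rotation, tolerance = 1e-12)
  expect_equal(T2$translation, T1$translation, tolerance = 1e-12)
  expect_identical(c(T2$from_frame, T2$to_frame), c("sem", "uct"))
})

test_that("circumferential reference is tangent to the fitted surface", {
  surf <- mini_surface("left")
  ref <- circumferential_reference(surf, 0.5, 0.9)
  expect_equal(sqrt(sum(ref^2)), 1, tolerance = 1e-9)
  fd <- (evaluate_surface(surf, 0.5 + 1e-6, 0.9) -
           evaluate_surface(surf, 0.5 - 1e-6, 0.9)) / 2e-6
  expect_lt(acos(min(1, abs(sum(ref * fd / sqrt(sum(fd^2)))))), 1e-4)
})
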