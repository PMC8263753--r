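# Per-pressure statistics: mean/s.e.m, regression, table assembly, derived
# quantities against the published reference values.

test_that("group mean and s.e.m follow the n-1 convention", {
  expect_equal(group_mean_sem(c(5, 5, 5)), list(mean = 5, sem = 0, n = 3L))
  g <- group_mean_sem(c(1, 2, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_error(group_mean_sem(5), "insufficient")
})

test_that("linear fit matches the closed-form OLS solution", {
  pts <- data.frame(tvp_mmHg = c(10, 10, 20, 20, 30, 30),
                    value = c(0.35, 0.37, 0.33, 0.35, 0.30, 0.33))
  fit <- fit_linear_vs_tvp(pts)
  x <- pts$tvp_mmHg; y <- pts$value; n <- length(y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  s2 <- sum((y - a - b * x)^2) / (n - 2)
  se_b <- sqrt(s2 / sum((x - mean(x))^2))
  se_a <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
  p <- 2 * pt(abs(b / se_b), n - 2, lower.tail = FALSE)
  expect_equal(fit$slope, b, tolerance = 1e-10)
  expect_equal(fit$intercept, a, tolerance = 1e-10)
  expect_equal(fit$slope_sem, se_b, tolerance = 1e-10)
  expect_equal(fit$intercept_sem, se_a, tolerance = 1e-10)
  expect_equal(fit$p_value, p, tolerance = 1e-10)
  expect_error(fit_linear_vs_tvp(data.frame(tvp_mmHg = c(10, 10, 10),
                                            value = 1:3)), "degeneracy")
})

test_that("noiseless lines are recovered exactly", {
  pts <- data.frame(tvp_mmHg = rep(c(10, 20, 30), c(3, 5, 3)))
  pts$value <- 0.38 - 0.002 * pts$tvp_mmHg
  fit <- fit_linear_vs_tvp(pts)
  expect_equal(fit$slope, -0.002, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.38, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-10)
})

test_that("constant model is the grand mean with no slope test", {
  fit <- fit_constant(data.frame(value = c(10, 10, 11, 11, 11)))
  expect_equal(fit$intercept, 10.6)
  expect_equal(fit$slope, 0)
  expect_true(is.na(fit$p_value))
  # equivalence with the linear intercept at the mean pressure on flat data
  pts <- data.frame(tvp_mmHg = rep(c(10, 20, 30), each = 2), value = 7)
  lin <- fit_linear_vs_tvp(pts)
  expect_equal(fit_constant(pts)$intercept,
               lin$intercept + lin$slope * 20, tolerance = 1e-12)
})

test_that("slope t-test holds its nominal type-I error", {
  n_rep <- 500
  rej <- vapply(seq_len(n_rep), function(s) {
    ser <- generate_gqoi_series(0.4, 0, 0.02,
                                n_per_tvp = c(`10` = 30, `20` = 50, `30` = 30),
                                seed = 10000 + s)
    fit_linear_vs_tvp(ser)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("table assembly pools left/right and recovers noiseless truth", {
  mk_rec <- function(id, tvp) {
    assemble_gqoi(id, tvp,
                  L_FE = c(anterior = 0.30, left = 0.36, right = 0.36) *
                    (4500 + 30 * tvp),
                  L_BA = c(anterior = 0.41, left = 0.48, right = 0.48) *
                    (4500 + 30 * tvp),
                  H = 0.15 * (4500 + 30 * tvp), w = 19,
                  L_gamma = 4500 + 30 * tvp, beta_deg = 10)
  }
  recs <- list()
  for (tvp in c(10, 20, 30)) for (r in 1:3) {
    recs[[length(recs) + 1]] <- mk_rec(sprintf("v%d-%d", tvp, r), tvp)
  }
  tab <- build_table1(recs)
  rg <- tab$regression
  lr <- rg[rg$gqoi == "L_FE_bar" & rg$group == "left_right", ]
  expect_equal(lr$slope, 0, tolerance = 1e-12)
  expect_equal(lr$intercept, 0.36, tolerance = 1e-12)
  # pooled rows take two entries per valve
  expect_equal(lr$n_points, 18L)
  st <- tab$stats
  expect_equal(st$n[st$gqoi == "L_FE_bar" & st$group == "left_right" &
                      st$tvp_mmHg == 20], 6L)
  # perimeter slope recovered on its natural scale
  lg <- rg[rg$gqoi == "L_gamma_um", ]
  expect_equal(lg$slope, 30, tolerance = 1e-9)
  expect_equal(lg$slope_display, 30, tolerance = 1e-9)  # not x100
  # permutation invariance
  tab2 <- build_table1(rev(recs))
  expect_equal(tab2$stats, tab$stats)
  expect_equal(tab2$regression, tab$regression)
})

test_that("pointwise OLS equals n-weighted regression on group means", {
  set.seed(9)
  pts <- data.frame(tvp_mmHg = rep(c(10, 20, 30), c(3, 5, 3)),
                    value = rnorm(11, 0.35, 0.02))
  fit_pts <- fit_linear_vs_tvp(pts)
  means <- aggregate(value ~ tvp_mmHg, pts, mean)
  ns <- aggregate(value ~ tvp_mmHg, pts, length)$value
  fit_means <- fit_linear_vs_tvp(means, weights = ns)
  expect_equal(fit_pts$slope, fit_means$slope, tolerance = 1e-10)
  expect_equal(fit_pts$intercept, fit_means$intercept, tolerance = 1e-10)
})

test_that("published reference table reproduces the in-print derived values", {
  tab <- published_gqoi_table()
  expect_equal(round(anterior_ratio(tab, "free_edge", 10), 2), 0.81)
  expect_equal(round(anterior_ratio(tab, "free_edge", 30), 2), 0.94)
  expect_equal(round(anterior_ratio(tab, "basal", 10), 2), 0.84)
  expect_equal(round(anterior_ratio(tab, "basal", 30), 2), 0.89)
  expect_equal(perimeter_change(tab, 10, 20), 12.05, tolerance = 0.01)
  expect_lt(abs(perimeter_change(tab, 20, 30)), 1)  # leveled off
  expect_equal(perimeter_change(tab, 10, 10), 0)
})
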