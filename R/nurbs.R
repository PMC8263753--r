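# Tensor-product B-spline (NURBS with unit weights) leaflet mid-surfaces:
# S(xi, eta) = sum_i sum_j R_ij(xi, eta) P_ij, with clamped open knot vectors
# and control points fitted to the segmented mid-surface by penalized linear
# least squares.

#' Clamped (open) uniform knot vector
#'
#' @param n number of basis functions (control points along the direction).
#' @param p degree.
#' @return Nondecreasing knot vector of length `n + p + 1` on `[0, 1]` whose
#'   first and last `p + 1` entries are 0 and 1.
#' @export
open_knots <- function(n, p) {
  stopifnot(n >= p + 1)
  c(rep(0, p + 1), seq_len(n - p - 1) / (n - p), rep(1, p + 1))
}

# knot span (1-based): U[s] <= u < U[s+1], clamped to valid range
knot_span <- function(u, U, p) {
  n <- length(U) - p - 1
  pmin(pmax(findInterval(u, U), p + 1), n)
}

#' Evaluate all B-spline basis functions at parameter values
#'
#' Cox-de Boor recursion (triangular scheme), vectorized over evaluation
#' points. The returned rows sum to one (partition of unity) for any
#' parameter in `[0, 1]`.
#'
#' @param u parameter values in `[0, 1]`.
#' @param U clamped knot vector.
#' @param p degree.
#' @return Dense matrix, `length(u)` x `n` basis functions.
#' @export
bspline_basis <- function(u, U, p) {
  n <- length(U) - p - 1
  K <- length(u)
  s <- knot_span(u, U, p)
  N <- matrix(0, K, p + 1)
  N[, 1] <- 1
  if (p > 0) {
    left <- right <- matrix(0, K, p)
    for (j in seq_len(p)) {
      left[, j] <- u - U[s + 1 - j]
      right[, j] <- U[s + j] - u
      saved <- numeric(K)
      for (r in seq_len(j)) {
        den <- right[, r] + left[, j - r + 1]
        temp <- ifelse(den > 0, N[, r] / den, 0)
        N[, r] <- saved + right[, r] * temp
        saved <- left[, j - r + 1] * temp
      }
      N[, j + 1] <- saved
    }
  }
  M <- matrix(0, K, n)
  for (r in 0:p) {
    M[cbind(seq_len(K), s - p + r)] <- N[, r + 1]
  }
  M
}

# first-derivative basis matrix d/du N_{i,p}(u)
bspline_basis_deriv <- function(u, U, p) {
  n <- length(U) - p - 1
  if (p == 0) return(matrix(0, length(u), n))
  Mlow <- bspline_basis(u, U, p - 1)  # n + 1 functions of degree p - 1
  D <- matrix(0, length(u), n)
  for (i in seq_len(n)) {
    d1 <- U[i + p] - U[i]
    d2 <- U[i + p + 1] - U[i + 1]
    t1 <- if (d1 > 0) Mlow[, i] / d1 else 0
    t2 <- if (d2 > 0) Mlow[, i + 1] / d2 else 0
    D[, i] <- p * (t1 - t2)
  }
  D
}

#' Construct a leaflet NURBS surface object
#'
#' Weights are fixed at 1 (B-spline specialization): the fit optimizes
#' control point positions only, which keeps it linear.
#'
#' @param control n x m x 3 array of control points (um).
#' @param p,q degrees in the circumferential (xi) and radial (eta) direction.
#' @param U,V clamped knot vectors (defaults: open uniform).
#' @param leaflet_id leaflet name.
#' @return An object of class `leaflet_nurbs`.
#' @export
leaflet_nurbs <- function(control, p = 3, q = 3,
                          U = open_knots(dim(control)[1], p),
                          V = open_knots(dim(control)[2], q),
                          leaflet_id = NA_character_) {
  stopifnot(length(dim(control)) == 3, dim(control)[3] == 3,
            length(U) == dim(control)[1] + p + 1,
            length(V) == dim(control)[2] + q + 1,
            !is.unsorted(U), !is.unsorted(V))
  structure(list(p = p, q = q, U = U, V = V, control = control,
                 weights = matrix(1, dim(control)[1], dim(control)[2]),
                 leaflet_id = leaflet_id),
            class = "leaflet_nurbs")
}

#' @export
print.leaflet_nurbs <- function(x, ...) {
  d <- dim(x$control)
  cat(sprintf("<leaflet_nurbs> %s: degrees (%d, %d), control net %d x %d\n",
              x$leaflet_id, x$p, x$q, d[1], d[2]))
  if (!is.null(attr(x, "rms_residual"))) {
    cat(sprintf("  fit RMS residual: %.3g um over %d points\n",
                attr(x, "rms_residual"), attr(x, "n_points")))
  }
  invisible(x)
}

#' Evaluate a leaflet NURBS surface
#'
#' @param surface a [leaflet_nurbs()].
#' @param xi,eta parameter vectors in `[0, 1]` (recycled to equal length).
#' @return `length(xi)` x 3 matrix of points (um).
#' @export
evaluate_surface <- function(surface, xi, eta) {
  kn <- max(length(xi), length(eta))
  xi <- rep_len(xi, kn); eta <- rep_len(eta, kn)
  if (any(xi < -1e-12 | xi > 1 + 1e-12 | eta < -1e-12 | eta > 1 + 1e-12)) {
    stop("domain error: surface parameters must lie in [0, 1]^2")
  }
  xi <- pmin(1, pmax(0, xi)); eta <- pmin(1, pmax(0, eta))
  Mu <- bspline_basis(xi, surface$U, surface$p)
  Mv <- bspline_basis(eta, surface$V, surface$q)
  vapply(1:3, function(ax) {
    rowSums((Mu %*% surface$control[, , ax]) * Mv)
  }, numeric(kn))
}

#' Surface tangent along the circumferential parameter
#'
#' The partial derivative `dS/dxi`, used as the local circumferential
#' direction when relating fiber orientations to the leaflet.
#'
#' @inheritParams evaluate_surface
#' @param normalize return unit vectors.
#' @return `length(xi)` x 3 matrix.
#' @export
surface_tangent_xi <- function(surface, xi, eta, normalize = FALSE) {
  kn <- max(length(xi), length(eta))
  xi <- rep_len(xi, kn); eta <- rep_len(eta, kn)
  Du <- bspline_basis_deriv(xi, surface$U, surface$p)
  Mv <- bspline_basis(eta, surface$V, surface$q)
  out <- vapply(1:3, function(ax) {
    rowSums((Du %*% surface$control[, , ax]) * Mv)
  }, numeric(kn))
  out <- rbind3(out)
  if (normalize) {
    len <- sqrt(rowSums(out^2))
    if (any(len < 1e-9)) {
      stop("tangent error: degenerate circumferential tangent (|dS/dxi| ~ 0)")
    }
    out <- out / len
  }
  out
}

# second-difference penalty matrix on the control net, both directions,
# for control indices paired column-major as (j - 1) * n + i
control_penalty <- function(n, m) {
  d2 <- function(k) {
    if (k < 3) return(matrix(0, 0, k))
    D <- matrix(0, k - 2, k)
    for (i in seq_len(k - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
    D
  }
  Dn <- d2(n); Dm <- d2(m)
  kronecker(diag(m), crossprod(Dn)) + kronecker(crossprod(Dm), diag(n))
}

#' Fit a NURBS surface to parametrized mid-surface points
#'
#' Solves the linear least-squares problem for the control points, one
#' coordinate at a time, with a ridge penalty on second differences of the
#' control net (scattered segmentations rarely constrain the corners of the
#' net, so the unpenalized problem can be rank-deficient).
#'
#' @param points K x 3 matrix of mid-surface points (um).
#' @param params list or data frame with `xi`, `eta` in `[0, 1]` per point.
#' @param p,q degrees (default cubic).
#' @param n,m control net size (default 8 x 8); needs `K >= n * m`.
#' @param lambda relative ridge strength: the penalty is scaled so `lambda`
#'   is its share of the normal-matrix trace (default `1e-3`). `lambda = 0`
#'   requests an unpenalized fit and fails if it is rank-deficient.
#' @param weights optional nonnegative case weights per point.
#' @param leaflet_id stored on the result.
#' @return A [leaflet_nurbs()] with attributes `rms_residual` (um) and
#'   `n_points`.
#' @export
fit_surface <- function(points, params, p = 3, q = 3, n = 8, m = 8,
                        lambda = 1e-3, weights = NULL,
                        leaflet_id = NA_character_) {
  points <- rbind3(points)
  K <- nrow(points)
  if (K < n * m) {
    stop("insufficient data: need at least n*m = ", n * m,
         " points to fit the control net")
  }
  U <- open_knots(n, p); V <- open_knots(m, q)
  Mu <- bspline_basis(pmin(1, pmax(0, params$xi)), U, p)
  Mv <- bspline_basis(pmin(1, pmax(0, params$eta)), V, q)
  A <- Mu[, rep(seq_len(n), m), drop = FALSE] *
    Mv[, rep(seq_len(m), each = n), drop = FALSE]
  if (!is.null(weights)) {
    sw <- sqrt(weights)
    AtA <- crossprod(A * sw)
    rhs <- crossprod(A * sw, points * sw)
  } else {
    AtA <- crossprod(A)
    rhs <- crossprod(A, points)
  }
  if (lambda > 0) {
    P <- control_penalty(n, m)
    trP <- sum(diag(P))
    scale <- if (trP > 0) lambda * sum(diag(AtA)) / trP else 0
    AtA <- AtA + scale * P
  } else {
    if (rcond(AtA) < 1e-12) {
      stop("ill-posed fit: collocation matrix is rank-deficient; ",
           "use lambda > 0 or a smaller control net")
    }
  }
  C <- solve(AtA, rhs)
  control <- array(C, dim = c(n, m, 3))
  surf <- leaflet_nurbs(control, p = p, q = q, U = U, V = V,
                        leaflet_id = leaflet_id)
  resid <- points - A %*% C
  attr(surf, "rms_residual") <- sqrt(mean(rowSums(resid^2)))
  attr(surf, "n_points") <- K
  surf
}

#' Extract the mid-surface point cloud of a leaflet
#'
#' The mid-surface is the ridge of the Euclidean distance transform of the
#' leaflet label: voxels whose distance value is a local maximum along at
#' least one axis pair of the 26-neighborhood, restricted to distances of at
#' least `ridge_frac` of the leaflet's maximum (which trims the rounded rim).
#'
#' @param volume a [valve_volume()].
#' @param leaflet leaflet name.
#' @param ridge_frac ridge acceptance threshold as a fraction of the maximum
#'   distance value.
#' @param normals if `TRUE`, attach unit surface normals estimated by local
#'   principal component analysis of the point cloud.
#' @return List with `points` (n x 3 um), `dist_um` (local half-thickness),
#'   and optionally `normals`.
#' @export
extract_mid_surface <- function(volume, leaflet, ridge_frac = 0.5,
                                normals = FALSE) {
  d <- dim(volume$grid)
  code <- label_code(volume, leaflet)
  cr <- cpp_crop_label(volume$grid, d, code, 2L)
  ms <- cpp_midsurface(cr$grid, cr$dim, code, ridge_frac)
  if (ms$max_dist_vox * 2 < 3) {
    stop("resolution error: leaflet '", leaflet, "' thinner than 3 voxels")
  }
  if (length(ms$idx) < 100) {
    stop("resolution error: too few mid-surface points on leaflet '",
         leaflet, "'")
  }
  sub <- volume
  sub$grid <- cr$grid; dim(sub$grid) <- cr$dim
  sub$origin <- volume$origin + cr$offset * volume$voxel_size
  pts <- voxel_coords(sub, ms$idx)
  out <- list(points = pts, dist_um = ms$dist_vox * volume$voxel_size)
  if (normals) out$normals <- estimate_normals(pts, 4 * volume$voxel_size)
  out
}

# unit normals by local PCA within a radius (grid-hashed neighborhoods)
estimate_normals <- function(pts, radius) {
  key <- floor(sweep(pts, 2, apply(pts, 2, min), `-`) / radius)
  hash <- paste(key[, 1], key[, 2], key[, 3])
  buckets <- split(seq_len(nrow(pts)), hash)
  keymap <- do.call(rbind, strsplit(names(buckets), " "))
  storage.mode(keymap) <- "integer"
  lookup <- new.env(hash = TRUE)
  for (b in seq_along(buckets)) assign(names(buckets)[b], b, envir = lookup)
  nrm <- matrix(0, nrow(pts), 3)
  for (b in seq_along(buckets)) {
    kb <- keymap[b, ]
    nb <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      nm <- paste(kb[1] + dx, kb[2] + dy, kb[3] + dz)
      hit <- get0(nm, envir = lookup)
      if (!is.null(hit)) nb <- c(nb, buckets[[hit]])
    }
    loc <- pts[nb, , drop = FALSE]
    ctr <- colMeans(loc)
    ev <- eigen(crossprod(sweep(loc, 2, ctr)) / nrow(loc), symmetric = TRUE)
    for (i in buckets[[b]]) nrm[i, ] <- ev$vectors[, 3]
  }
  nrm
}

#' Parametrize mid-surface points over the leaflet chart
#'
#' `xi` is the normalized azimuth about the valve axis between the leaflet's
#' two commissures (0 at the first, 1 at the second); `eta` is the
#' fractional position along the local radial transect from the basal
#' attachment (0) to the free edge (1), computed from the distances to the
#' interpolated edge chains.
#'
#' @param points n x 3 matrix (um).
#' @param landmarks a [valve_landmarks()] carrying edge `charts`.
#' @param leaflet leaflet name.
#' @param strict error (rather than clamp) when points fall outside the
#'   leaflet's azimuthal sector by more than 5% of its width.
#' @return List with numeric vectors `xi` and `eta` in `[0, 1]`.
#' @export
parametrize_points <- function(points, landmarks, leaflet, strict = TRUE) {
  chart <- landmarks$charts[[leaflet]]
  if (is.null(chart)) {
    stop("landmarks carry no edge charts for leaflet '", leaflet,
         "'; run extract_leaflet_edges/measure_gqoi first")
  }
  points <- rbind3(points)
  center <- colMeans(landmarks$P5)
  direction <- landmarks$anl$normal
  cm <- leaflet_commissures()[[leaflet]]
  psi_a <- drop(azimuth_about(landmarks$commissures[cm[1], ], center, direction))
  psi_b <- drop(azimuth_about(landmarks$commissures[cm[2], ], center, direction))
  interior <- drop(azimuth_about(
    chart$basal_attachment[ceiling(nrow(chart$basal_attachment) / 2), ],
    center, direction))
  xi <- sector_fraction(azimuth_about(points, center, direction),
                        psi_a, psi_b, interior)
  if (strict && any(xi < -0.05 | xi > 1.05)) {
    stop("parametrization error: points outside the leaflet's azimuthal sector")
  }
  xi <- pmin(1, pmax(0, xi))
  interp_chain <- function(nodes, node_xi, at) {
    vapply(1:3, function(ax) {
      approx(node_xi, nodes[, ax], xout = at, rule = 2, ties = "ordered")$y
    }, numeric(length(at)))
  }
  B <- rbind3(interp_chain(chart$basal_attachment, chart$basal_xi, xi))
  F <- rbind3(interp_chain(chart$free_edge, chart$free_xi, xi))
  dB <- sqrt(rowSums((points - B)^2))
  dF <- sqrt(rowSums((points - F)^2))
  eta <- ifelse(dB + dF > 0, dB / (dB + dF), 0)
  list(xi = xi, eta = pmin(1, pmax(0, eta)), d_basal = dB, d_free = dF)
}

#' Fit a leaflet NURBS surface from a labeled volume
#'
#' Convenience driver: extracts the mid-surface ridge, parametrizes it over
#' the leaflet chart, discards ridge points closer than 0.8 leaflet
#' thicknesses to the basal chain (where the leaflet merges into the wall)
#' and rim-fringe ridge voxels with low distance values, anchors the fit
#' with the measured basal (`eta = 0`) and free-edge (`eta = 1`) node chains
#' as lightly weighted boundary data, and performs one robust trim-and-refit
#' pass to reject stray ridge voxels. The reported RMS residual is over the
#' mid-surface points (the chains carry their own placement uncertainty).
#'
#' @param volume a [valve_volume()].
#' @param landmarks a [valve_landmarks()] with edge charts.
#' @param leaflet leaflet name.
#' @param trim trim threshold in multiples of the median residual (one
#'   refit pass); `Inf` disables trimming.
#' @inheritParams fit_surface
#' @return A [leaflet_nurbs()] with `rms_residual`/`n_points` attributes.
#' @export
fit_leaflet_surface <- function(volume, landmarks, leaflet, p = 3, q = 3,
                                n = 8, m = 8, lambda = 1e-3, trim = 2) {
  ms <- extract_mid_surface(volume, leaflet)
  par <- parametrize_points(ms$points, landmarks, leaflet, strict = FALSE)
  h <- volume$voxel_size
  w_est <- 2 * stats::median(ms$dist_um) + 0.35 * h
  # drop the wall-merge zone and the low-confidence rim fringe (ridge voxels
  # whose distance value is well below the leaflet's half thickness)
  keep <- par$d_basal >= 0.8 * w_est &
    ms$dist_um >= 0.8 * stats::median(ms$dist_um)
  pts <- ms$points[keep, , drop = FALSE]
  par <- list(xi = par$xi[keep], eta = par$eta[keep])
  chart <- landmarks$charts[[leaflet]]
  chain_pts <- rbind(chart$basal_attachment, chart$free_edge)
  chain_par <- list(xi = c(chart$basal_xi, chart$free_xi),
                    eta = rep(c(0, 1), c(nrow(chart$basal_attachment),
                                         nrow(chart$free_edge))))
  chain_w <- max(1, nrow(pts) / (60 * nrow(chain_pts)))
  all_pts <- rbind(pts, chain_pts)
  all_par <- list(xi = c(par$xi, chain_par$xi), eta = c(par$eta, chain_par$eta))
  wts <- c(rep(1, nrow(pts)), rep(chain_w, nrow(chain_pts)))
  surf <- fit_surface(all_pts, all_par, p = p, q = q, n = n, m = m,
                      lambda = lambda, weights = wts, leaflet_id = leaflet)
  is_chain <- seq_len(nrow(all_pts)) > nrow(pts)
  if (is.finite(trim)) {
    pred <- evaluate_surface(surf, all_par$xi, all_par$eta)
    rn <- sqrt(rowSums((all_pts - pred)^2))
    ok <- rn <= trim * stats::median(rn)
    ok[is_chain] <- TRUE  # chains always kept
    surf <- fit_surface(all_pts[ok, , drop = FALSE],
                        list(xi = all_par$xi[ok], eta = all_par$eta[ok]),
                        p = p, q = q, n = n, m = m, lambda = lambda,
                        weights = wts[ok], leaflet_id = leaflet)
    is_chain <- is_chain[ok]
    all_pts <- all_pts[ok, , drop = FALSE]
    all_par <- list(xi = all_par$xi[ok], eta = all_par$eta[ok])
  }
  # the reported residual is over the mid-surface data; the edge chains are
  # boundary anchors with their own (larger) placement uncertainty
  pred <- evaluate_surface(surf, all_par$xi, all_par$eta)
  rn <- sqrt(rowSums((all_pts - pred)^2))
  attr(surf, "rms_residual") <- sqrt(mean(rn[!is_chain]^2))
  attr(surf, "n_points") <- sum(!is_chain)
  surf
}

#' Central circumferential and radial cross-sections of a fitted leaflet
#'
#' The radial section `r2` is the iso-curve `S(xi*, .)` whose free-edge end
#' is nearest the free-edge midpoint `P4`; the circumferential section `c2`
#' is the iso-curve `S(., 0.5)` through the belly point `S(xi*, 0.5)`.
#'
#' @param surface a fitted [leaflet_nurbs()].
#' @param landmarks a [valve_landmarks()].
#' @param n_samples samples per section (>= 101).
#' @return List with `c2` and `r2` (`curve3d`, role `"cross_section"`) and
#'   `xi_star`.
#' @export
central_cross_sections <- function(surface, landmarks, n_samples = 101) {
  n_samples <- max(101L, as.integer(n_samples))
  P4 <- landmarks$P4[surface$leaflet_id, ]
  xg <- seq(0, 1, length.out = 401)
  tips <- evaluate_surface(surface, xg, rep(1, length(xg)))
  xi_star <- xg[which.min(rowSums(sweep(tips, 2, P4, `-`)^2))]
  eta_g <- seq(0, 1, length.out = n_samples)
  r2 <- fit_curve_and_length(evaluate_surface(surface, rep(xi_star, n_samples),
                                              eta_g),
                             role = "cross_section")
  c2 <- fit_curve_and_length(evaluate_surface(surface,
                                              seq(0, 1, length.out = n_samples),
                                              rep(0.5, n_samples)),
                             role = "cross_section")
  list(c2 = c2, r2 = r2, xi_star = xi_star)
}

#' Normalize a cross-section into representative-shape coordinates
#'
#' Projects the section onto its best-fitted vertical plane (the plane
#' containing the valve-axis direction that minimizes the sum of squared
#' distances to the samples), takes the in-plane horizontal coordinate as
#' abscissa and the signed distance to the ANL plane as height, and divides
#' both by the normalization scale determined from the abscissa extent.
#' Circumferential sections span `[-1, 1]` (scale = half the extent);
#' radial sections span `[0, 1]` with 0 at the basal end (scale = the
#' extent). Heights are divided by the same scale, with `h = 0` on the ANL
#' plane.
#'
#' @param curve a `curve3d` cross-section.
#' @param anl the annulus plane.
#' @param valve_axis unit vector (the ANL normal).
#' @param direction `"circumferential"` or `"radial"`.
#' @param leaflet_id,tvp metadata stored on the result.
#' @param n_samples number of samples along the curve.
#' @return An object of class `cross_section` with a `samples` tibble
#'   (`abscissa`, `h_bar`), the fitted vertical `plane`, and
#'   `normalization_scale` (um).
#' @export
normalize_cross_section <- function(curve, anl, valve_axis,
                                    direction = c("circumferential", "radial"),
                                    leaflet_id = NA_character_, tvp = NA_real_,
                                    n_samples = 101) {
  direction <- match.arg(direction)
  u <- seq(0, 1, length.out = n_samples)
  pts <- rbind3(curve$eval(u * curve$param[length(curve$param)]))
  a <- unitize(valve_axis)
  fr <- frame_from_normal(a)
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr, `-`)
  q <- rel %*% fr[, 1:2]  # coordinates in the plane orthogonal to the axis
  C2 <- crossprod(q) / nrow(q)
  ev <- eigen(C2, symmetric = TRUE)
  n_in <- fr[, 1:2] %*% ev$vectors[, 2]   # smallest-variance in-plane normal
  horiz <- unitize(cross3(a, drop(n_in)))
  t_raw <- drop(rel %*% horiz)
  extent <- max(t_raw) - min(t_raw)
  if (extent < 1e-6 * max(1, vec_norm(apply(pts, 2, max) - apply(pts, 2, min)))) {
    stop("normalization error: degenerate (near-vertical-line) cross-section")
  }
  if (t_raw[n_samples] < t_raw[1]) {
    horiz <- -horiz
    t_raw <- -t_raw
  }
  hgt <- plane_distance(anl, pts)
  if (direction == "circumferential") {
    scale <- extent / 2
    abscissa <- (t_raw - (max(t_raw) + min(t_raw)) / 2) / scale
  } else {
    scale <- extent
    abscissa <- (t_raw - min(t_raw)) / scale
  }
  structure(list(direction = direction,
                 samples = tibble(abscissa = abscissa, h_bar = hgt / scale),
                 plane = valve_plane(ctr, n_in),
                 normalization_scale = scale,
                 leaflet_id = leaflet_id, tvp = tvp),
            class = "cross_section")
}

#' Average cross-sections into a representative shape
#'
#' Resamples every section onto a common abscissa grid by linear
#' interpolation and reports the per-gridpoint mean and standard deviation.
#'
#' @param sections list of `cross_section`, all with the same direction and
#'   transvalvular pressure.
#' @param n_grid number of abscissa grid points.
#' @return An object of class `mean_cross_section` with a tibble `samples`
#'   (`abscissa`, `h_bar_mean`, `h_bar_sd`), `n_samples`, `direction`, `tvp`.
#' @export
average_cross_sections <- function(sections, n_grid = 101) {
  stopifnot(length(sections) >= 2)
  dirs <- unique(vapply(sections, function(s) s$direction, character(1)))
  tvps <- unique(vapply(sections, function(s) s$tvp, numeric(1)))
  if (length(dirs) != 1 || length(tvps) != 1) {
    stop("grouping error: sections mix directions or transvalvular pressures")
  }
  grid <- if (dirs == "circumferential") {
    seq(-1, 1, length.out = n_grid)
  } else {
    seq(0, 1, length.out = n_grid)
  }
  H <- vapply(sections, function(s) {
    approx(s$samples$abscissa, s$samples$h_bar, xout = grid, rule = 2,
           ties = "ordered")$y
  }, numeric(n_grid))
  structure(list(direction = dirs, tvp = tvps,
                 samples = tibble(abscissa = grid,
                                  h_bar_mean = rowMeans(H),
                                  h_bar_sd = apply(H, 1, sd)),
                 n_samples = length(sections)),
            class = "mean_cross_section")
}

#' Serialize a leaflet NURBS surface to JSON
#' @param surface a [leaflet_nurbs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_leaflet_nurbs <- function(surface, path) {
  d <- dim(surface$control)
  # row-major flattening: i (slow), then j, then xyz (fast)
  flat <- as.numeric(aperm(surface$control, c(3, 2, 1)))
  obj <- list(leaflet_id = surface$leaflet_id, p = surface$p, q = surface$q,
              U = surface$U, V = surface$V, n = d[1], m = d[2],
              control_row_major = flat,
              control_order = "i (slowest), j, xyz (fastest)",
              weights = "all 1 (B-spline specialization)",
              units = "um")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a leaflet NURBS surface written by [write_leaflet_nurbs()]
#' @param path JSON path.
#' @return A [leaflet_nurbs()].
#' @export
read_leaflet_nurbs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  control <- aperm(array(as.numeric(obj$control_row_major),
                         c(3, obj$m, obj$n)), c(3, 2, 1))
  leaflet_nurbs(control, p = obj$p, q = obj$q, U = obj$U, V = obj$V,
                leaflet_id = obj$leaflet_id)
}
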