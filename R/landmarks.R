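# Landmark detection on labeled valve volumes: valve axis, commissure
# points, leaflet edge chains, and the ANL / STJ planes.

#' Valve landmarks container
#'
#' @param commissures 3 x 3 matrix, rows `P1` (anterior/left), `P2`
#'   (anterior/right), `P3` (left/right), in um.
#' @param P4,P5 3 x 3 matrices of per-leaflet free-edge and basal midpoints,
#'   rows named anterior/left/right.
#' @param anl,stj the annulus and sino-tubular junction planes
#'   ([valve_plane()]), normals oriented towards the arterial side.
#' @param charts optional per-leaflet edge chains used for surface
#'   parametrization (as returned by [extract_leaflet_edges()]).
#' @return An object of class `valve_landmarks`.
#' @export
valve_landmarks <- function(commissures, P4, P5, anl, stj, charts = NULL) {
  commissures <- rbind3(commissures)
  rownames(commissures) <- c("P1", "P2", "P3")
  P4 <- rbind3(P4); rownames(P4) <- leaflet_names()
  P5 <- rbind3(P5); rownames(P5) <- leaflet_names()
  structure(list(commissures = commissures, P4 = P4, P5 = P5,
                 anl = anl, stj = stj, charts = charts),
            class = "valve_landmarks")
}

#' @export
print.valve_landmarks <- function(x, ...) {
  cat("<valve_landmarks>\n")
  cat(sprintf("  tilt angle ANL/STJ: %.2f deg\n", tilt_angle(x$anl, x$stj)))
  cat(sprintf("  commissure heights above ANL (um): %s\n",
              paste(signif(plane_distance(x$anl, x$commissures), 4),
                    collapse = ", ")))
  invisible(x)
}

# leaflet -> (first, second) commissure names; the circumferential direction
# of every leaflet runs from its first to its second commissure
leaflet_commissures <- function() {
  list(anterior = c("P1", "P2"), left = c("P3", "P1"), right = c("P2", "P3"))
}

#' Estimate the valve axis from the wall label
#'
#' The wall is an approximate tube of revolution, so the covariance of its
#' voxel cloud has two nearly equal (radial) eigenvalues; the axis is the
#' eigenvector of the isolated eigenvalue, oriented from the leaflet side
#' towards the arterial side (the wall centroid lies beyond the leaflet
#' centroid).
#'
#' @param volume a [valve_volume()].
#' @return List with `center` (wall centroid, um) and `direction` (unit).
#' @export
valve_axis <- function(volume) {
  d <- dim(volume$grid)
  mw <- cpp_label_moments(volume$grid, d, label_code(volume, "wall"),
                          volume$origin, volume$voxel_size)
  if (mw$n < 10) stop("wall label missing or too small to define an axis")
  cw <- mw$sum / mw$n
  cov <- mw$sumsq / mw$n - tcrossprod(cw)
  ev <- eigen(cov, symmetric = TRUE)
  # the wall is a tube of revolution: the two radial eigenvalues are nearly
  # equal, and the rotation axis belongs to the isolated eigenvalue
  iso <- vapply(1:3, function(i) min(abs(ev$values[i] - ev$values[-i])),
                numeric(1))
  axis <- ev$vectors[, which.max(iso)]
  # refine: centroids of fully annular axial slabs lie exactly on the axis
  # even when the rim is tilted, which the covariance estimate is not robust to
  idx <- cpp_which_label(volume$grid, d, label_code(volume, "wall"))
  xyz <- voxel_coords(volume, idx)
  t_ax <- drop(sweep(xyz, 2, cw) %*% axis)
  slabs <- seq(min(t_ax), max(t_ax), by = 5 * volume$voxel_size)
  if (length(slabs) >= 5) {
    fr <- frame_from_normal(axis)
    psi <- atan2(sweep(xyz, 2, cw) %*% fr[, 2], sweep(xyz, 2, cw) %*% fr[, 1])
    sl <- findInterval(t_ax, slabs, rightmost.closed = TRUE)
    cents <- NULL
    for (s in unique(sl)) {
      in_s <- sl == s
      cover <- tabulate(findInterval(psi[in_s], seq(-pi, pi, length.out = 25),
                                     all.inside = TRUE), nbins = 24)
      if (all(cover > 0)) cents <- rbind(cents, colMeans(xyz[in_s, , drop = FALSE]))
    }
    if (!is.null(cents) && nrow(cents) >= 3) {
      cc <- colMeans(cents)
      ax2 <- eigen(crossprod(sweep(cents, 2, cc)), symmetric = TRUE)$vectors[, 1]
      if (sum(ax2 * axis) < 0) ax2 <- -ax2
      axis <- ax2
      cw <- cc
    }
  }
  # orient towards the arterial side: wall centroid beyond leaflet centroid
  csum <- c(0, 0, 0); ctot <- 0
  for (nm in leaflet_names()) {
    ml <- cpp_label_moments(volume$grid, d, label_code(volume, nm),
                            volume$origin, volume$voxel_size)
    csum <- csum + ml$sum; ctot <- ctot + ml$n
  }
  if (ctot > 0 && sum(axis * (cw - csum / ctot)) < 0) axis <- -axis
  list(center = cw, direction = unitize(axis))
}

#' Detect the three commissure points of a labeled valve
#'
#' For each unordered leaflet pair, the contact set is the voxels of either
#' leaflet that are 26-adjacent to the other leaflet and 26-adjacent to the
#' arterial wall. The commissure is the contact voxel farthest towards the
#' arterial side along the valve axis (ties broken by lexicographic
#' coordinate order).
#'
#' @param volume a [valve_volume()].
#' @return 3 x 3 matrix of points (um); rows `P1` = anterior/left,
#'   `P2` = anterior/right, `P3` = left/right.
#' @export
find_commissures <- function(volume) {
  d <- dim(volume$grid)
  for (nm in c("wall", leaflet_names())) {
    if (length(cpp_which_label(volume$grid, d, label_code(volume, nm))) == 0) {
      stop("landmark detection error: label '", nm, "' absent from volume")
    }
  }
  axis <- valve_axis(volume)
  pairs <- list(P1 = c("anterior", "left"), P2 = c("anterior", "right"),
                P3 = c("left", "right"))
  wall <- label_code(volume, "wall")
  wall_adj <- lapply(setNames(leaflet_names(), leaflet_names()), function(nm) {
    cpp_adjacency(volume$grid, d, label_code(volume, nm), wall)
  })
  contact <- lapply(pairs, function(pr) {
    a <- label_code(volume, pr[1]); b <- label_code(volume, pr[2])
    ia <- intersect(cpp_adjacency(volume$grid, d, a, b), wall_adj[[pr[1]]])
    ib <- intersect(cpp_adjacency(volume$grid, d, b, a), wall_adj[[pr[2]]])
    idx <- c(ia, ib)
    if (length(idx) == 0) {
      stop("landmark detection error: leaflet pair ", pr[1], "/", pr[2],
           " has no mutual contact adjacent to the wall")
    }
    voxel_coords(volume, idx)
  })
  # commissures sit on the arterial side: orient the axis so the contact
  # sets project beyond the leaflet bulk
  csum <- c(0, 0, 0); ctot <- 0
  for (nm in leaflet_names()) {
    ml <- cpp_label_moments(volume$grid, d, label_code(volume, nm),
                            volume$origin, volume$voxel_size)
    csum <- csum + ml$sum; ctot <- ctot + ml$n
  }
  cmean <- colMeans(do.call(rbind, contact))
  if (sum(axis$direction * (cmean - csum / ctot)) < 0) {
    axis$direction <- -axis$direction
  }
  # mid-surface clouds give the thickness scale and local sheet orientation
  mids <- lapply(setNames(leaflet_names(), leaflet_names()), function(nm) {
    extract_mid_surface(volume, nm)
  })
  w_est <- 2 * stats::median(mids$anterior$dist_um) + 0.35 * volume$voxel_size
  rho <- max(6 * volume$voxel_size, 3 * w_est)
  pts <- t(vapply(names(pairs), function(pn) {
    pr <- pairs[[pn]]
    C <- contact[[pn]]
    q <- C[which.max(C %*% axis$direction), ]
    # the leaflet pair merges into one label right at the tip, so the contact
    # set stops short of the commissure; the basal attachment does not, so
    # refine to the farthest wall-attached voxel of either leaflet near the
    # contact region
    wa <- voxel_coords(volume, c(wall_adj[[pr[1]]], wall_adj[[pr[2]]]))
    keep <- colSums((t(wa) - q)^2) <= rho^2
    xyz <- rbind(q, wa[keep, , drop = FALSE])
    proj <- drop(xyz %*% axis$direction)
    cand <- which(proj >= max(proj) - 1e-9)
    if (length(cand) > 1) {
      xyzc <- xyz[cand, , drop = FALSE]
      cand <- cand[order(xyzc[, 1], xyzc[, 2], xyzc[, 3])[1]]
    }
    top <- xyz[cand, ]
    # the thickened leaflet overshoots its mid-surface tip by half a
    # thickness along the sheet normal; project that overshoot out using the
    # local mid-surface orientation
    near <- list()
    for (nm in pr) {
      ml <- mids[[nm]]
      sel <- rowSums(sweep(ml$points, 2, top, `-`)^2) <= (3 * w_est)^2
      near[[nm]] <- ml$points[sel, , drop = FALSE]
    }
    P <- do.call(rbind, near)
    if (!is.null(P) && nrow(P) >= 8) {
      nrm <- eigen(crossprod(sweep(P, 2, colMeans(P))),
                   symmetric = TRUE)$vectors[, 3]
      top <- top - (w_est / 2) * abs(sum(nrm * axis$direction)) * axis$direction
    }
    top
  }, numeric(3)))
  rownames(pts) <- names(pairs)
  pts
}

# azimuth of points about an axis, and the leaflet-sector fraction machinery
wrap_pos <- function(a) a %% (2 * pi)

sector_fraction <- function(psi, psi_a, psi_b, interior_psi) {
  span_pos <- wrap_pos(psi_b - psi_a)
  use_pos <- wrap_pos(interior_psi - psi_a) <= span_pos
  if (use_pos) {
    frac <- wrap_pos(psi - psi_a) / span_pos
    # points marginally on the other arc wrap to ~2pi/span; fold them back
    frac[frac > 1 + (2 * pi / span_pos - 1) / 2] <-
      frac[frac > 1 + (2 * pi / span_pos - 1) / 2] - 2 * pi / span_pos
  } else {
    span_neg <- 2 * pi - span_pos
    frac <- wrap_pos(psi_a - psi) / span_neg
    frac[frac > 1 + (2 * pi / span_neg - 1) / 2] <-
      frac[frac > 1 + (2 * pi / span_neg - 1) / 2] - 2 * pi / span_neg
  }
  frac
}

azimuth_about <- function(pts, center, direction) {
  fr <- frame_from_normal(direction)
  rel <- sweep(rbind3(pts), 2, center, `-`)
  atan2(rel %*% fr[, 2], rel %*% fr[, 1])
}

#' Extract the free-edge and basal-attachment node chains of a leaflet
#'
#' The basal attachment is the chain of leaflet voxels 26-adjacent to the
#' arterial wall (a 1-voxel dilation defines "attached"); the free edge is,
#' per azimuthal transect, the radially innermost margin of the leaflet
#' mid-surface (the mid-surface ridge carries no half-thickness ambiguity,
#' and the free margin is the leaflet's closest approach to the valve axis).
#' Bins within ~1.5 leaflet thicknesses of a commissure are discarded (the
#' coapting leaflets contaminate both chains there) and both chains are
#' anchored at the exact commissure points, ordered from the leaflet's first
#' commissure to its second, and decimated to approximately `spacing` um
#' between nodes by window averaging. These deterministic rules replace
#' interactive correction of mis-detected edge nodes.
#'
#' @param volume a [valve_volume()].
#' @param leaflet `"anterior"`, `"left"` or `"right"`.
#' @param commissures 3 x 3 matrix from [find_commissures()].
#' @param spacing node spacing after decimation (um).
#' @param thickness_hint leaflet thickness (um) used for rim retraction;
#'   estimated from the distance transform when `NULL`.
#' @return List with `free_edge` and `basal_attachment` (node matrices, um),
#'   the corresponding sector fractions `free_xi` / `basal_xi`, and the
#'   estimated `thickness_um`.
#' @export
extract_leaflet_edges <- function(volume, leaflet, commissures, spacing = 10,
                                  thickness_hint = NULL) {
  d <- dim(volume$grid)
  code <- label_code(volume, leaflet)
  wall <- label_code(volume, "wall")
  axis <- valve_axis(volume)
  h <- volume$voxel_size

  idx_all <- cpp_which_label(volume$grid, d, code)
  if (length(idx_all) == 0) stop("leaflet label '", leaflet, "' absent")
  idx_basal <- cpp_adjacency(volume$grid, d, code, wall)
  if (length(idx_basal) < 4) {
    stop("topology error: leaflet '", leaflet, "' has no basal attachment to the wall")
  }
  all_xyz <- voxel_coords(volume, idx_all)
  basal_xyz <- voxel_coords(volume, idx_basal)

  cm <- leaflet_commissures()[[leaflet]]
  ca <- commissures[cm[1], ]; cb <- commissures[cm[2], ]
  psi_a <- drop(azimuth_about(ca, axis$center, axis$direction))
  psi_b <- drop(azimuth_about(cb, axis$center, axis$direction))
  interior <- drop(azimuth_about(colMeans(all_xyz), axis$center, axis$direction))
  frac_basal <- sector_fraction(azimuth_about(basal_xyz, axis$center, axis$direction),
                                psi_a, psi_b, interior)

  mid <- extract_mid_surface(volume, leaflet)
  if (is.null(thickness_hint)) {
    thickness_hint <- max(h, 2 * stats::median(mid$dist_um) + 0.35 * h)
  }

  # azimuthal bins spanning the leaflet sector
  arc <- abs(wrap_pos(psi_b - psi_a))
  arc <- min(arc, 2 * pi - arc)
  rad <- stats::median(sqrt(rowSums(sweep(basal_xyz, 2, axis$center, `-`)[, 1:2, drop = FALSE]^2)))
  n_bins <- max(24L, min(600L, as.integer(arc * rad / max(2 * h, 5))))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin_of <- function(frac) pmin(n_bins, pmax(1L, findInterval(frac, edges,
                                                              rightmost.closed = TRUE)))
  mids <- (edges[-1] + edges[-length(edges)]) / 2

  b_bin <- bin_of(frac_basal)
  basal_nodes <- matrix(NA_real_, n_bins, 3)
  for (ax in 1:3) {
    s <- tapply(basal_xyz[, ax], factor(b_bin, levels = seq_len(n_bins)), mean)
    basal_nodes[, ax] <- as.numeric(s)
  }
  miss <- which(is.na(basal_nodes[, 1]))
  if (length(miss) > 0) {
    runs <- rle(seq_len(n_bins) %in% miss)
    if (any(runs$lengths[runs$values] > max(3, n_bins %/% 20))) {
      stop("topology error: basal attachment chain of leaflet '", leaflet,
           "' is disconnected")
    }
    for (ax in 1:3) {
      basal_nodes[, ax] <- approx(mids[-miss], basal_nodes[-miss, ax],
                                  xout = mids, rule = 2)$y
    }
  }

  # free edge = radially innermost margin of the mid-surface per transect:
  # the mid-surface ridge carries no +/- half-thickness ambiguity, and the
  # leaflet's free margin is its closest approach to the valve axis
  frac_mid <- sector_fraction(azimuth_about(mid$points, axis$center,
                                            axis$direction),
                              psi_a, psi_b, interior)
  rel_mid <- sweep(mid$points, 2, axis$center, `-`)
  ax_comp <- drop(rel_mid %*% axis$direction)
  r_mid <- sqrt(rowSums((rel_mid - outer(ax_comp, axis$direction))^2))
  m_bin <- bin_of(frac_mid)
  free_nodes <- matrix(NA_real_, n_bins, 3)
  for (bi in seq_len(n_bins)) {
    in_bin <- which(m_bin == bi)
    if (length(in_bin) == 0) next
    rmin <- min(r_mid[in_bin])
    cap <- in_bin[r_mid[in_bin] <= rmin + h]
    free_nodes[bi, ] <- colMeans(mid$points[cap, , drop = FALSE])
  }
  miss <- which(is.na(free_nodes[, 1]))
  if (length(miss) > 0) {
    runs <- rle(seq_len(n_bins) %in% miss)
    if (any(runs$lengths[runs$values] > max(3, n_bins %/% 20))) {
      stop("topology error: free-edge chain of leaflet '", leaflet,
           "' is disconnected")
    }
    for (ax in 1:3) {
      free_nodes[, ax] <- approx(mids[-miss], free_nodes[-miss, ax],
                                 xout = mids, rule = 2)$y
    }
  }

  # drop bins within ~1.5 thicknesses of either commissure: there the two
  # leaflets coapt and the adjacency bands contaminate both chains
  trim <- 1.5 * thickness_hint
  keep_b <- sqrt(rowSums(sweep(basal_nodes, 2, ca, `-`)^2)) > trim &
    sqrt(rowSums(sweep(basal_nodes, 2, cb, `-`)^2)) > trim
  keep_f <- sqrt(rowSums(sweep(free_nodes, 2, ca, `-`)^2)) > trim &
    sqrt(rowSums(sweep(free_nodes, 2, cb, `-`)^2)) > trim

  # light chain smoothing against voxel-quantization jitter
  basal_nodes <- smooth_chain(basal_nodes[keep_b, , drop = FALSE])
  free_nodes <- smooth_chain(free_nodes[keep_f, , drop = FALSE])

  # anchor both chains at the exact commissure points
  basal_nodes <- rbind(ca, basal_nodes, cb)
  free_nodes <- rbind(ca, free_nodes, cb)
  xi_b <- c(0, mids[keep_b], 1)
  xi_f <- c(0, mids[keep_f], 1)

  bk <- decimate_keep(basal_nodes, xi_b, spacing)
  fk <- decimate_keep(free_nodes, xi_f, spacing)
  list(free_edge = fk$nodes, basal_attachment = bk$nodes,
       free_xi = fk$xi, basal_xi = bk$xi, thickness_um = thickness_hint)
}

# 3-node moving average, endpoints kept
smooth_chain <- function(nodes) {
  n <- nrow(nodes)
  if (n < 3) return(nodes)
  sm <- (nodes[c(1, 1:(n - 1)), ] + nodes + nodes[c(2:n, n), ]) / 3
  sm[1, ] <- nodes[1, ]; sm[n, ] <- nodes[n, ]
  sm
}

# decimate nodes (with attached parameter values) to ~spacing um by
# window-averaging, keeping the exact endpoints
decimate_keep <- function(nodes, xi, spacing) {
  cl <- polyline_cumlen(nodes)
  total <- cl[length(cl)]
  nseg <- max(3, ceiling(total / spacing))
  edges <- seq(0, total, length.out = nseg + 1)
  win <- findInterval(cl, edges, rightmost.closed = TRUE)
  out_nodes <- rowsum(nodes, win) / as.numeric(table(win))
  out_xi <- as.numeric(rowsum(xi, win) / as.numeric(table(win)))
  # exact endpoints (commissures) stay
  out_nodes[1, ] <- nodes[1, ]; out_nodes[nrow(out_nodes), ] <- nodes[nrow(nodes), ]
  out_xi[1] <- xi[1]; out_xi[length(out_xi)] <- xi[length(xi)]
  list(nodes = out_nodes, xi = out_xi)
}

#' Build the ANL and STJ planes and assemble the valve landmarks
#'
#' The basal midpoint `P5` of each leaflet is the arc-length midpoint of its
#' basal-attachment curve; the ANL (annulus) plane passes through the three
#' `P5`. The STJ plane passes through the commissure points `P1`, `P2`, `P3`.
#' `P4` is the arc-length midpoint of each free edge. Both normals point
#' towards the arterial side.
#'
#' @param commissures 3 x 3 matrix from [find_commissures()].
#' @param basal_curves named list (anterior/left/right) of `curve3d`.
#' @param free_curves named list of `curve3d`.
#' @param charts optional per-leaflet chain lists stored for parametrization.
#' @return A [valve_landmarks()] object.
#' @export
build_planes <- function(commissures, basal_curves, free_curves,
                         charts = NULL) {
  P5 <- t(vapply(leaflet_names(),
                 function(nm) curve_midpoint(basal_curves[[nm]]), numeric(3)))
  P4 <- t(vapply(leaflet_names(),
                 function(nm) curve_midpoint(free_curves[[nm]]), numeric(3)))
  anl <- plane_through_points(P5[1, ], P5[2, ], P5[3, ],
                              orient_towards = colMeans(commissures))
  stj <- plane_through_points(commissures[1, ], commissures[2, ],
                              commissures[3, ],
                              orient_towards = commissures[1, ] + anl$normal * 10)
  if (sum(stj$normal * anl$normal) < 0) stj$normal <- -stj$normal
  valve_landmarks(commissures, P4, P5, anl, stj, charts = charts)
}
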