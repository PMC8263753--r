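# Synthetic tri-leaflet valve phantoms with closed-form ground truth.
#
# The phantom lives in a canonical frame with the valve axis along +z and the
# nominal annulus (ANL) level at z = 0, then is rigidly placed by
# `axis_origin` / `axis_direction`. The arterial wall is a shell of revolution
# whose rim (commissure circle, nominal sino-tubular junction level) is tilted
# by `tilt_angle_true` about an axis through the anterior leaflet midpoint.
# Each leaflet mid-surface is a ruled patch between its basal attachment arc
# on the wall and a free-edge curve, with a quadratic belly sag, so that every
# geometric quantity of interest has a closed form that can be evaluated by
# dense sampling, independent of the voxel pipeline under test.

quad_bezier <- function(t, a, c, b) (1 - t)^2 * a + 2 * t * (1 - t) * c + t^2 * b

#' Parameters of a synthetic valve phantom
#'
#' @param axis_origin point on the valve axis at the nominal annulus level (um).
#' @param axis_direction unit vector along the valve axis (towards the artery).
#' @param wall_radius_at_ANL,wall_radius_at_STJ wall mid-surface radii (um) at
#'   the annulus level and at the commissure rim.
#' @param valve_height_true rim height above the annulus at the anterior
#'   leaflet midpoint (um); the tilt raises the rest of the rim.
#' @param leaflet_scale named dimensionless scales in (0, 1] for
#'   `anterior`, `left`, `right`; azimuthal sector widths are proportional.
#' @param leaflet_thickness_true leaflet thickness (um).
#' @param tilt_angle_true tilt of the commissure rim plane relative to the
#'   annulus plane (degrees, in `[0, 30)`).
#' @param belly_sag_depth downward sag of the leaflet belly (um).
#' @param free_edge_radius_frac radial position of the free-edge midpoint as a
#'   fraction of `wall_radius_at_STJ`.
#' @param free_edge_mid_height height (um) of the free-edge midpoint relative
#'   to the nominal annulus level (negative: below).
#' @param wall_thickness arterial wall shell thickness (um).
#' @param voxel_size isotropic voxel size (um); must not exceed
#'   `leaflet_thickness_true / 3` so leaflets remain resolvable.
#' @param tvp transvalvular pressure the phantom represents (mmHg).
#' @param seed integer seed recorded with the phantom.
#' @return An object of class `valve_phantom_params`.
#' @export
valve_phantom_params <- function(axis_origin = c(0, 0, 0),
                                 axis_direction = c(0, 0, 1),
                                 wall_radius_at_ANL = 780,
                                 wall_radius_at_STJ = 700,
                                 valve_height_true = 650,
                                 leaflet_scale = c(anterior = 0.8, left = 1, right = 1),
                                 leaflet_thickness_true = 19,
                                 tilt_angle_true = 10,
                                 belly_sag_depth = 120,
                                 free_edge_radius_frac = 0.5,
                                 free_edge_mid_height = -40,
                                 wall_thickness = 45,
                                 voxel_size = 2.8,
                                 tvp = 10,
                                 seed = 1L) {
  p <- list(axis_origin = as.numeric(axis_origin),
            axis_direction = unitize(axis_direction),
            wall_radius_at_ANL = wall_radius_at_ANL,
            wall_radius_at_STJ = wall_radius_at_STJ,
            valve_height_true = valve_height_true,
            leaflet_scale = leaflet_scale[leaflet_names()],
            leaflet_thickness_true = leaflet_thickness_true,
            tilt_angle_true = tilt_angle_true,
            belly_sag_depth = belly_sag_depth,
            free_edge_radius_frac = free_edge_radius_frac,
            free_edge_mid_height = free_edge_mid_height,
            wall_thickness = wall_thickness,
            voxel_size = voxel_size, tvp = tvp, seed = as.integer(seed))
  lengths <- c(p$wall_radius_at_ANL, p$wall_radius_at_STJ, p$valve_height_true,
               p$leaflet_thickness_true, p$wall_thickness, p$voxel_size)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all phantom lengths must be finite and > 0")
  }
  if (any(is.na(p$leaflet_scale)) || any(p$leaflet_scale <= 0) ||
      any(p$leaflet_scale > 1)) {
    stop("leaflet scales must be in (0, 1] and named anterior/left/right")
  }
  if (p$tilt_angle_true < 0 || p$tilt_angle_true >= 30) {
    stop("tilt angle must lie in [0, 30) degrees")
  }
  if (p$voxel_size > p$leaflet_thickness_true / 3) {
    stop(sprintf(paste0("resolution error: voxel size %.3g um cannot resolve ",
                        "leaflets of thickness %.3g um (need voxel <= thickness/3)"),
                 p$voxel_size, p$leaflet_thickness_true))
  }
  structure(p, class = "valve_phantom_params")
}

#' Murine pulmonary valve phantom preset
#'
#' Emulates a 1-year C57BL/6J pulmonary valve fixed at a transvalvular
#' pressure of 10, 20 or 30 mmHg: perimeter near 4.6 mm at 10 mmHg growing
#' about 12% to 20 mmHg and then leveling off, leaflet thickness 19 um,
#' tilt 10 degrees, anterior leaflet 0.8x the left/right leaflets. Dimensional
#' free-edge/basal lengths are approximate (backed out of normalized values).
#'
#' @param tvp transvalvular pressure (10, 20 or 30 mmHg).
#' @param voxel_size voxel size (um).
#' @param seed integer seed.
#' @param ... overrides passed on to [valve_phantom_params()].
#' @return A `valve_phantom_params` object.
#' @export
murine_pv_preset <- function(tvp = 10, voxel_size = 2.8, seed = 1L, ...) {
  stopifnot(tvp %in% c(10, 20, 30))
  # radial growth follows the perimeter trend 4646 : 5206 : 5219 um
  growth <- c(`10` = 1, `20` = 5206 / 4646, `30` = 5219 / 4646)[[as.character(tvp)]]
  sag <- c(`10` = 120, `20` = 90, `30` = 70)[[as.character(tvp)]]
  fmh <- c(`10` = -40, `20` = -10, `30` = 10)[[as.character(tvp)]]
  args <- list(wall_radius_at_ANL = 780 * growth,
               wall_radius_at_STJ = 700 * growth,
               valve_height_true = 560,
               belly_sag_depth = sag,
               free_edge_mid_height = fmh,
               voxel_size = voxel_size, tvp = tvp, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(valve_phantom_params, args)
}

# Closed-form phantom geometry: azimuthal layout, curve and surface functions.
phantom_geometry <- function(params) {
  p <- params
  scales <- p$leaflet_scale
  widths <- 2 * pi * scales / sum(scales)
  psi_mid_anterior <- pi / 2
  psi_P1 <- psi_mid_anterior + widths[["anterior"]] / 2  # anterior/left
  psi_P2 <- psi_mid_anterior - widths[["anterior"]] / 2  # anterior/right
  psi_P3 <- psi_P1 + widths[["left"]]                    # left/right
  tanb <- tan(p$tilt_angle_true * pi / 180)
  r_anl <- p$wall_radius_at_ANL
  r_stj <- p$wall_radius_at_STJ
  h0 <- p$valve_height_true
  # rim tilted about a horizontal axis through the anterior leaflet
  # midpoint: the anterior rim stays at h0 and the opposite side rises, so
  # the commissure plane makes exactly tilt_angle_true with the annulus
  z_rim <- function(psi) h0 + r_stj * tanb * (1 - cos(psi - psi_mid_anterior))
  r_wall <- function(psi, z) r_anl + (r_stj - r_anl) * z / z_rim(psi)

  # each leaflet runs from its first to its second commissure (decreasing psi)
  leaves <- list(
    anterior = list(psi0 = psi_P1, dpsi = -widths[["anterior"]],
                    comm = c("P1", "P2")),
    left = list(psi0 = psi_P3, dpsi = -widths[["left"]], comm = c("P3", "P1")),
    right = list(psi0 = psi_P2 + 2 * pi, dpsi = -widths[["right"]],
                 comm = c("P2", "P3")))

  r_free_mid <- p$free_edge_radius_frac * r_stj
  z_free_mid <- p$free_edge_mid_height
  sag <- p$belly_sag_depth

  Q <- frame_from_normal(p$axis_direction)  # canonical -> world rotation
  to_world <- function(pc) {
    pc <- rbind3(pc)
    sweep(pc %*% t(Q), 2, p$axis_origin, `+`)
  }

  curve_funs <- lapply(leaves, function(lf) {
    psi_fun <- function(xi) lf$psi0 + xi * lf$dpsi
    z_a <- z_rim(lf$psi0)
    z_b <- z_rim(lf$psi0 + lf$dpsi)
    # basal attachment: flat-bottomed dip to the annulus level (z = 0) with
    # cubic shoulders rising to the commissures, C2 at the bottom
    zB <- function(xi) {
      z_a * pmax(0, 1 - 2 * xi)^3 + z_b * pmax(0, 2 * xi - 1)^3
    }
    zF <- function(xi) quad_bezier(xi, z_a, 2 * z_free_mid - (z_a + z_b) / 2, z_b)
    rF <- function(xi) quad_bezier(xi, r_stj, 2 * r_free_mid - r_stj, r_stj)
    B <- function(xi) {
      psi <- psi_fun(xi); z <- zB(xi); r <- r_wall(psi, z)
      cbind(r * cos(psi), r * sin(psi), z)
    }
    F <- function(xi) {
      psi <- psi_fun(xi); z <- zF(xi); r <- rF(xi)
      cbind(r * cos(psi), r * sin(psi), z)
    }
    S <- function(xi, eta) {
      psi <- psi_fun(xi)
      r <- (1 - eta) * r_wall(psi, zB(xi)) + eta * rF(xi)
      z <- (1 - eta) * zB(xi) + eta * zF(xi) - sag * 4 * eta * (1 - eta) * sin(pi * xi)
      cbind(r * cos(psi), r * sin(psi), z)
    }
    list(psi = psi_fun, B = B, F = F, S = S,
         B_world = function(xi) to_world(B(xi)),
         F_world = function(xi) to_world(F(xi)),
         S_world = function(xi, eta) to_world(S(xi, eta)),
         comm = lf$comm)
  })

  comm_psi <- c(P1 = psi_P1, P2 = psi_P2, P3 = psi_P3)
  comm_can <- t(vapply(comm_psi, function(ps) {
    z <- z_rim(ps)
    c(r_stj * cos(ps), r_stj * sin(ps), z)
  }, numeric(3)))
  list(leaves = curve_funs, commissures = to_world(comm_can),
       comm_psi = comm_psi, z_rim = z_rim, r_wall = r_wall,
       psi_mid_anterior = psi_mid_anterior, tanb = tanb, Q = Q,
       to_world = to_world)
}

#' Closed-form ground truth of a valve phantom
#'
#' Evaluates the phantom's analytic curves by dense sampling (default 4001
#' points per curve) to produce landmarks and all geometric quantities of
#' interest. This is computed entirely from the closed forms; the voxel
#' pipeline is never involved.
#'
#' @param params a [valve_phantom_params()].
#' @param n_dense number of samples per curve.
#' @return A list with `landmarks`, `gqoi` (a `gqoi_record`), and
#'   `mid_surfaces` (per-leaflet closures `S(xi, eta)` in world coordinates).
#' @export
phantom_ground_truth <- function(params, n_dense = 4001) {
  geom <- phantom_geometry(params)
  xi <- seq(0, 1, length.out = n_dense)
  basal <- lapply(geom$leaves, function(lf) lf$B_world(xi))
  free <- lapply(geom$leaves, function(lf) lf$F_world(xi))
  L_BA <- vapply(basal, polyline_length, numeric(1))
  L_FE <- vapply(free, polyline_length, numeric(1))
  P5 <- lapply(basal, polyline_point_at, frac = 0.5)
  P4 <- lapply(free, polyline_point_at, frac = 0.5)
  comm <- geom$commissures  # rows P1, P2, P3

  stj <- plane_through_points(comm[1, ], comm[2, ], comm[3, ],
                              orient_towards = comm[1, ] + params$axis_direction)
  anl <- plane_through_points(P5$anterior, P5$left, P5$right,
                              orient_towards = colMeans(comm))
  if (sum(stj$normal * anl$normal) < 0) stj$normal <- -stj$normal

  H <- mean(abs(plane_distance(anl, comm)))
  beta <- acos(min(1, abs(sum(anl$normal * stj$normal)))) * 180 / pi

  # perimeter: project basal chains onto the ANL plane; traversal order
  # anterior (P1->P2), right (P2->P3), left (P3->P1) closes the loop
  proj <- lapply(basal[c("anterior", "right", "left")],
                 function(ch) project_onto_plane(anl, ch))
  contour <- rbind(proj[[1]], proj[[2]][-1, ], proj[[3]][-1, ])
  L_gamma <- polyline_length(rbind(contour, contour[1, , drop = FALSE]))

  landmarks <- valve_landmarks(
    commissures = comm,
    P4 = do.call(rbind, P4[leaflet_names()]),
    P5 = do.call(rbind, P5[leaflet_names()]),
    anl = anl, stj = stj)

  gqoi <- assemble_gqoi(sample_id = "phantom-truth", tvp = params$tvp,
                        L_FE = L_FE[leaflet_names()],
                        L_BA = L_BA[leaflet_names()],
                        H = H, w = params$leaflet_thickness_true,
                        L_gamma = L_gamma, beta_deg = beta)
  list(landmarks = landmarks, gqoi = gqoi,
       mid_surfaces = lapply(geom$leaves, function(lf) lf$S_world))
}

#' Generate a labeled voxel phantom of a tri-leaflet valve
#'
#' Voxelizes the phantom's arterial wall and thickened leaflet mid-surfaces
#' into a labeled volume (labels per [valve_labels()]), builds per-leaflet
#' triangle meshes of the analytic mid-surfaces, and returns the closed-form
#' ground truth alongside.
#'
#' @param params a [valve_phantom_params()].
#' @param mesh_res grid resolution `(n_xi, n_eta)` of the output meshes.
#' @return List with `volume` (a [valve_volume()]), `meshes` (per leaflet:
#'   `vertices`, `faces`), `truth` (see [phantom_ground_truth()]), `params`.
#' @export
generate_valve_phantom <- function(params, mesh_res = c(64, 24)) {
  stopifnot(inherits(params, "valve_phantom_params"))
  h <- params$voxel_size
  geom <- phantom_geometry(params)
  truth <- phantom_ground_truth(params)

  # bounding box: sample the outer wall shell and rim in world coordinates
  psi <- seq(0, 2 * pi, length.out = 181)
  r_out <- max(params$wall_radius_at_ANL, params$wall_radius_at_STJ) +
    params$wall_thickness
  z_bot <- -max(120, 2 * params$belly_sag_depth)
  ring <- function(z) cbind(r_out * cos(psi), r_out * sin(psi), z)
  shell <- rbind(ring(z_bot), cbind(r_out * cos(psi), r_out * sin(psi),
                                    geom$z_rim(psi) + 4 * h))
  shell_w <- geom$to_world(shell)
  margin <- 4 * h
  lo <- apply(shell_w, 2, min) - margin
  hi <- apply(shell_w, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / h))
  grid <- raw(prod(dims))
  dim(grid) <- dims

  labs <- valve_labels()
  rot_wc <- t(geom$Q)  # world -> canonical
  cpp_paint_wall(grid, dims, lo, h, rot_wc, params$axis_origin,
                 params$wall_radius_at_ANL, params$wall_radius_at_STJ,
                 params$valve_height_true, geom$tanb, geom$psi_mid_anterior,
                 params$wall_thickness, z_bot, labs[["wall"]])

  half_t <- params$leaflet_thickness_true / 2
  step <- 0.45 * h
  for (nm in leaflet_names()) {
    lf <- geom$leaves[[nm]]
    L_ba <- truth$gqoi$L_BA[[nm]]
    trans_len <- vec_norm(lf$F_world(0.5) - lf$B_world(0.5)) +
      2 * params$belly_sag_depth
    n_xi <- max(64L, ceiling(L_ba / (h / 2)))
    n_eta <- max(32L, ceiling(trans_len / (h / 2)))
    eta_ext <- (params$wall_thickness / 2 + 2 * h) / max(trans_len, 1)
    eta <- seq(-eta_ext, 1, length.out = n_eta)
    xi_all <- seq(0, 1, length.out = n_xi)
    block <- max(1L, floor(2e5 / n_eta))
    for (start in seq(1, n_xi, by = block)) {
      xs <- xi_all[start:min(start + block - 1, n_xi)]
      g <- expand.grid(xi = xs, eta = eta)
      pts <- lf$S_world(g$xi, g$eta)
      d <- 1e-4
      du <- lf$S_world(pmin(g$xi + d, 1), g$eta) -
        lf$S_world(pmax(g$xi - d, 0), g$eta)
      dv <- lf$S_world(g$xi, g$eta + d) - lf$S_world(g$xi, g$eta - d)
      nrm <- cbind(du[, 2] * dv[, 3] - du[, 3] * dv[, 2],
                   du[, 3] * dv[, 1] - du[, 1] * dv[, 3],
                   du[, 1] * dv[, 2] - du[, 2] * dv[, 1])
      len <- sqrt(rowSums(nrm^2))
      ok <- len > 1e-9
      nrm <- nrm[ok, , drop = FALSE] / len[ok]
      cpp_stamp_points(grid, dims, lo, h, pts[ok, , drop = FALSE], nrm,
                       half_t, step, labs[[nm]], labs[["wall"]])
    }
  }

  meshes <- lapply(leaflet_names(), function(nm) {
    surface_mesh(geom$leaves[[nm]]$S_world, mesh_res[1], mesh_res[2])
  })
  names(meshes) <- leaflet_names()

  list(volume = valve_volume(grid, h, lo), meshes = meshes, truth = truth,
       params = params)
}

# triangle mesh of a parametric surface on a regular (xi, eta) grid
surface_mesh <- function(S, n_xi, n_eta) {
  g <- expand.grid(xi = seq(0, 1, length.out = n_xi),
                   eta = seq(0, 1, length.out = n_eta))
  v <- S(g$xi, g$eta)
  idx <- function(i, j) (j - 1) * n_xi + i
  faces <- NULL
  i <- rep(seq_len(n_xi - 1), n_eta - 1)
  j <- rep(seq_len(n_eta - 1), each = n_xi - 1)
  faces <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  list(vertices = v, faces = faces)
}

#' Generate a synthetic collagen fiber set
#'
#' Fiber axes are drawn from a von Mises-Fisher distribution about the mean
#' direction and antipodally symmetrized (fibers are orientations, not
#' vectors); the stored representative lies in the z >= 0 hemisphere.
#' Diameters follow a normal distribution truncated to positive values.
#'
#' @param mean_direction unit 3-vector; the preferred fiber axis.
#' @param concentration von Mises-Fisher concentration kappa >= 0
#'   (0 = isotropic; values above 1e6 collapse onto the mean axis).
#' @param n_fibers number of fibers (>= 1).
#' @param diameter_mean_nm,diameter_sd_nm diameter distribution (nm).
#' @param frame_name coordinate frame name stored with the set.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @param centroid_box_um edge length of the cube in which centroids are
#'   placed uniformly (um).
#' @return A [fiber_set()].
#' @export
generate_fiber_set <- function(mean_direction, concentration, n_fibers,
                               diameter_mean_nm = 90, diameter_sd_nm = 5,
                               frame_name = "sem", seed = 1L,
                               centroid_box_um = 40) {
  if (!is.finite(concentration) || concentration < 0) {
    stop("concentration kappa must be >= 0")
  }
  stopifnot(n_fibers >= 1)
  mu <- unitize(mean_direction)
  with_seed(seed, {
    kap <- min(concentration, 1e6)
    u <- runif(n_fibers)
    w <- if (kap < 1e-12) {
      2 * u - 1  # uniform on the sphere
    } else if (concentration >= 1e6) {
      rep(1, n_fibers)
    } else {
      1 + log(u + (1 - u) * exp(-2 * kap)) / kap
    }
    w <- pmin(1, pmax(-1, w))
    phi <- runif(n_fibers, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - w^2))
    local <- cbind(s * cos(phi), s * sin(phi), w)
    Q <- frame_from_normal(mu)  # maps local z to mu
    dirs <- local %*% t(Q)
    dirs <- fold_axial(dirs)
    diam <- rnorm(n_fibers, diameter_mean_nm, diameter_sd_nm)
    while (any(diam <= 0)) {
      bad <- diam <= 0
      diam[bad] <- rnorm(sum(bad), diameter_mean_nm, diameter_sd_nm)
    }
    cent <- matrix(runif(3 * n_fibers, 0, centroid_box_um), ncol = 3)
    len <- 2 + 6 * runif(n_fibers)
    fiber_set(centroid = cent, direction = dirs, diameter_nm = diam,
              length_um = len, frame = frame_name)
  })
}

#' Generate a synthetic series of one gQOI across transvalvular pressures
#'
#' One record per sample with `value = intercept + slope * TVP + noise`,
#' mirroring a study design with a fixed number of valves per pressure
#' (default 3/5/3 at 10/20/30 mmHg).
#'
#' @param intercept,slope line parameters (slope per mmHg).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_per_tvp named integer vector: samples per pressure.
#' @param seed integer seed.
#' @return A tibble with columns `sample_id`, `tvp_mmHg`, `value`.
#' @export
generate_gqoi_series <- function(intercept, slope, noise_sd,
                                 n_per_tvp = c(`10` = 3, `20` = 5, `30` = 3),
                                 seed = 1L) {
  stopifnot(noise_sd >= 0)
  tvps <- as.numeric(names(n_per_tvp))
  tvp <- rep(tvps, times = n_per_tvp)
  with_seed(seed, {
    value <- intercept + slope * tvp + rnorm(length(tvp), 0, noise_sd)
    tibble(sample_id = sprintf("synth-%02d", seq_along(tvp)),
           tvp_mmHg = tvp, value = value)
  })
}
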