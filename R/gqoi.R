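# Geometric quantities of interest (gQOIs): valve height, leaflet thickness,
# projected perimeter, tilt angle, and their perimeter-normalized forms.

#' Valve height above the annulus plane
#'
#' Mean unsigned distance of the three commissure points to the ANL plane.
#'
#' @param commissures 3 x 3 matrix (um).
#' @param anl the annulus plane.
#' @return Height H (um).
#' @export
valve_height <- function(commissures, anl) {
  mean(abs(plane_distance(anl, commissures)))
}

#' Tilt angle between the annulus and sino-tubular junction planes
#'
#' The dihedral angle `beta = arccos(|n_ANL . n_STJ|)`, insensitive to the
#' sign convention of either normal.
#'
#' @param anl,stj [valve_plane()] objects.
#' @return Angle in degrees, in `[0, 90]`.
#' @export
tilt_angle <- function(anl, stj) {
  acos(min(1, abs(sum(anl$normal * stj$normal)))) * 180 / pi
}

#' Leaflet thickness from the distance transform at belly sites
#'
#' The belly region of each leaflet is its mid-surface restricted to radial
#' coordinate `eta` in `[0.35, 0.65]` and the central circumferential half
#' (`xi` in `[0.25, 0.75]`). At `n_sites_per_leaflet` seeded random belly
#' sites per leaflet, local thickness is twice the Euclidean distance
#' transform value at the mid-surface voxel plus a sub-voxel boundary
#' correction (`edge_correction_vox`, default 0.35 voxels, calibrated on
#' analytic slabs of known thickness at generic tilts). The result is the
#' mean over all sites of all three leaflets.
#'
#' @param volume a [valve_volume()].
#' @param landmarks a [valve_landmarks()] with edge charts (as produced by
#'   [measure_gqoi()] / [build_planes()] with `charts`).
#' @param n_sites_per_leaflet sites per leaflet (default 3, i.e. 9 total).
#' @param seed integer seed for site selection, recorded in the output.
#' @param edge_correction_vox boundary-offset correction in voxels.
#' @return List with `thickness_um` (the mean), `sites` (site coordinates and
#'   local values), and `seed`.
#' @export
leaflet_thickness <- function(volume, landmarks, n_sites_per_leaflet = 3,
                              seed = 17L, edge_correction_vox = 0.35) {
  h <- volume$voxel_size
  d <- dim(volume$grid)
  site_rows <- list()
  for (nm in leaflet_names()) {
    code <- label_code(volume, nm)
    cr <- cpp_crop_label(volume$grid, d, code, 2L)
    ms <- cpp_midsurface(cr$grid, cr$dim, code, 0.5)
    if (ms$max_dist_vox * 2 < 3) {
      stop("resolution error: leaflet '", nm,
           "' is thinner than 3 voxels; thickness cannot be measured")
    }
    sub <- list(grid = cr$grid, voxel_size = h,
                origin = volume$origin + cr$offset * h,
                label_map = volume$label_map)
    class(sub) <- "valve_volume"
    dim(sub$grid) <- cr$dim
    xyz <- voxel_coords(sub, ms$idx)
    par <- parametrize_points(xyz, landmarks, nm, strict = FALSE)
    belly <- which(par$eta >= 0.35 & par$eta <= 0.65 &
                     par$xi >= 0.25 & par$xi <= 0.75)
    if (length(belly) < n_sites_per_leaflet) {
      stop("resolution error: too few belly mid-surface voxels on leaflet '",
           nm, "'")
    }
    picked <- with_seed(seed + match(nm, leaflet_names()),
                        sample(belly, n_sites_per_leaflet))
    site_rows[[nm]] <- data.frame(
      leaflet = nm, x = xyz[picked, 1], y = xyz[picked, 2], z = xyz[picked, 3],
      thickness_um = 2 * ms$dist_vox[picked] * h + edge_correction_vox * h)
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  list(thickness_um = mean(sites$thickness_um), sites = as_tibble(sites),
       seed = as.integer(seed))
}

#' Valve perimeter: projected basal contour length
#'
#' Projects every basal-attachment node orthogonally onto the ANL plane,
#' concatenates the three projected chains into one closed contour (adjacent
#' leaflets share a commissure projection, which is deduplicated), and
#' measures the closed-spline arc length.
#'
#' @param basal_curves named list (anterior/left/right) of `curve3d` basal
#'   attachments, each ordered from its leaflet's first to second commissure.
#' @param anl the annulus plane.
#' @return List with `L_gamma` (um) and `contour` (closed `curve3d`).
#' @export
valve_perimeter <- function(basal_curves, anl) {
  # traversal anterior (P1->P2), right (P2->P3), left (P3->P1)
  ord <- c("anterior", "right", "left")
  chains <- lapply(basal_curves[ord], function(cv) {
    project_onto_plane(anl, cv$nodes)
  })
  tol <- 25  # um; chains must hand over at shared commissure projections
  for (i in 1:3) {
    nxt <- chains[[i %% 3 + 1]]
    gap <- vec_norm(chains[[i]][nrow(chains[[i]]), ] - nxt[1, ])
    if (gap > tol) {
      stop("topology error: projected basal chains do not join into a single ",
           "closed contour (gap ", signif(gap, 3), " um)")
    }
  }
  contour_nodes <- rbind(chains[[1]],
                         chains[[2]][-1, , drop = FALSE],
                         chains[[3]][-1, , drop = FALSE])
  # last node duplicates the first commissure projection
  if (vec_norm(contour_nodes[nrow(contour_nodes), ] - contour_nodes[1, ]) < tol) {
    contour_nodes <- contour_nodes[-nrow(contour_nodes), , drop = FALSE]
  }
  contour <- fit_curve_and_length(contour_nodes, closed = TRUE,
                                  role = "perimeter_contour")
  list(L_gamma = contour$length, contour = contour)
}

#' Assemble a gQOI record with perimeter-normalized values
#'
#' Normalized quantities are the dimensional quantities divided by the valve
#' perimeter length, so `normalized * L_gamma` recovers the dimensional value
#' exactly.
#'
#' @param sample_id sample identifier.
#' @param tvp transvalvular pressure (mmHg).
#' @param L_FE,L_BA named per-leaflet lengths (um), names anterior/left/right.
#' @param H valve height (um).
#' @param w leaflet thickness (um).
#' @param L_gamma valve perimeter (um), > 0.
#' @param beta_deg tilt angle (degrees).
#' @return An object of class `gqoi_record`.
#' @export
assemble_gqoi <- function(sample_id, tvp, L_FE, L_BA, H, w, L_gamma, beta_deg) {
  if (!is.finite(L_gamma) || L_gamma <= 0) {
    stop("normalization error: valve perimeter length must be positive")
  }
  L_FE <- unlist(L_FE)[leaflet_names()]
  L_BA <- unlist(L_BA)[leaflet_names()]
  stopifnot(all(L_FE > 0), all(L_BA > 0), H > 0, w > 0,
            beta_deg >= 0, beta_deg < 90)
  structure(list(sample_id = sample_id, tvp_mmHg = tvp,
                 L_FE = L_FE, L_BA = L_BA, H = H, w = w,
                 L_gamma = L_gamma, beta_deg = beta_deg,
                 L_FE_bar = L_FE / L_gamma, L_BA_bar = L_BA / L_gamma,
                 H_bar = H / L_gamma, w_bar = w / L_gamma),
            class = "gqoi_record")
}

#' @export
print.gqoi_record <- function(x, ...) {
  cat(sprintf("<gqoi_record> %s @ %g mmHg\n", x$sample_id, x$tvp_mmHg))
  cat(sprintf("  L_gamma %.0f um | H %.0f um | w %.1f um | beta %.1f deg\n",
              x$L_gamma, x$H, x$w, x$beta_deg))
  for (nm in leaflet_names()) {
    cat(sprintf("  %-8s L_FE %.0f um (%.2f) | L_BA %.0f um (%.2f)\n", nm,
                x$L_FE[[nm]], x$L_FE_bar[[nm]], x$L_BA[[nm]], x$L_BA_bar[[nm]]))
  }
  invisible(x)
}

#' Flatten gQOI records into a tidy per-leaflet table
#'
#' @param records a `gqoi_record` or list of them.
#' @return Tibble with one row per record and leaflet; valve-level quantities
#'   are repeated across leaflet rows.
#' @export
gqoi_to_tibble <- function(records) {
  if (inherits(records, "gqoi_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    tibble(sample_id = r$sample_id, tvp_mmHg = r$tvp_mmHg,
           leaflet = leaflet_names(),
           L_FE_um = as.numeric(r$L_FE), L_BA_um = as.numeric(r$L_BA),
           H_um = r$H, w_um = r$w, L_gamma_um = r$L_gamma,
           beta_deg = r$beta_deg,
           L_FE_bar = as.numeric(r$L_FE_bar), L_BA_bar = as.numeric(r$L_BA_bar),
           H_bar = r$H_bar, w_bar = r$w_bar)
  })
  do.call(rbind, rows)
}

#' Measure all gQOIs of a labeled valve volume
#'
#' End-to-end landmark detection and measurement: commissures, edge chains,
#' spline curves, ANL/STJ planes, valve height, thickness, perimeter and
#' tilt, assembled into a [assemble_gqoi()] record.
#'
#' @param volume a [valve_volume()].
#' @param sample_id,tvp identifiers stored in the record.
#' @param seed seed for thickness site sampling.
#' @param spacing edge-node decimation spacing (um).
#' @param smoothing edge spline smoothing (0 = interpolating).
#' @param thickness if `FALSE`, skip the thickness measurement (useful at
#'   resolutions too coarse to resolve the leaflet interior); `w` is then NA.
#' @return List with `gqoi`, `landmarks`, `basal_curves`, `free_curves`,
#'   `perimeter`, and `axis`.
#' @export
measure_gqoi <- function(volume, sample_id = "sample", tvp = NA_real_,
                         seed = 17L, spacing = 10, smoothing = 0,
                         thickness = TRUE) {
  comm <- find_commissures(volume)
  edges <- lapply(leaflet_names(), function(nm) {
    extract_leaflet_edges(volume, nm, comm, spacing = spacing)
  })
  names(edges) <- leaflet_names()
  basal_curves <- lapply(edges, function(e) {
    fit_curve_and_length(e$basal_attachment, smoothing = smoothing,
                         role = "basal_attachment")
  })
  free_curves <- lapply(edges, function(e) {
    fit_curve_and_length(e$free_edge, smoothing = smoothing,
                         role = "free_edge")
  })
  landmarks <- build_planes(comm, basal_curves, free_curves, charts = edges)
  H <- valve_height(comm, landmarks$anl)
  perim <- valve_perimeter(basal_curves, landmarks$anl)
  beta <- tilt_angle(landmarks$anl, landmarks$stj)
  w <- NA_real_
  thick <- NULL
  if (thickness) {
    thick <- leaflet_thickness(volume, landmarks, seed = seed)
    w <- thick$thickness_um
  }
  gq <- assemble_gqoi(sample_id, tvp,
                      L_FE = vapply(free_curves, function(cv) cv$length, numeric(1)),
                      L_BA = vapply(basal_curves, function(cv) cv$length, numeric(1)),
                      H = H, w = if (is.na(w)) 1e-6 else w,
                      L_gamma = perim$L_gamma, beta_deg = beta)
  if (is.na(w)) {
    gq$w <- NA_real_; gq$w_bar <- NA_real_
  }
  list(gqoi = gq, landmarks = landmarks, basal_curves = basal_curves,
       free_curves = free_curves, perimeter = perim, thickness = thick,
       axis = valve_axis(volume))
}
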