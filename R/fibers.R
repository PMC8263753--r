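# Collagen fiber sets: frame transforms between the local (SEM) and valve
# (uCT) coordinate systems, and orientation / diameter statistics. Fibers are
# axial quantities (v and -v are the same fiber); the stored representative
# direction lies in the z >= 0 hemisphere.

# canonical axial representative: z > 0; ties (|z| below tolerance) broken
# by y >= 0, then x >= 0
fold_axial <- function(dirs, tol = 1e-12) {
  dirs <- rbind3(dirs)
  z0 <- abs(dirs[, 3]) <= tol
  flip <- (!z0 & dirs[, 3] < 0) |
    (z0 & (dirs[, 2] < -tol | (abs(dirs[, 2]) <= tol & dirs[, 1] < 0)))
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  dirs
}

#' Construct a fiber set
#'
#' @param centroid n x 3 matrix of fiber centroids (um).
#' @param direction n x 3 matrix of unit fiber axes; folded to the z >= 0
#'   hemisphere representative.
#' @param diameter_nm fiber diameters (nm), > 0.
#' @param length_um fiber lengths (um).
#' @param frame non-empty coordinate frame name.
#' @return An object of class `fiber_set`.
#' @export
fiber_set <- function(centroid, direction, diameter_nm, length_um, frame) {
  centroid <- rbind3(centroid); direction <- rbind3(direction)
  stopifnot(nrow(centroid) == nrow(direction),
            length(diameter_nm) == nrow(centroid),
            length(length_um) == nrow(centroid),
            is.character(frame), nzchar(frame))
  nr <- sqrt(rowSums(direction^2))
  if (any(abs(nr - 1) > 1e-6)) direction <- direction / nr
  if (any(diameter_nm <= 0)) stop("fiber diameters must be > 0")
  structure(list(centroid = centroid, direction = fold_axial(direction),
                 diameter_nm = as.numeric(diameter_nm),
                 length_um = as.numeric(length_um), frame = frame),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set> %d fibers in frame '%s'\n", nrow(x$direction),
              x$frame))
  cat(sprintf("  diameter (nm): median %.1f [%.1f, %.1f]\n",
              stats::median(x$diameter_nm), min(x$diameter_nm),
              max(x$diameter_nm)))
  invisible(x)
}

#' Construct a rigid transform between named frames
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation 3-vector (um).
#' @param from_frame,to_frame frame names.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0),
                            from_frame = "sem", to_frame = "uct") {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 from_frame = from_frame, to_frame = to_frame),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse transform (frames swapped).
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation),
                  from_frame = transform$to_frame,
                  to_frame = transform$from_frame)
}

#' Apply a rigid transform to a fiber set
#'
#' Centroids are mapped affinely (`R x + t`); directions by the rotation
#' only, then re-folded to the z >= 0 hemisphere representative. Diameters
#' and lengths are unchanged.
#'
#' @param fibers a [fiber_set()] whose frame matches `transform$from_frame`.
#' @param transform a [rigid_transform()].
#' @return The transformed [fiber_set()] in `transform$to_frame`.
#' @export
apply_transform <- function(fibers, transform) {
  if (!identical(fibers$frame, transform$from_frame)) {
    stop("frame error: fiber set is in frame '", fibers$frame,
         "' but the transform maps from '", transform$from_frame, "'")
  }
  cent <- sweep(fibers$centroid %*% t(transform$rotation), 2,
                transform$translation, `+`)
  dirs <- fibers$direction %*% t(transform$rotation)
  fiber_set(cent, dirs, fibers$diameter_nm, fibers$length_um,
            frame = transform$to_frame)
}

#' Spherical angles of a fiber axis
#'
#' Under the axial convention, `theta = arccos(|v_z|)` is the deviation from
#' the z-axis in `[0, 90]` degrees and `phi = atan2(v_y, v_x) mod 180` is the
#' azimuth in the xy-plane. At the pole (`theta = 0`) the azimuth is
#' undefined and reported as 0.
#'
#' @param direction unit 3-vector or n x 3 matrix.
#' @return Matrix with columns `theta_deg`, `phi_deg`.
#' @export
spherical_angles <- function(direction) {
  v <- rbind3(direction)
  nr <- sqrt(rowSums(v^2))
  if (any(nr < 1e-12)) stop("domain error: zero fiber direction vector")
  v <- v / nr
  theta <- acos(pmin(1, abs(v[, 3]))) * 180 / pi
  phi <- (atan2(v[, 2], v[, 1]) * 180 / pi) %% 180
  phi[theta < 1e-9] <- 0
  cbind(theta_deg = theta, phi_deg = phi)
}

#' Unit vector from spherical angles
#' @param theta_deg deviation from the z-axis (degrees).
#' @param phi_deg azimuth in the xy-plane from the x-axis (degrees).
#' @return Unit 3-vector.
#' @export
spherical_to_cartesian <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Orientation summary of a fiber set
#'
#' Histograms of the spherical angles, the mean fiber axis as the principal
#' eigenvector of the orientation second-moment tensor `sum v v^T / N` (the
#' vector mean vanishes for axial data), and the angle between the mean axis
#' and a reference direction.
#'
#' @param fibers a [fiber_set()].
#' @param reference_direction unit 3-vector (e.g. the circumferential
#'   direction from [surface_tangent_xi()]).
#' @param n_bins number of theta bins over `[0, 90]` degrees (phi uses
#'   `2 * n_bins` over `[0, 180)`).
#' @return An object of class `orientation_summary` with `theta_hist`,
#'   `phi_hist` (tibbles of bin edges and counts), `mean_axis`,
#'   `alignment_angle_deg`, `second_moment_eigenvalues`, `n_fibers`.
#' @export
orientation_summary <- function(fibers, reference_direction = c(1, 0, 0),
                                n_bins = 18) {
  v <- fibers$direction
  N <- nrow(v)
  stopifnot(N >= 1)
  ang <- spherical_angles(v)
  th_edges <- seq(0, 90, length.out = n_bins + 1)
  ph_edges <- seq(0, 180, length.out = 2 * n_bins + 1)
  th_cut <- findInterval(ang[, 1], th_edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
  ph_cut <- findInterval(ang[, 2], ph_edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
  M <- crossprod(v) / N
  ev <- eigen(M, symmetric = TRUE)
  mean_axis <- drop(fold_axial(ev$vectors[, 1]))
  ref <- unitize(reference_direction)
  align <- acos(min(1, abs(sum(mean_axis * ref)))) * 180 / pi
  structure(list(
    theta_hist = tibble(lower_deg = th_edges[-length(th_edges)],
                        upper_deg = th_edges[-1],
                        count = tabulate(th_cut, nbins = n_bins)),
    phi_hist = tibble(lower_deg = ph_edges[-length(ph_edges)],
                      upper_deg = ph_edges[-1],
                      count = tabulate(ph_cut, nbins = 2 * n_bins)),
    mean_axis = mean_axis, alignment_angle_deg = align,
    second_moment_eigenvalues = ev$values, n_fibers = N),
    class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf("<orientation_summary> %d fibers\n", x$n_fibers))
  cat(sprintf("  mean axis: (%.3f, %.3f, %.3f); alignment to reference %.2f deg\n",
              x$mean_axis[1], x$mean_axis[2], x$mean_axis[3],
              x$alignment_angle_deg))
  invisible(x)
}

#' Fiber diameter histogram and in-range fraction
#'
#' @param fibers a [fiber_set()].
#' @param bin_width_nm histogram bin width (nm), > 0.
#' @param range_nm diameter band of interest (default the 80-100 nm band
#'   typical of valve collagen fibrils).
#' @return List with `hist` (tibble of bin edges and counts) and
#'   `fraction_in_range`.
#' @export
diameter_summary <- function(fibers, bin_width_nm = 5, range_nm = c(80, 100)) {
  if (!is.finite(bin_width_nm) || bin_width_nm <= 0) {
    stop("parameter error: bin width must be > 0")
  }
  dd <- fibers$diameter_nm
  lo <- floor(min(dd) / bin_width_nm) * bin_width_nm
  hi <- ceiling(max(dd) / bin_width_nm) * bin_width_nm
  if (hi <= lo) hi <- lo + bin_width_nm
  edges <- seq(lo, hi, by = bin_width_nm)
  cut <- findInterval(dd, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(hist = tibble(lower_nm = edges[-length(edges)], upper_nm = edges[-1],
                     count = tabulate(cut, nbins = length(edges) - 1)),
       fraction_in_range = mean(dd >= range_nm[1] & dd <= range_nm[2]))
}

#' Write a fiber set to CSV
#'
#' Columns: `fiber_id, cx_um, cy_um, cz_um, dx, dy, dz, diameter_nm,
#' length_um, frame`.
#'
#' @param fibers a [fiber_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_csv <- function(fibers, path) {
  df <- data.frame(fiber_id = seq_len(nrow(fibers$direction)),
                   cx_um = fibers$centroid[, 1], cy_um = fibers$centroid[, 2],
                   cz_um = fibers$centroid[, 3],
                   dx = fibers$direction[, 1], dy = fibers$direction[, 2],
                   dz = fibers$direction[, 3],
                   diameter_nm = fibers$diameter_nm,
                   length_um = fibers$length_um, frame = fibers$frame)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a fiber set from CSV written by [write_fiber_csv()]
#' @param path CSV path.
#' @return A [fiber_set()].
#' @export
read_fiber_csv <- function(path) {
  df <- read.csv(path)
  fiber_set(cbind(df$cx_um, df$cy_um, df$cz_um),
            cbind(df$dx, df$dy, df$dz),
            df$diameter_nm, df$length_um, frame = unique(df$frame)[1])
}

#' Write a rigid transform as JSON (4 x 4 row-major homogeneous matrix)
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  M <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(from = transform$from_frame,
                            to = transform$to_frame,
                            matrix = as.numeric(t(M))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON written by [write_transform_json()]
#' @param path JSON path.
#' @return A [rigid_transform()].
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- matrix(obj$matrix, 4, 4, byrow = TRUE)
  rigid_transform(M[1:3, 1:3], M[1:3, 4], from_frame = obj$from,
                  to_frame = obj$to)
}
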