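# Labeled valve volumes: raw (uint8) voxel arrays with physical metadata.
# Label convention: 0 background, 1 arterial wall, 2 anterior leaflet,
# 3 left leaflet, 4 right leaflet.

#' Default label map for a tri-leaflet valve segmentation
#' @return Named integer vector mapping structure names to label codes.
#' @export
valve_labels <- function() {
  c(wall = 1L, anterior = 2L, left = 3L, right = 4L)
}

leaflet_names <- function() c("anterior", "left", "right")

#' Construct a labeled valve volume
#'
#' @param grid raw or integer 3D array of label codes (see [valve_labels()]).
#' @param voxel_size isotropic voxel edge length (um), > 0.
#' @param origin physical coordinate (um) of the grid corner; voxel `(i,j,k)`
#'   (1-based) is centered at `origin + (c(i,j,k) - 0.5) * voxel_size`.
#' @param label_map named integer vector; defaults to [valve_labels()].
#' @return An object of class `valve_volume`.
#' @export
valve_volume <- function(grid, voxel_size, origin = c(0, 0, 0),
                         label_map = valve_labels()) {
  stopifnot(length(dim(grid)) == 3, is.numeric(voxel_size), voxel_size > 0,
            length(origin) == 3)
  if (!is.raw(grid)) {
    dm <- dim(grid)
    grid <- as.raw(grid)
    dim(grid) <- dm
  }
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), label_map = label_map),
            class = "valve_volume")
}

#' @export
print.valve_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<valve_volume> %d x %d x %d voxels @ %.3g um\n", d[1], d[2], d[3],
              x$voxel_size))
  cat("  origin (um):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  for (nm in names(x$label_map)) {
    cat(sprintf("  label %d (%s): %d voxels\n", x$label_map[[nm]], nm,
                length(cpp_which_label(x$grid, d, x$label_map[[nm]]))))
  }
  invisible(x)
}

label_code <- function(volume, structure) {
  code <- volume$label_map[[structure]]
  if (is.null(code)) stop("unknown structure label: ", structure)
  as.integer(code)
}

# world coordinates (n x 3) of 1-based linear voxel indices
voxel_coords <- function(volume, idx) {
  d <- dim(volume$grid)
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(volume$origin[1] + (i + 0.5) * volume$voxel_size,
        volume$origin[2] + (j + 0.5) * volume$voxel_size,
        volume$origin[3] + (k + 0.5) * volume$voxel_size)
}

#' Write a labeled valve volume as multi-page TIFF with a JSON sidecar
#'
#' Pages are z-slices; labels are stored as 8-bit grayscale codes. Physical
#' metadata (voxel size in um, origin, label map) is written to
#' `<path>.json` because baseline TIFF has no standard voxel-size field.
#'
#' @param volume a [valve_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_valve_tiff <- function(volume, path) {
  d <- dim(volume$grid)
  ivals <- as.integer(volume$grid)
  pages <- lapply(seq_len(d[3]), function(k) {
    sl <- matrix(ivals[((k - 1) * d[1] * d[2] + 1):(k * d[1] * d[2])], d[1], d[2])
    # tiff writes row-major images; store x along columns, y along rows
    t(sl) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- list(voxel_size_um = volume$voxel_size, origin_um = volume$origin,
               label_map = as.list(volume$label_map),
               axis_order = "xyz", pages = "z-slices")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a labeled valve volume written by [write_valve_tiff()]
#'
#' Refuses to guess physical metadata: the JSON sidecar must be present.
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return A [valve_volume()].
#' @export
read_valve_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing voxel-size sidecar ", sidecar,
         "; refusing to assume a default voxel size")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  grid <- as.raw(unlist(lapply(pages, function(m) as.integer(t(m)))))
  dim(grid) <- d
  valve_volume(grid, meta$voxel_size_um, meta$origin_um,
               label_map = unlist(meta$label_map))
}

#' Write a leaflet surface mesh as binary little-endian PLY
#'
#' Vertices carry a `label` property with the leaflet's label code.
#'
#' @param mesh list with `vertices` (n x 3 um) and `faces` (m x 3, 1-based).
#' @param label integer label code stored per vertex.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_leaflet_ply <- function(mesh, label, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           "property uchar label",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con, sep = "\n")
  for (i in seq_len(nv)) {
    writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(label), con)
  }
  for (i in seq_len(nf)) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
  invisible(path)
}
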