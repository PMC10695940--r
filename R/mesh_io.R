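# Mesh input/output: STL (binary and ASCII) with a JSON sidecar carrying the
# landmarks and foramen loop, plus a legacy-VTK writer for displacement
# fields.  Units are millimetres throughout.

#' Write a mesh or skull surface to STL
#'
#' Binary little-endian STL.  For a `skull_surface`, a JSON sidecar
#' (`<path>.json`) stores the landmarks (mm), the ordered foramen loop and
#' the shell thickness so that [read_skull_stl()] can round-trip the object.
#'
#' @param x a `skull_surface`, or a list with `vertices` and `faces`.
#' @param path output path (`.stl`).
#' @param ascii write ASCII STL instead of binary.
#' @param sidecar write the JSON sidecar (default for skull surfaces).
#' @return `path`, invisibly.
#' @export
write_skull_stl <- function(x, path, ascii = FALSE,
                            sidecar = inherits(x, "skull_surface")) {
  v <- x$vertices
  f <- x$faces
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines("solid vaultsim", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", v1[i, 1], v1[i, 2], v1[i, 3]),
                   sprintf("      vertex %.9g %.9g %.9g", v2[i, 1], v2[i, 2], v2[i, 3]),
                   sprintf("      vertex %.9g %.9g %.9g", v3[i, 1], v3[i, 2], v3[i, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid vaultsim", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    header <- charToRaw(formatC("vaultsim binary STL", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], v1[i, ], v2[i, ], v3[i, ])), con,
               size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  if (sidecar) {
    side <- list(landmarks = lapply(x$landmarks, as.numeric),
                 foramen_loop = as.integer(x$foramen_loop),
                 thickness = x$thickness, units = "mm")
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  nums
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(0, 3 * nf, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    tri[3 * (i - 1) + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    invisible(readBin(con, "raw", 2))
  }
  tri
}

#' Read a skull surface from STL (+ JSON sidecar)
#'
#' Accepts binary or ASCII STL; vertices are welded on exact coordinates.
#' When `<path>.json` exists, landmarks, the foramen loop and the thickness
#' are restored from it; otherwise they must be supplied before the surface
#' can enter the pipeline.
#'
#' @param path the `.stl` file.
#' @return a `skull_surface` (landmarks and foramen loop may be `NULL`
#'   without a sidecar).
#' @export
read_skull_stl <- function(path) {
  head4 <- readChar(path, 5, useBytes = TRUE)
  tri <- if (identical(tolower(head4), "solid") &&
             any(grepl("facet", readLines(path, n = 3, warn = FALSE)))) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
  key <- apply(tri, 1, function(p) paste(format(p, digits = 12), collapse = " "))
  idx <- match(key, unique(key))
  vertices <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  side_path <- paste0(path, ".json")
  landmarks <- NULL; foramen <- NULL; thickness <- NA_real_
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    landmarks <- lapply(side$landmarks, as.numeric)
    foramen <- as.integer(side$foramen_loop)
    thickness <- as.numeric(side$thickness)
  }
  structure(list(vertices = vertices, faces = faces, landmarks = landmarks,
                 foramen_loop = foramen, thickness = thickness, spec = NULL),
            class = "skull_surface")
}

#' Write a deformed mesh with point data as legacy VTK
#'
#' @param mesh list with `vertices` and `faces`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-vertex vectors or 3-column matrices
#'   (e.g. displacements).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0", "vaultsim output", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(v))), con)
  writeLines(apply(v, 1, function(p) paste(format(p, digits = 9), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  writeLines(apply(f - 1L, 1, function(p) paste(c(3L, p), collapse = " ")), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      if (is.matrix(d) && ncol(d) == 3) {
        writeLines(sprintf("VECTORS %s float", nm), con)
        writeLines(apply(d, 1, function(p) paste(format(p, digits = 9), collapse = " ")), con)
      } else {
        writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(d), digits = 9), con)
      }
    }
  }
  invisible(path)
}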