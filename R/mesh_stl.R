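# Triangle surface meshes and STL input/output.
# The exported mesh is the exact boundary of the voxel occupancy grid
# (axis-aligned quads split into triangles): watertight and consistent
# with the occupancy by construction.

#' Extract the surface mesh of a scaffold model
#'
#' @param model A `scaffold_model`.
#' @return A `surface_mesh`: list with `vertices` (n x 3 mm) and `faces`
#'   (m x 3, 1-based indices, outward orientation).
#' @export
surface_mesh <- function(model) {
  stopifnot(inherits(model, "scaffold_model"))
  m <- .cpp_voxel_mesh(model$occupancy, model$dims, model$voxel, c(0, 0, 0))
  structure(list(vertices = m$vertices, faces = m$faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Mesh volume by signed tetrahedron sum
#' @param mesh A `surface_mesh`.
#' @export
mesh_volume <- function(mesh) {
  .cpp_mesh_measure(mesh$vertices, mesh$faces)$volume
}

#' Total mesh surface area
#' @param mesh A `surface_mesh`.
#' @export
mesh_area <- function(mesh) {
  .cpp_mesh_measure(mesh$vertices, mesh$faces)$area
}

#' Is a mesh watertight?
#'
#' TRUE when every directed edge is matched by exactly one opposite edge
#' (closed, consistently oriented surface).
#' @param mesh A `surface_mesh`.
#' @export
is_watertight <- function(mesh) {
  .cpp_mesh_watertight(mesh$faces, nrow(mesh$vertices))
}

#' Write a mesh as STL
#'
#' Binary STL by default; `ascii = TRUE` writes the ASCII dialect.
#' Coordinates are written in single precision (binary) as the format
#' prescribes.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param ascii Write ASCII STL instead of binary.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  V <- mesh$vertices; F <- mesh$faces
  n <- nrow(F)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid scaffseed", con)
    for (t in seq_len(n)) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[t,1], nrm[t,2], nrm[t,3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", a[t,1], a[t,2], a[t,3]),
        sprintf("      vertex %.9g %.9g %.9g", b[t,1], b[t,2], b[t,3]),
        sprintf("      vertex %.9g %.9g %.9g", cc[t,1], cc[t,2], cc[t,3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid scaffseed", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("scaffseed binary STL", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 (12 floats) + attribute short
    dat <- t(cbind(nrm, a, b, cc))
    for (t in seq_len(n)) {
      writeBin(as.numeric(dat[, t]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Vertices are deduplicated by exact coordinate match so shared edges are
#' recovered; malformed files raise an error reporting the byte offset at
#' which parsing failed.
#'
#' @param path STL file path.
#' @return A `surface_mesh`.
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("malformed STL at byte 0: file too short")
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  is_ascii <- !any(head > as.raw(127)) && !any(head == as.raw(0)) && {
    txt <- rawToChar(head)
    grepl("^\\s*solid", txt) && grepl("facet", txt)
  }
  tri <- if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(path, sz)
  # deduplicate vertices
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uid <- !duplicated(key)
  verts <- tri[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  structure(list(vertices = unname(verts), faces = faces),
            class = "surface_mesh")
}

.read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(n) || n < 0 || 84 + n * 50 > sz) {
    stop(sprintf("malformed STL at byte 80: facet count %s inconsistent with file size %d",
                 n, sz))
  }
  tri <- matrix(NA_real_, nrow = 3 * n, ncol = 3)
  for (t in seq_len(n)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    if (length(vals) < 12) {
      stop(sprintf("malformed STL at byte %d: truncated facet %d",
                   84 + (t - 1) * 50, t))
    }
    readBin(con, "raw", n = 2)
    tri[3 * t - 2, ] <- vals[4:6]
    tri[3 * t - 1, ] <- vals[7:9]
    tri[3 * t, ] <- vals[10:12]
  }
  tri
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    stop(sprintf("malformed STL at byte %d: vertex count %d not a multiple of 3",
                 sum(nchar(lines)) + length(lines), length(vl)))
  }
  parts <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 4)
  if (length(bad)) {
    off <- sum(nchar(lines[seq_len(grep("^\\s*vertex", lines)[bad[1]] - 1)]))
    stop(sprintf("malformed STL at byte %d: unparseable vertex line", off))
  }
  tri <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(tri)) stop("malformed STL: non-numeric vertex coordinates")
  tri
}

#' Export a scaffold model's surface mesh to STL
#' @param model A `scaffold_model`.
#' @param path Output path.
#' @param ascii Write the ASCII dialect (default binary).
#' @export
export_mesh <- function(model, path, ascii = FALSE) {
  write_stl(surface_mesh(model), path, ascii = ascii)
}

#' Import an STL surface into a scaffold model
#'
#' The mesh is voxelized by parity ray casting onto a grid covering its
#' bounding extent (assumed to lie in the positive octant, as exported
#' meshes do).
#'
#' @param path STL file path.
#' @param voxel Voxel edge length in mm.
#' @return A `scaffold_model` with `design = "imported"` (no lattice
#'   parameterisation; metrics come from the mesh itself).
#' @export
import_mesh <- function(path, voxel = 0.025) {
  mesh <- read_stl(path)
  bbox <- apply(mesh$vertices, 2, max)
  occ <- .cpp_voxelize_mesh(mesh$vertices, mesh$faces, bbox, voxel)
  dims <- as.integer(round(bbox / voxel))
  meas <- .cpp_mesh_measure(mesh$vertices, mesh$faces)
  structure(list(design = "imported", spec = NULL, params = NULL,
                 voxel = voxel, dims = dims, occupancy = occ,
                 bounding_box = bbox, V = meas$volume, S = meas$area,
                 n_solid = sum(as.integer(occ)), mesh = mesh),
            class = "scaffold_model")
}
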