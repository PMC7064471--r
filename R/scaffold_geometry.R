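# Parametric lattice scaffold construction and geometric metrics.
#
# Two open-cell designs are supported:
#   * "cubic": a cross-link lattice of three orthogonal families of
#     cylindrical struts (0.5 mm diameter) leaving square windows of
#     1000 um side (pitch = pore + strut = 1.5 mm).
#   * "truncated_octahedron": cylindrical struts along the 36 edges of the
#     space-filling truncated octahedron honeycomb (BCC Voronoi cells),
#     hexagonal window side 240 um.
# All scaffold-scale lengths are millimetres; voxel default 25 um.

#' Unit-cell specification for a lattice scaffold
#'
#' Collects the parameters that define one lattice unit cell and derives the
#' cell pitch.  For the cubic cross-link design the pitch is the pore side
#' plus one strut diameter.  For the truncated octahedron (TO) design the
#' hexagonal face edge is the pore side plus the in-plane wall offset on
#' both sides (`a = s + 2 w / sqrt(3)`), and the pitch (width across the
#' square faces of the cell) is `2 sqrt(2) a`.
#'
#' @param design `"cubic"` or `"truncated_octahedron"`.
#' @param strut_diameter Strut diameter in mm.  Default 0.5 for the cubic
#'   design.  For the TO design the nominal metrics pin down the structure
#'   volume rather than the strut size; the default 0.176 mm reproduces the
#'   nominal structure volume of the 7.9 x 7.9 x 6 mm scaffold.
#' @param pore_side Open window side in micrometres (cubic: square window,
#'   default 1000; TO: hexagonal window, default 240).
#' @param wall_offset In-plane distance from the window side to the cell
#'   face edge, mm (TO only, default 0.1).
#' @return An object of class `unit_cell_spec`.
#' @examples
#' unit_cell_spec("cubic")
#' unit_cell_spec("truncated_octahedron")
#' @export
unit_cell_spec <- function(design = c("cubic", "truncated_octahedron"),
                           strut_diameter = NULL, pore_side = NULL,
                           wall_offset = NULL) {
  design <- match.arg(design)
  if (design == "cubic") {
    if (is.null(strut_diameter)) strut_diameter <- 0.5
    if (is.null(pore_side)) pore_side <- 1000
    if (!is.null(wall_offset)) {
      stop("wall_offset applies to the truncated octahedron design only")
    }
    wall_offset <- NA_real_
  } else {
    if (is.null(strut_diameter)) strut_diameter <- 0.176
    if (is.null(pore_side)) pore_side <- 240
    if (is.null(wall_offset)) wall_offset <- 0.1
    if (wall_offset <= 0) stop("invalid unit-cell spec: wall_offset must be > 0")
  }
  if (strut_diameter <= 0 || pore_side <= 0) {
    stop("invalid unit-cell spec: all lengths must be > 0")
  }
  pore_mm <- pore_side / 1000
  if (design == "cubic") {
    pitch <- pore_mm + strut_diameter
    pore_shape <- "square"
  } else {
    edge <- pore_mm + 2 * wall_offset / sqrt(3)
    if (edge <= pore_mm) stop("invalid unit-cell spec: degenerate hole")
    pitch <- 2 * sqrt(2) * edge
    pore_shape <- "hexagon"
  }
  structure(list(design = design, strut_diameter = strut_diameter,
                 pore_side = pore_side, wall_offset = wall_offset,
                 pitch = pitch, pore_shape = pore_shape),
            class = "unit_cell_spec")
}

#' @export
print.unit_cell_spec <- function(x, ...) {
  cat("Lattice unit cell:", x$design, "\n")
  cat(sprintf("  strut diameter: %.3f mm\n", x$strut_diameter))
  cat(sprintf("  pore side: %g um (%s)\n", x$pore_side, x$pore_shape))
  if (!is.na(x$wall_offset))
    cat(sprintf("  wall offset: %.3f mm\n", x$wall_offset))
  cat(sprintf("  pitch: %.4f mm\n", x$pitch))
  invisible(x)
}

# Internal: parameter list consumed by the C++ SDF kernels.
# `offset` aligns the lattice inside the bounding box; the scaffold-scale
# defaults (lateral 1.25 mm, vertical 0 for cubic; box-centred for TO) are
# the alignment calibrated against the nominal scaffold metrics.
.sdf_params <- function(spec, bbox, offset = NULL, offset_z = NULL,
                        center = NULL) {
  if (spec$design == "cubic") {
    if (is.null(offset)) offset <- 1.25
    if (is.null(offset_z)) offset_z <- 0
    list(design_code = 0L, pitch = spec$pitch,
         radius = spec$strut_diameter / 2,
         offset = offset, offset_z = offset_z, bbox = bbox)
  } else {
    if (is.null(center)) center <- bbox / 2
    list(design_code = 1L, pitch = spec$pitch,
         radius = spec$strut_diameter / 2,
         center = center, bbox = bbox)
  }
}

.new_scaffold_model <- function(spec, params, voxel, include_clip = TRUE) {
  m <- .cpp_voxelize_metrics(params, voxel, include_clip, TRUE)
  structure(list(design = if (is.null(spec)) "imported" else spec$design,
                 spec = spec, params = params, voxel = voxel,
                 dims = m$dims, occupancy = m$occupancy,
                 bounding_box = params$bbox,
                 V = m$V, S = m$S, n_solid = m$n_solid),
            class = "scaffold_model")
}

#' Build one cubic cross-link unit cell
#'
#' The unit cell is one pitch cube with quarter-struts along its twelve
#' edges, so the open square window through each face has side `pore_side`.
#'
#' @param spec A [unit_cell_spec()] with `design = "cubic"`.
#' @param voxel Voxel edge length in mm (default 0.025).
#' @return A `scaffold_model`: voxel occupancy grid plus the signed distance
#'   parameterisation it was sampled from.
#' @export
build_cubic_cell <- function(spec = unit_cell_spec("cubic"), voxel = 0.025) {
  stopifnot(inherits(spec, "unit_cell_spec"))
  if (spec$design != "cubic") stop("spec is not a cubic design")
  p <- spec$pitch
  params <- .sdf_params(spec, bbox = c(p, p, p), offset = 0, offset_z = 0)
  .new_scaffold_model(spec, params, voxel)
}

#' Build one truncated-octahedron unit cell
#'
#' One periodic cube of the TO honeycomb with a full cell at the cube
#' centre (and the eight corner cells it shares struts with).
#'
#' @inheritParams build_cubic_cell
#' @param spec A [unit_cell_spec()] with `design = "truncated_octahedron"`.
#' @export
build_to_cell <- function(spec = unit_cell_spec("truncated_octahedron"),
                          voxel = 0.025) {
  stopifnot(inherits(spec, "unit_cell_spec"))
  if (spec$design != "truncated_octahedron")
    stop("spec is not a truncated octahedron design")
  p <- spec$pitch
  params <- .sdf_params(spec, bbox = c(p, p, p), center = c(p, p, p) / 2)
  .new_scaffold_model(spec, params, voxel)
}

#' Tile a unit cell periodically into a scaffold bounding box
#'
#' The periodic lattice the unit cell belongs to is evaluated over the
#' requested bounding box and clipped to it; struts crossing cell borders
#' merge by construction (boolean union of the signed distance fields).
#'
#' @param cell A `scaffold_model` produced by [build_cubic_cell()] or
#'   [build_to_cell()].
#' @param bounding_box Numeric length-3, mm.  Default `c(7.9, 7.9, 6)`.
#' @param voxel Voxel edge length in mm; defaults to the cell's.
#' @param offset,offset_z Lateral/vertical lattice alignment for the cubic
#'   design, mm (defaults: the calibrated scaffold alignment).
#' @param center Lattice origin for the TO design, mm (default: box
#'   centre).
#' @return A `scaffold_model` for the full scaffold.
#' @export
tile_scaffold <- function(cell, bounding_box = c(7.9, 7.9, 6),
                          voxel = cell$voxel, offset = NULL,
                          offset_z = NULL, center = NULL) {
  stopifnot(inherits(cell, "scaffold_model"))
  if (is.null(cell$spec)) stop("imported models carry no lattice to tile")
  if (any(bounding_box <= 0) || any(bounding_box < cell$spec$pitch / 2))
    stop("bounding box has empty intersection with the lattice")
  params <- .sdf_params(cell$spec, bbox = as.numeric(bounding_box),
                        offset = offset, offset_z = offset_z,
                        center = center)
  .new_scaffold_model(cell$spec, params, voxel)
}

#' Build a full scaffold for a named design
#'
#' Convenience wrapper: unit-cell spec, then periodic tiling into the
#' bounding box.
#'
#' @param design `"cubic"` or `"truncated_octahedron"`.
#' @param bounding_box Numeric length-3, mm (default `c(7.9, 7.9, 6)`).
#' @param voxel Voxel edge, mm.
#' @param ... Passed to [unit_cell_spec()].
#' @export
build_scaffold <- function(design = c("cubic", "truncated_octahedron"),
                           bounding_box = c(7.9, 7.9, 6), voxel = 0.025,
                           ...) {
  design <- match.arg(design)
  spec <- unit_cell_spec(design, ...)
  cell <- if (design == "cubic") build_cubic_cell(spec, voxel)
          else build_to_cell(spec, voxel)
  tile_scaffold(cell, bounding_box, voxel)
}

#' @export
print.scaffold_model <- function(x, ...) {
  cat("Scaffold model:", x$design, "\n")
  cat(sprintf("  bounding box: %.2f x %.2f x %.2f mm\n",
              x$bounding_box[1], x$bounding_box[2], x$bounding_box[3]))
  cat(sprintf("  voxel: %g mm, grid %d x %d x %d (%d solid voxels)\n",
              x$voxel, x$dims[1], x$dims[2], x$dims[3], x$n_solid))
  cat(sprintf("  V = %.2f mm^3, S = %.2f mm^2\n", x$V, x$S))
  invisible(x)
}

#' Scaffold porosity
#'
#' `porosity = (1 - V_structure / V_overall) * 100%`.
#'
#' @param V_structure Structural material volume (mm^3).
#' @param V_overall Overall (bounding) volume (mm^3).
#' @return Porosity in percent.
#' @examples
#' porosity_pct(60.54, 7.9 * 7.9 * 6)
#' @export
porosity_pct <- function(V_structure, V_overall) {
  if (any(V_overall <= 0)) stop("V_overall must be > 0")
  if (any(V_structure < 0) || any(V_structure > V_overall))
    stop("V_structure must lie in [0, V_overall]")
  (1 - V_structure / V_overall) * 100
}

#' Surface-area-to-volume ratio
#'
#' `SA:V = S / V`, units mm^-1 when S is mm^2 and V mm^3.
#'
#' @param S Surface area.
#' @param V Structure volume.
#' @export
sa_to_v <- function(S, V) {
  if (any(V <= 0)) stop("V must be > 0")
  S / V
}

#' Maximum pore diagonal
#'
#' Longest diagonal of a square (`side * sqrt(2)`) or regular hexagonal
#' (`2 * side`) pore opening.
#'
#' @param shape `"square"` or `"hexagon"`.
#' @param side Pore side length (any unit; result in the same unit).
#' @export
pore_diagonal <- function(shape = c("square", "hexagon"), side) {
  shape <- match.arg(shape)
  if (any(side <= 0)) stop("side must be > 0")
  switch(shape, square = side * sqrt(2), hexagon = 2 * side)
}

#' Measure scaffold geometry
#'
#' Structure volume and surface area are computed by smoothed-indicator
#' (co-area) integration of the lattice signed distance field on the voxel
#' grid, which is exact for cylindrical struts up to sampling noise; the
#' voxel count times voxel volume is retained in the model as a cross-check.
#' Flat faces created by clipping the lattice at the bounding box count
#' toward S by default (the printed part's total surface), switchable via
#' `include_clip`.
#'
#' @param model A `scaffold_model`.
#' @param include_clip Count bounding-box clip faces in S (default TRUE).
#' @return A `geometry_metrics` object: `V_structure`, `V_overall`, `S`,
#'   `porosity` (%), `sa_to_v` (mm^-1), `max_pore_side` (um),
#'   `max_pore_diagonal` (um).
#' @export
measure_geometry <- function(model, include_clip = TRUE) {
  stopifnot(inherits(model, "scaffold_model"))
  if (model$n_solid == 0) stop("empty occupancy: nothing to measure")
  if (include_clip && !is.null(model$V)) {
    V <- model$V; S <- model$S
  } else {
    m <- .cpp_voxelize_metrics(model$params, model$voxel, include_clip, FALSE)
    V <- m$V; S <- m$S
  }
  if (V <= 0) stop("zero structure volume")
  V_overall <- prod(model$bounding_box)
  spec <- model$spec
  pore_side <- if (is.null(spec)) NA_real_ else spec$pore_side
  pore_diag <- if (is.null(spec)) NA_real_ else
    pore_diagonal(spec$pore_shape, spec$pore_side)
  structure(list(design = model$design,
                 V_structure = V, V_overall = V_overall, S = S,
                 porosity = porosity_pct(V, V_overall),
                 sa_to_v = sa_to_v(S, V),
                 max_pore_side = pore_side,
                 max_pore_diagonal = pore_diag),
            class = "geometry_metrics")
}

#' @export
print.geometry_metrics <- function(x, ...) {
  cat("Scaffold geometry metrics (", x$design, ")\n", sep = "")
  cat(sprintf("  V = %.2f mm^3 of %.2f mm^3 overall\n",
              x$V_structure, x$V_overall))
  cat(sprintf("  S = %.2f mm^2\n", x$S))
  cat(sprintf("  porosity = %.2f%%   SA:V = %.2f mm^-1\n",
              x$porosity, x$sa_to_v))
  if (!is.na(x$max_pore_side))
    cat(sprintf("  max pore side %g um, diagonal %g um\n",
                x$max_pore_side, round(x$max_pore_diagonal)))
  invisible(x)
}

#' Write geometry metrics to CSV
#'
#' One row per design with columns
#' `design, V_mm3, S_mm2, porosity_pct, sa_to_v_per_mm, pore_side_um,
#' pore_diag_um`.
#'
#' @param metrics A `geometry_metrics` or list of them.
#' @param path Output file.
#' @export
write_metrics_csv <- function(metrics, path) {
  if (inherits(metrics, "geometry_metrics")) metrics <- list(metrics)
  df <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(design = m$design, V_mm3 = m$V_structure, S_mm2 = m$S,
               porosity_pct = m$porosity, sa_to_v_per_mm = m$sa_to_v,
               pore_side_um = m$max_pore_side,
               pore_diag_um = m$max_pore_diagonal)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Evaluate the scaffold signed distance field
#'
#' Distance (mm) from points to the scaffold surface, negative inside the
#' solid.  Used for validation and downstream masking.
#'
#' @param model A `scaffold_model` built from a lattice spec.
#' @param points Numeric matrix (n x 3), mm.
#' @export
scaffold_sdf <- function(model, points) {
  stopifnot(inherits(model, "scaffold_model"))
  if (is.null(model$params)) stop("imported models carry no distance field")
  points <- rbind(points)
  .cpp_sdf_eval(model$params, points)
}

# Internal: occupancy as a logical array (i fastest), used by tests.
.occupancy_array <- function(model) {
  array(as.logical(as.integer(model$occupancy)), dim = model$dims)
}
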