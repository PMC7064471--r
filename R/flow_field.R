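# Desk-scale filling flow in the culture well: laminar incompressible
# staggered-grid solver with a liquid volume-fraction front.
# Flow quantities are SI (m, s, kg); scaffold geometry is mm and is
# converted when registered into the well.

#' Fluid properties of the seeding medium
#'
#' @param rho_fluid Density, kg/m^3 (default 1000).
#' @param mu Dynamic viscosity, Pa s (default 0.001).
#' @param sigma_solution Solution surface tension, N/m (default 0.07).
#'   Retained for the impact-energy model; the coarse filling solver does
#'   not apply interface tension forcing.
#' @param g Gravitational acceleration, m/s^2, acting downward.
#' @export
fluid_properties <- function(rho_fluid = 1.0e3, mu = 0.001,
                             sigma_solution = 0.07, g = 9.81) {
  vals <- c(rho_fluid, mu, sigma_solution, g)
  if (any(vals <= 0)) stop("all fluid properties must be strictly positive")
  structure(list(rho_fluid = rho_fluid, mu = mu,
                 sigma_solution = sigma_solution, g = g),
            class = "fluid_properties")
}

#' Culture-well domain with a registered scaffold
#'
#' The well is a vertical cylinder (default 15 mm deep, 11 mm diameter)
#' with the scaffold resting centred on its bottom.  Medium is injected
#' horizontally through a small disk on the side wall at mid-height
#' ("from the middle of the well wall").
#'
#' @param scaffold A `scaffold_model` (mm units), or NULL for an empty well.
#' @param depth Well depth, m (default 0.015).
#' @param diameter Well diameter, m (default 0.011).
#' @param inlet_diameter Injection disk diameter, m (default 0.002; the
#'   experiment reports only the injected volume and time, so the inlet
#'   size is a free parameter).
#' @param inlet_height Height of the inlet centre above the bottom, m
#'   (default mid-depth).
#' @export
well_domain <- function(scaffold = NULL, depth = 0.015, diameter = 0.011,
                        inlet_diameter = 0.002, inlet_height = depth / 2) {
  if (depth <= 0 || diameter <= 0 || inlet_diameter <= 0)
    stop("well dimensions must be positive")
  if (!is.null(scaffold)) {
    stopifnot(inherits(scaffold, "scaffold_model"))
    ext <- scaffold$bounding_box / 1000 # mm -> m
    if (ext[1] > diameter || ext[2] > diameter || ext[3] > depth)
      stop("scaffold does not fit inside the well")
  }
  structure(list(scaffold = scaffold, depth = depth, diameter = diameter,
                 inlet_diameter = inlet_diameter,
                 inlet_height = inlet_height),
            class = "well_domain")
}

# Internal: scaffold placement (origin of the mm occupancy grid in well
# coordinates, m): centred laterally, resting on the bottom.
.scaffold_origin <- function(domain) {
  ext <- domain$scaffold$bounding_box / 1000
  c((domain$diameter - ext[1]) / 2, (domain$diameter - ext[2]) / 2, 0)
}

#' Initialise the filling flow state
#'
#' Velocities and pressure start at zero and the well holds air
#' (`alpha = 0`).  Cells outside the well cylinder are solid.  The
#' scaffold enters the flow problem in one of two ways: where its pores
#' span at least three grid cells it is resolved as a no-slip mask; finer
#' lattices act as an isotropic Darcy drag region with a Kozeny-Carman
#' permeability derived from the local solid fraction and the measured
#' specific surface.
#'
#' @param domain A [well_domain()].
#' @param props A [fluid_properties()].
#' @param grid_n Cells per axis (default 64): the grid is
#'   `grid_n x grid_n x grid_n` over the well bounding box.
#' @param darcy_mode `"auto"` (resolve if pores span >= 3 cells),
#'   `"resolved"`, or `"darcy"`.
#' @return A `flow_state` environment holding the staggered fields.
#' @export
init_flow <- function(domain, props = fluid_properties(), grid_n = 64,
                      darcy_mode = c("auto", "resolved", "darcy")) {
  darcy_mode <- match.arg(darcy_mode)
  stopifnot(inherits(domain, "well_domain"))
  nx <- ny <- nz <- as.integer(grid_n)
  Lx <- Ly <- domain$diameter
  Lz <- domain$depth
  hx <- Lx / nx; hy <- Ly / ny; hz <- Lz / nz
  flag <- array(0L, dim = c(nx, ny, nz))
  drag <- array(0, dim = c(nx, ny, nz))
  cx <- Lx / 2; cy <- Ly / 2; R <- domain$diameter / 2
  xc <- (seq_len(nx) - 0.5) * hx
  yc <- (seq_len(ny) - 0.5) * hy
  out_cyl <- outer(xc, yc, function(x, y) (x - cx)^2 + (y - cy)^2 > R^2)
  flag[] <- rep(as.integer(out_cyl), nz)

  scaffold <- domain$scaffold
  resolved <- TRUE
  if (!is.null(scaffold)) {
    frac <- .coarse_solid_fraction(scaffold, domain, c(nx, ny, nz),
                                   c(hx, hy, hz))
    pore_m <- if (!is.null(scaffold$spec)) scaffold$spec$pore_side * 1e-6 else Inf
    resolved <- switch(darcy_mode,
                       auto = pore_m >= 3 * min(hx, hy, hz),
                       resolved = TRUE, darcy = FALSE)
    if (resolved) {
      flag[frac > 0.5] <- 1L
    } else {
      # Kozeny-Carman: K = eps^3 / (c S0^2 (1-eps)^2), c = 5,
      # S0 = surface per unit solid volume (the measured SA:V)
      S0 <- (scaffold$S / scaffold$V) * 1000 # mm^-1 -> m^-1
      eps <- pmin(pmax(1 - frac, 0.05), 0.999)
      K <- eps^3 / (5 * S0^2 * (1 - eps)^2)
      dcoef <- ifelse(frac > 0.02, props$mu / K, 0)
      drag[] <- dcoef
    }
  }

  # inlet: u-faces on the -x side of the first fluid cell in each (j,k)
  # row whose face centre lies in the injection disk
  zin <- domain$inlet_height
  Rin <- domain$inlet_diameter / 2
  inlet_idx <- integer(0)
  kz <- (seq_len(nz) - 0.5) * hz
  for (k in seq_len(nz)) {
    for (j in seq_len(ny)) {
      if ((yc[j] - cy)^2 + (kz[k] - zin)^2 > Rin^2) next
      i <- which(flag[, j, k] == 0L)[1]
      if (is.na(i)) next
      # u-face index (0-based linear into (nx+1, ny, nz))
      inlet_idx <- c(inlet_idx,
                     (i - 1L) + (nx + 1L) * ((j - 1L) + ny * (k - 1L)))
    }
  }
  if (length(inlet_idx) == 0) {
    # grid too coarse for the disk: use the face nearest the inlet centre
    jn <- which.min(abs(yc - cy))
    kn <- which.min(abs(kz - zin))
    i <- which(flag[, jn, kn] == 0L)[1]
    if (is.na(i)) stop("inlet disk does not intersect the fluid")
    inlet_idx <- (i - 1L) + (nx + 1L) * ((jn - 1L) + ny * (kn - 1L))
  }

  st <- new.env(parent = emptyenv())
  st$u <- array(0, dim = c(nx + 1, ny, nz))
  st$v <- array(0, dim = c(nx, ny + 1, nz))
  st$w <- array(0, dim = c(nx, ny, nz + 1))
  st$p <- array(0, dim = c(nx, ny, nz))
  st$alpha <- array(0, dim = c(nx, ny, nz))
  st$flag <- flag
  st$drag <- drag
  st$dims <- c(nx, ny, nz)
  st$spacing <- c(hx, hy, hz)
  st$t <- 0
  st$props <- props
  st$domain <- domain
  st$resolved_scaffold <- resolved
  st$inlet_idx <- inlet_idx
  st$inlet_rate <- 0
  st$inlet_duration <- 0
  st$u_in <- 0
  st$injected_volume <- 0
  st$cg_tol <- 1e-6
  st$cg_maxiter <- 5000L
  st$last_diag <- NULL
  class(st) <- "flow_state"
  st
}

# Internal: solid fraction of each coarse flow cell from the fine scaffold
# occupancy grid.
.coarse_solid_fraction <- function(scaffold, domain, dims, spacing) {
  org <- .scaffold_origin(domain)
  occ <- as.integer(scaffold$occupancy)
  sd <- scaffold$dims
  vox <- scaffold$voxel / 1000
  # fine voxel centre coordinates per axis (m, well frame)
  ci <- pmin(pmax(floor((org[1] + (seq_len(sd[1]) - 0.5) * vox) / spacing[1]),
                  0), dims[1] - 1)
  cj <- pmin(pmax(floor((org[2] + (seq_len(sd[2]) - 0.5) * vox) / spacing[2]),
                  0), dims[2] - 1)
  ck <- pmin(pmax(floor((org[3] + (seq_len(sd[3]) - 0.5) * vox) / spacing[3]),
                  0), dims[3] - 1)
  idx <- rep(ci, times = sd[2] * sd[3]) +
    dims[1] * (rep(rep(cj, each = sd[1]), times = sd[3]) +
               dims[2] * rep(ck, each = sd[1] * sd[2]))
  solid <- tabulate(idx[occ == 1L] + 1L, nbins = prod(dims))
  total <- tabulate(idx + 1L, nbins = prod(dims))
  frac <- ifelse(total > 0, solid / total, 0)
  array(frac, dim = dims)
}

#' Prescribe the inlet flow
#'
#' A uniform normal velocity on the inlet disk faces such that the
#' volumetric rate matches `rate`; zero after `duration` seconds.
#'
#' @param state A `flow_state`.
#' @param rate Volumetric inflow, m^3/s (0.5 ml over 5 s = 1e-7).
#' @param duration Injection duration, s.
#' @export
inlet_flow <- function(state, rate, duration) {
  stopifnot(inherits(state, "flow_state"))
  if (rate < 0) stop("rate must be >= 0")
  state$inlet_rate <- rate
  state$inlet_duration <- duration
  area <- length(state$inlet_idx) * state$spacing[2] * state$spacing[3]
  state$u_in <- if (rate > 0) rate / area else 0
  invisible(state)
}

#' Advance the filling flow one macro time step
#'
#' Upwind advection (with automatic CFL sub-stepping), explicit viscosity,
#' liquid-weighted gravity, implicit Darcy drag, then a pressure projection
#' (conjugate gradients to relative residual 1e-6) enforcing the discrete
#' divergence constraint.  Diagnostics for the step are stored in
#' `state$last_diag`.
#'
#' @param state A `flow_state`.
#' @param dt Macro time step, s.
#' @export
advance_flow <- function(state, dt) {
  stopifnot(inherits(state, "flow_state"))
  if (dt <= 0) stop("dt must be > 0")
  inlet_on <- state$inlet_rate > 0 && state$t < state$inlet_duration
  diag <- .cpp_flow_step(state$u, state$v, state$w, state$p, state$alpha,
                         state$flag, state$drag,
                         as.integer(state$inlet_idx), state$u_in, inlet_on,
                         as.integer(state$dims), state$spacing, dt,
                         state$props$rho_fluid, state$props$mu,
                         state$props$g, state$cg_tol, state$cg_maxiter)
  state$t <- state$t + dt
  state$injected_volume <- state$injected_volume + diag$injected_volume
  state$last_diag <- diag
  invisible(state)
}

#' Sample the fluid velocity at points
#'
#' Trilinear interpolation of the staggered velocity field; points inside
#' solid cells return the zero vector; points outside the domain raise an
#' error.
#'
#' @param state A `flow_state`.
#' @param position Length-3 vector or n x 3 matrix, m.
#' @return n x 3 matrix of velocities (m/s).
#' @export
sample_velocity <- function(state, position) {
  stopifnot(inherits(state, "flow_state"))
  pts <- rbind(position)
  L <- state$spacing * state$dims
  if (any(pts[, 1] < 0 | pts[, 1] > L[1] | pts[, 2] < 0 | pts[, 2] > L[2] |
          pts[, 3] < 0 | pts[, 3] > L[3]))
    stop("position outside the flow domain")
  out <- .cpp_sample_velocity(state$u, state$v, state$w,
                              as.integer(state$dims), state$spacing, pts)
  ij <- cbind(pmin(pmax(floor(pts[, 1] / state$spacing[1]), 0),
                   state$dims[1] - 1) + 1,
              pmin(pmax(floor(pts[, 2] / state$spacing[2]), 0),
                   state$dims[2] - 1) + 1,
              pmin(pmax(floor(pts[, 3] / state$spacing[3]), 0),
                   state$dims[3] - 1) + 1)
  solid <- state$flag[ij] != 0L
  out[solid, ] <- 0
  out
}

#' Total liquid volume in the well
#' @param state A `flow_state`.
#' @return Volume in m^3.
#' @export
total_liquid_volume <- function(state) {
  sum(state$alpha[state$flag == 0L]) * prod(state$spacing)
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("Flow state: %d x %d x %d grid, t = %.3f s\n",
              x$dims[1], x$dims[2], x$dims[3], x$t))
  cat(sprintf("  liquid volume %.3f ml (injected %.3f ml)\n",
              total_liquid_volume(x) * 1e6, x$injected_volume * 1e6))
  cat(sprintf("  scaffold handling: %s\n",
              if (x$resolved_scaffold) "resolved no-slip mask"
              else "Darcy drag region"))
  invisible(x)
}

#' Write a flow snapshot as a legacy VTK structured-points file
#'
#' Cell data: liquid fraction `alpha`, pressure `p`, and the cell-centred
#' velocity vector.  Readable by ParaView/VisIt.
#'
#' @param state A `flow_state`.
#' @param path Output file (conventionally `.vtk`).
#' @export
write_vtk <- function(state, path) {
  stopifnot(inherits(state, "flow_state"))
  n <- state$dims; h <- state$spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("scaffseed flow snapshot t=%.6f", state$t),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1] + 1, n[2] + 1, n[3] + 1),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", h[1], h[2], h[3]),
               sprintf("CELL_DATA %d", prod(n))), con)
  fmt <- function(x) formatC(x, format = "g", digits = 7)
  writeLines(c("SCALARS alpha float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(fmt(as.numeric(state$alpha)), collapse = "\n"), con)
  writeLines(c("SCALARS p float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(fmt(as.numeric(state$p)), collapse = "\n"), con)
  uc <- 0.5 * (state$u[-1, , , drop = FALSE] +
               state$u[-(n[1] + 1), , , drop = FALSE])
  vc <- 0.5 * (state$v[, -1, , drop = FALSE] +
               state$v[, -(n[2] + 1), , drop = FALSE])
  wc <- 0.5 * (state$w[, , -1, drop = FALSE] +
               state$w[, , -(n[3] + 1), drop = FALSE])
  writeLines("VECTORS velocity float", con)
  writeLines(paste(fmt(as.numeric(uc)), fmt(as.numeric(vc)),
                   fmt(as.numeric(wc))), con)
  invisible(path)
}
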