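# Lagrangian cell transport: force balance per cell (drag toward the local
# fluid velocity with relaxation time tau_r, buoyancy-corrected gravity,
# optional discrete-random-walk dispersion).  SI units.

#' Physical properties of the seeded cells
#'
#' @param rho_cell Cell density, kg/m^3 (default 1000: neutrally buoyant in
#'   the medium).
#' @param d_cell Cell diameter, m (default 15e-6, rat MSC size assumption).
#' @param mu_cell Cell-phase viscosity, Pa s (default 0.005).
#' @param sigma_cell Cell surface tension, N/m (default 0.03).
#' @export
cell_properties <- function(rho_cell = 1.0e3, d_cell = 15e-6,
                            mu_cell = 0.005, sigma_cell = 0.03) {
  if (any(c(rho_cell, d_cell, mu_cell, sigma_cell) <= 0))
    stop("all cell properties must be positive")
  structure(list(rho_cell = rho_cell, d_cell = d_cell, mu_cell = mu_cell,
                 sigma_cell = sigma_cell),
            class = "cell_properties")
}

#' Cell injection specification
#'
#' @param mass_flow_rate Injected cell mass per second, kg/s
#'   (default 8.18e-10).
#' @param duration Injection duration, s (default 5).
#' @export
injection_spec <- function(mass_flow_rate = 8.18e-10, duration = 5) {
  if (mass_flow_rate < 0) stop("mass_flow_rate must be >= 0")
  structure(list(mass_flow_rate = mass_flow_rate, duration = duration),
            class = "injection_spec")
}

#' Particle Reynolds number
#'
#' `Re = rho_fluid * |v_rel| * d / mu`.
#'
#' @param props A [fluid_properties()].
#' @param v_rel Relative (slip) speed, m/s.
#' @param d Particle diameter, m.
#' @export
particle_reynolds <- function(props, v_rel, d) {
  if (any(d <= 0)) stop("diameter must be > 0")
  props$rho_fluid * abs(v_rel) * d / props$mu
}

#' Smooth-sphere drag coefficient
#'
#' Piecewise `C_D = a1 + a2/Re + a3/Re^2` with the Morsi-Alexander constant
#' bands, using the Stokes band (0, 24, 0) below Re = 0.1 so that
#' `C_D * Re -> 24` as `Re -> 0`.
#'
#' @param Re Particle Reynolds number, > 0.
#' @export
drag_coefficient <- function(Re) {
  if (any(Re <= 0)) stop("Re must be > 0 (use the Stokes limit explicitly)")
  a <- .morsi_bands(Re)
  a[, 1] + a[, 2] / Re + a[, 3] / Re^2
}

.morsi_bands <- function(Re) {
  t(vapply(Re, function(r) {
    if (r < 0.1) c(0, 24, 0)
    else if (r < 1) c(3.690, 22.73, 0.0903)
    else if (r < 10) c(1.222, 29.1667, -3.8889)
    else if (r < 100) c(0.6167, 46.50, -116.67)
    else if (r < 1000) c(0.3644, 98.33, -2778)
    else c(0.357, 148.62, -47500)
  }, numeric(3)))
}

#' Particle relaxation time
#'
#' `tau_r = 4 rho_cell d^2 / (3 mu C_D Re)`; in the Stokes limit (Re -> 0,
#' `C_D Re -> 24`) this reduces to `rho_cell d^2 / (18 mu)`.
#'
#' @param cell A [cell_properties()].
#' @param fluid A [fluid_properties()].
#' @param Re Particle Reynolds number (0 selects the Stokes limit).
#' @export
relaxation_time <- function(cell, fluid, Re = 0) {
  d <- cell$d_cell
  if (Re <= 0 || Re < 0.1) {
    return(cell$rho_cell * d^2 / (18 * fluid$mu))
  }
  CD <- drag_coefficient(Re)
  4 * cell$rho_cell * d^2 / (3 * fluid$mu * CD * Re)
}

#' Exact drag relaxation update for one particle
#'
#' Analytic (exponential) integration of the linear drag term over `dt`:
#' `v(t+dt) = u_f + (v - u_f) exp(-dt/tau) + g_eff tau (1 - exp(-dt/tau))`
#' with `g_eff = g (rho_cell - rho_fluid) / rho_cell` acting downward.
#' Stable for `dt >> tau`.  Position advances with the end-of-step
#' velocity (`tau` is microseconds here, so the distinction from the exact
#' displacement integral is negligible).
#'
#' @param position,velocity Length-3 numeric, m and m/s.
#' @param u_fluid Local fluid velocity, length-3, m/s.
#' @param cell A [cell_properties()].
#' @param fluid A [fluid_properties()].
#' @param dt Time step, s.
#' @param gravity Apply the buoyancy-corrected gravity term (default TRUE).
#' @return List with `position` and `velocity`.
#' @export
step_particle <- function(position, velocity, u_fluid, cell, fluid, dt,
                          gravity = TRUE) {
  if (dt <= 0) stop("dt must be > 0")
  slip <- sqrt(sum((velocity - u_fluid)^2))
  Re <- particle_reynolds(fluid, slip, cell$d_cell)
  tau <- relaxation_time(cell, fluid, Re)
  ef <- exp(-dt / tau)
  geff <- if (gravity) {
    fluid$g * (cell$rho_cell - fluid$rho_fluid) / cell$rho_cell
  } else 0
  v <- u_fluid + (velocity - u_fluid) * ef +
    c(0, 0, -geff) * tau * (1 - ef)
  list(position = position + v * dt, velocity = v)
}

#' Discrete-random-walk velocity perturbations
#'
#' Zero-mean Gaussian eddy fluctuations with the configured RMS, redrawn
#' after each eddy lifetime.  The default RMS in the simulation config is 0
#' (off): the laminar carrier field carries no turbulent kinetic energy to
#' scale fluctuations from.
#'
#' @param n Number of particles.
#' @param rms Fluctuation RMS per component, m/s.
#' @return n x 3 matrix of velocity perturbations.
#' @export
random_walk_kick <- function(n, rms) {
  if (rms < 0) stop("rms must be >= 0")
  matrix(rnorm(3 * n, sd = rms), ncol = 3)
}

# ---- particle set ----------------------------------------------------------

# Status codes used throughout the engine:
.STATUS_LEVELS <- c(suspended = 0L, attached = 1L, attached_spread = 2L,
                    dead_attached = 3L, fragment = 4L)

#' Create an empty particle set
#'
#' A mutable container (environment) of per-particle state vectors used by
#' the simulation loop.
#' @return A `particle_set`.
#' @export
new_particle_set <- function() {
  ps <- new.env(parent = emptyenv())
  for (f in c("x", "y", "z", "vx", "vy", "vz", "diam", "birth",
              "upx", "upy", "upz", "uplife"))
    assign(f, numeric(0), envir = ps)
  ps$status <- integer(0)
  ps$id <- integer(0)
  ps$next_id <- 1L
  class(ps) <- "particle_set"
  ps
}

#' Add particles to a set
#'
#' @param ps A `particle_set`.
#' @param pos n x 3 positions (m).
#' @param vel n x 3 velocities (m/s).
#' @param diam Diameters (m), recycled.
#' @param status Integer status codes (default 0, suspended).
#' @param birth Birth times (s), recycled.
#' @export
add_particles <- function(ps, pos, vel, diam, status = 0L, birth = 0) {
  n <- nrow(pos)
  if (n == 0) return(invisible(ps))
  ps$x <- c(ps$x, pos[, 1]); ps$y <- c(ps$y, pos[, 2]); ps$z <- c(ps$z, pos[, 3])
  ps$vx <- c(ps$vx, vel[, 1]); ps$vy <- c(ps$vy, vel[, 2]); ps$vz <- c(ps$vz, vel[, 3])
  ps$diam <- c(ps$diam, rep_len(diam, n))
  ps$status <- c(ps$status, rep_len(as.integer(status), n))
  ps$birth <- c(ps$birth, rep_len(birth, n))
  ps$upx <- c(ps$upx, numeric(n)); ps$upy <- c(ps$upy, numeric(n))
  ps$upz <- c(ps$upz, numeric(n)); ps$uplife <- c(ps$uplife, numeric(n))
  ps$id <- c(ps$id, seq.int(ps$next_id, length.out = n))
  ps$next_id <- ps$next_id + n
  invisible(ps)
}

#' @export
print.particle_set <- function(x, ...) {
  tab <- table(factor(x$status, levels = .STATUS_LEVELS,
                      labels = names(.STATUS_LEVELS)))
  cat("Particle set:", length(x$x), "particles\n")
  print(tab)
  invisible(x)
}

#' Particle set as a data frame
#'
#' @param x A `particle_set`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @export
as.data.frame.particle_set <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(id = x$id, x = x$x, y = x$y, z = x$z,
             vx = x$vx, vy = x$vy, vz = x$vz,
             diam = x$diam, birth = x$birth,
             status = factor(x$status, levels = .STATUS_LEVELS,
                             labels = names(.STATUS_LEVELS)))
}

#' Inject cells at the inlet
#'
#' The number of whole cells released over `dt` is
#' `rate * dt / m_cell` with the fractional remainder carried between
#' calls (stored in `carry_env`), so the total count over the full
#' injection window is exact.  Positions are uniform on the inlet disk
#' just inside the fluid; initial velocities match the local fluid.
#'
#' @param spec An [injection_spec()].
#' @param cell A [cell_properties()].
#' @param flow A `flow_state` (provides inlet geometry and velocities).
#' @param ps A `particle_set` to append to.
#' @param t Current time, s.
#' @param dt Step, s.
#' @param carry_env Environment carrying the fractional remainder
#'   (field `carry`); defaults to an attribute-like env on the spec.
#' @return Number of cells injected this call.
#' @export
inject_cells <- function(spec, cell, flow, ps, t, dt,
                         carry_env = NULL) {
  if (is.null(carry_env)) {
    if (is.null(attr(spec, "carry_env"))) {
      e <- new.env(parent = emptyenv()); e$carry <- 0
      attr(spec, "carry_env") <- e
    }
    carry_env <- attr(spec, "carry_env")
  }
  if (t >= spec$duration || spec$mass_flow_rate <= 0) return(0L)
  dt_eff <- min(dt, spec$duration - t)
  m_cell <- cell$rho_cell * pi / 6 * cell$d_cell^3
  frac <- spec$mass_flow_rate * dt_eff / m_cell + carry_env$carry
  n <- floor(frac)
  carry_env$carry <- frac - n
  n <- as.integer(n)
  if (n == 0) return(0L)
  dom <- flow$domain
  Rin <- dom$inlet_diameter / 2
  cy <- dom$diameter / 2
  zin <- dom$inlet_height
  rr <- Rin * sqrt(runif(n)) * 0.98
  th <- runif(n, 0, 2 * pi)
  yy <- cy + rr * cos(th)
  zz <- zin + rr * sin(th)
  # just inside the fluid at the inlet faces
  iface <- min(flow$inlet_idx %% (flow$dims[1] + 1))
  xx <- rep((iface + 0.6) * flow$spacing[1], n)
  pos <- cbind(xx, yy, zz)
  vel <- sample_velocity(flow, pos)
  still <- rowSums(vel^2) == 0
  vel[still, 1] <- flow$u_in * (flow$t < flow$inlet_duration)
  add_particles(ps, pos, vel, cell$d_cell, status = 0L, birth = t)
  n
}

#' Advance all mobile particles one step
#'
#' Velocity relaxation toward the sampled fluid velocity (exact
#' exponential integrator), buoyancy-corrected gravity, optional DRW kick,
#' then collision-aware transport: ray-voxel traversal against the fine
#' scaffold occupancy decides scaffold impingements (classified by the
#' impact-energy regime model), and the well cylinder/bottom/top reflect
#' specularly without trapping.
#'
#' @param ps A `particle_set`.
#' @param flow A `flow_state`.
#' @param engine A `seeding_engine` created by [seeding_engine()] (carries
#'   the scaffold occupancy, wall film and impingement settings).
#' @param t Current time, s.
#' @param dt Step, s.
#' @return Data frame of impingement events this step (possibly empty).
#' @export
step_particles <- function(ps, flow, engine, t, dt) {
  if (length(ps$x) == 0) return(.empty_events())
  res <- .cpp_particles_step(ps$x, ps$y, ps$z, ps$vx, ps$vy, ps$vz,
                             ps$status, ps$diam,
                             ps$upx, ps$upy, ps$upz, ps$uplife,
                             flow$u, flow$v, flow$w, flow$alpha,
                             as.integer(flow$dims), flow$spacing,
                             engine$occ, as.integer(engine$occ_dims),
                             engine$occ_voxel, engine$occ_origin,
                             engine$film, engine$params, t, dt)
  nf <- length(res$frag_x)
  if (nf > 0) {
    add_particles(ps, cbind(res$frag_x, res$frag_y, res$frag_z),
                  cbind(res$frag_vx, res$frag_vy, res$frag_vz),
                  diam = res$frag_d, status = 4L, birth = t)
  }
  if (length(res$event_t) == 0) return(.empty_events())
  data.frame(t = res$event_t, particle = res$event_id, E = res$event_E,
             v_pn = res$event_vpn,
             regime = factor(res$event_regime, levels = 0:3,
                             labels = c("stick", "rebound", "spread",
                                        "splash")),
             element = res$event_elem)
}

.empty_events <- function() {
  data.frame(t = numeric(0), particle = integer(0), E = numeric(0),
             v_pn = numeric(0),
             regime = factor(character(0),
                             levels = c("stick", "rebound", "spread",
                                        "splash")),
             element = numeric(0))
}

#' Total particle mass by status
#'
#' Mass is `rho_cell * pi/6 * d^3` per particle (fragments carry their
#' reduced diameter, so six fragments sum to their parent's mass exactly).
#'
#' @param ps A `particle_set`.
#' @param cell A [cell_properties()].
#' @return Named numeric: mass in kg per status class.
#' @export
particle_mass_by_status <- function(ps, cell) {
  m <- cell$rho_cell * pi / 6 * ps$diam^3
  out <- vapply(.STATUS_LEVELS, function(s) sum(m[ps$status == s]),
                numeric(1))
  names(out) <- names(.STATUS_LEVELS)
  out
}
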