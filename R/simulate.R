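# Coupled simulation driver: filling flow + Lagrangian cells + impingement.

#' Simulation configuration
#'
#' Collects every tunable of the coupled run with the reference seeding
#' conditions as defaults:
#' 0.5 ml of medium and 8.18e-10 kg/s of 15-um cells injected for 5 s from
#' a 2-mm disk at mid-height of the well wall, simulated for 6 s on a
#' 64^3 grid.
#'
#' @param design `"cubic"` or `"truncated_octahedron"`.
#' @param grid_n Flow cells per axis (default 64).
#' @param dt Macro time step, s (default 2.5e-3; advection sub-steps
#'   internally on the CFL limit).
#' @param t_end Simulated time, s (default 6).
#' @param fluid_volume_ml Injected medium volume, ml (default 0.5).
#' @param inject_fluid_s Medium injection duration, s (default 5).
#' @param inject_cells_s Cell injection duration, s (default 5).
#' @param mass_flow_rate Cell mass flow, kg/s (default 8.18e-10).
#' @param voxel Scaffold voxel edge, mm (default 0.025).
#' @param seed RNG seed for the run.
#' @param darcy_mode Scaffold-in-flow handling; see [init_flow()].
#' @param drw_rms,drw_life Discrete-random-walk fluctuation RMS (m/s,
#'   default 0 = off) and eddy lifetime (s).
#' @param restitution_n,restitution_t Rebound restitution coefficients.
#' @param e_stick,e_splash Impact-energy regime thresholds (16, 57.7).
#' @param n_splash_fragments Drops per splashed cell (default 6).
#' @param sigma_source `"cell"` (default) or `"solution"`: which surface
#'   tension enters the impact energy.
#' @param eq9_form `"standard"` or `"literal"` impact-energy bracket.
#' @param prewet_h Initial film height on wetted surface elements, m
#'   (default 1e-6).
#' @param T_wall,T_s,Tc_star Thermal context (culture defaults).
#' @param inlet_diameter Injection disk diameter, m.
#' @param record_every Record the time series every this many steps.
#' @export
seeding_config <- function(design = c("cubic", "truncated_octahedron"),
                           grid_n = 64, dt = 2.5e-3, t_end = 6,
                           fluid_volume_ml = 0.5, inject_fluid_s = 5,
                           inject_cells_s = 5, mass_flow_rate = 8.18e-10,
                           voxel = 0.025, seed = 1,
                           darcy_mode = "auto",
                           drw_rms = 0, drw_life = 1e-3,
                           restitution_n = 0.9, restitution_t = 1,
                           e_stick = 16, e_splash = 57.7,
                           n_splash_fragments = 6,
                           sigma_source = c("cell", "solution"),
                           eq9_form = c("standard", "literal"),
                           prewet_h = 1e-6,
                           T_wall = 310.15, T_s = 373.15, Tc_star = 1,
                           inlet_diameter = 0.002, record_every = 25) {
  design <- match.arg(design)
  sigma_source <- match.arg(sigma_source)
  eq9_form <- match.arg(eq9_form)
  structure(as.list(environment()), class = "seeding_config")
}

#' Assemble the particle/impingement engine for a run
#'
#' Bundles the fine scaffold occupancy (registered into the well in SI
#' units), the wall-film store, and the impingement parameters consumed by
#' the compiled particle stepper.
#'
#' @param scaffold A `scaffold_model`.
#' @param domain A [well_domain()].
#' @param fluid A [fluid_properties()].
#' @param cell A [cell_properties()].
#' @param config A [seeding_config()].
#' @export
seeding_engine <- function(scaffold, domain, fluid, cell, config) {
  org <- .scaffold_origin(domain)
  thermal <- thermal_context(config$T_wall, config$T_s, config$Tc_star)
  sigma <- if (config$sigma_source == "cell") cell$sigma_cell
           else fluid$sigma_solution
  params <- list(rho_fluid = fluid$rho_fluid, mu = fluid$mu,
                 rho_cell = cell$rho_cell, sigma = sigma, g = fluid$g,
                 e_stick = config$e_stick, e_splash = config$e_splash,
                 T_wall = thermal$T_wall,
                 T_c = critical_temperature(thermal),
                 restitution_n = config$restitution_n,
                 restitution_t = config$restitution_t,
                 n_splash_fragments = as.integer(config$n_splash_fragments),
                 drw_rms = config$drw_rms, drw_life = config$drw_life,
                 prewet_h = config$prewet_h,
                 well_radius = domain$diameter / 2,
                 well_cx = domain$diameter / 2,
                 well_cy = domain$diameter / 2,
                 well_depth = domain$depth,
                 eq9_literal = identical(config$eq9_form, "literal"),
                 frag_speed_factor = 0.8)
  structure(list(occ = scaffold$occupancy,
                 occ_dims = scaffold$dims,
                 occ_voxel = scaffold$voxel / 1000,
                 occ_origin = org,
                 film = .cpp_film_new(),
                 params = params,
                 thermal = thermal),
            class = "seeding_engine")
}

#' Run the coupled cell-seeding simulation
#'
#' Builds the scaffold, fills the well while injecting cells, tracks every
#' cell to attachment or rest, and records the attachment time series.
#'
#' @param config A [seeding_config()].
#' @param fluid,cell Property sets (reference-condition defaults).
#' @param scaffold Optionally a prebuilt `scaffold_model` (mm units);
#'   by default built from `config$design`.
#' @param verbose Print progress every simulated second.
#' @return A `seeding_result`: list with `series` (time series data
#'   frame), `particles` (final particle data frame), `events`
#'   (impingement log), `metrics` (scaffold geometry), `config`.
#' @export
run_seeding <- function(config = seeding_config(),
                        fluid = fluid_properties(),
                        cell = cell_properties(),
                        scaffold = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "seeding_config"))
  set.seed(config$seed)
  if (is.null(scaffold)) {
    scaffold <- build_scaffold(config$design, voxel = config$voxel)
  }
  metrics <- measure_geometry(scaffold)
  domain <- well_domain(scaffold, inlet_diameter = config$inlet_diameter)
  flow <- init_flow(domain, fluid, grid_n = config$grid_n,
                    darcy_mode = config$darcy_mode)
  rate <- config$fluid_volume_ml * 1e-6 / config$inject_fluid_s
  inlet_flow(flow, rate, config$inject_fluid_s)
  engine <- seeding_engine(scaffold, domain, fluid, cell, config)
  inj <- injection_spec(config$mass_flow_rate, config$inject_cells_s)
  carry <- new.env(parent = emptyenv()); carry$carry <- 0
  ps <- new_particle_set()

  nstep <- ceiling(config$t_end / config$dt)
  events <- list()
  rec <- list()
  n_injected <- 0L
  for (s in seq_len(nstep)) {
    t <- (s - 1) * config$dt
    advance_flow(flow, config$dt)
    n_injected <- n_injected +
      inject_cells(inj, cell, flow, ps, t, config$dt, carry_env = carry)
    ev <- step_particles(ps, flow, engine, t, config$dt)
    if (nrow(ev) > 0) events[[length(events) + 1L]] <- ev
    if (s %% config$record_every == 0 || s == nstep) {
      st <- ps$status
      live <- sum(st == 1L | st == 2L)
      rec[[length(rec) + 1L]] <- data.frame(
        t = s * config$dt,
        injected = n_injected,
        attached_live = live,
        attached_stick = sum(st == 1L),
        attached_spread = sum(st == 2L),
        dead_attached = sum(st == 3L),
        fragments_mobile = sum(st == 4L),
        suspended = sum(st == 0L),
        efficiency = if (n_injected > 0)
          seeding_efficiency(live, n_injected) else 0,
        liquid_ml = total_liquid_volume(flow) * 1e6)
    }
    if (verbose && s %% round(1 / config$dt) == 0) {
      d <- flow$last_diag
      message(sprintf(
        "t=%.1f s: injected %d, attached %d (%.1f%%), liquid %.3f ml, cg %d",
        s * config$dt, n_injected,
        sum(ps$status == 1L | ps$status == 2L),
        if (n_injected > 0) 100 * sum(ps$status %in% c(1L, 2L)) / n_injected
        else 0,
        total_liquid_volume(flow) * 1e6, d$cg_iters))
    }
  }
  series <- do.call(rbind, rec)
  events <- if (length(events)) do.call(rbind, events) else .empty_events()
  structure(list(series = series,
                 particles = as.data.frame(ps),
                 events = events,
                 metrics = metrics,
                 mass = particle_mass_by_status(ps, cell),
                 config = config,
                 domain = domain,
                 flow = flow,
                 scaffold_origin = .scaffold_origin(domain)),
            class = "seeding_result")
}

#' @export
print.seeding_result <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat("Cell seeding simulation:", x$config$design, "\n")
  cat(sprintf("  t = %.1f s, injected %d cells\n", last$t, last$injected))
  cat(sprintf("  attached live %d (stick %d, spread %d), dead %d, suspended %d\n",
              last$attached_live, last$attached_stick, last$attached_spread,
              last$dead_attached, last$suspended))
  cat(sprintf("  seeding efficiency %.1f%%\n", last$efficiency))
  invisible(x)
}

#' Write simulation outputs as CSV
#'
#' `results.csv` (time series: t, N_i, N_a, Phi_pct, dead), `bins.csv`
#' (lateral live/dead attachment bins), `events.csv` (impingement log:
#' t, particle_id, E, regime, element_id) and `particles.csv` (final
#' particle snapshot).
#'
#' @param result A `seeding_result`.
#' @param dir Output directory (created if missing).
#' @export
write_results_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- result$series
  write.csv(data.frame(t = s$t, N_i = s$injected, N_a = s$attached_live,
                       Phi_pct = s$efficiency, dead = s$dead_attached),
            file.path(dir, "results.csv"), row.names = FALSE)
  b <- lateral_bin_counts(result$particles,
                          origin = result$scaffold_origin[1])
  write.csv(b, file.path(dir, "bins.csv"), row.names = FALSE)
  e <- result$events
  write.csv(data.frame(t = e$t, particle_id = e$particle, E = e$E,
                       regime = e$regime, element_id = e$element),
            file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(result$particles, file.path(dir, "particles.csv"),
            row.names = FALSE)
  invisible(dir)
}
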