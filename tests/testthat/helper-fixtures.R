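# Shared fixtures, memoized so expensive builds run once per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# coarse (50 um) unit cells and scaffolds: fast, adequate for structure tests
coarse_cubic_cell <- function() fixture("cubic_cell", function()
  build_cubic_cell(unit_cell_spec("cubic"), voxel = 0.05))

coarse_to_cell <- function() fixture("to_cell", function()
  build_to_cell(unit_cell_spec("truncated_octahedron"), voxel = 0.05))

coarse_cubic_scaffold <- function() fixture("cubic_scaffold", function()
  build_scaffold("cubic", voxel = 0.05))

coarse_to_scaffold <- function() fixture("to_scaffold", function()
  build_scaffold("truncated_octahedron", voxel = 0.05))

# a small empty-well flow state for particle/flow unit tests
small_flow <- function(grid_n = 24) {
  fl <- init_flow(well_domain(NULL), fluid_properties(), grid_n = grid_n)
  inlet_flow(fl, 1e-7, 5)
  fl
}

# an engine over an empty (or custom) occupancy grid in a unit-well frame,
# for exercising the compiled particle stepper in isolation
bare_engine <- function(occ_dims = c(10L, 10L, 10L), occ = NULL,
                        params = list()) {
  if (is.null(occ)) occ <- as.raw(rep(0L, prod(occ_dims)))
  defaults <- list(rho_fluid = 1000, mu = 0.001, rho_cell = 1000,
                   sigma = 0.03, g = 9.81, e_stick = 16, e_splash = 57.7,
                   T_wall = 310.15, T_c = 373.15,
                   restitution_n = 0.9, restitution_t = 1,
                   n_splash_fragments = 6L, drw_rms = 0, drw_life = 1e-3,
                   prewet_h = 0, well_radius = 5.5e-3, well_cx = 5.5e-3,
                   well_cy = 5.5e-3, well_depth = 15e-3,
                   eq9_literal = FALSE, frag_speed_factor = 0.8)
  defaults[names(params)] <- params
  structure(list(occ = occ, occ_dims = occ_dims,
                 occ_voxel = 25e-6,
                 occ_origin = c(4e-3, 4e-3, 0),
                 film = scaffseed:::.cpp_film_new(),
                 params = defaults),
            class = "seeding_engine")
}

# a still "flow" whose arrays are all zero, sized to the well
still_flow <- function(grid_n = 8) {
  init_flow(well_domain(NULL), fluid_properties(), grid_n = grid_n)
}
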