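# Impact energy, regime classification, wall interaction.

test_that("boundary layer thickness is d/sqrt(Re)", {
  expect_equal(boundary_layer_thickness(15e-6, 0.15), 15e-6 / sqrt(0.15))
  expect_equal(boundary_layer_thickness(15e-6, 0.15), 3.873e-5,
               tolerance = 1e-4)
  expect_equal(boundary_layer_thickness(15e-6, 1), 15e-6)
  Re <- c(0.1, 0.5, 2, 10)
  expect_true(all(diff(boundary_layer_thickness(15e-6, Re)) < 0))
  expect_error(boundary_layer_thickness(15e-6, 0), "Re")
})

test_that("impact energy reproduces hand arithmetic on a dry wall", {
  # rho 1000, V 0.01, d 15 um, sigma 0.03 (cell), Re = 0.15
  dbl <- boundary_layer_thickness(15e-6, 0.15)
  E <- impact_energy(1000, 0.01, 15e-6, 0.03, h_o = 0, delta_bl = dbl)
  expect_equal(E, sqrt(1000 * 1e-4 * 15e-6 / 0.03 * sqrt(0.15)),
               tolerance = 1e-12)
  expect_equal(E, 4.4e-3, tolerance = 0.01)
  expect_equal(impact_energy(1000, 0, 15e-6, 0.03, 0, dbl), 0)
  # deep film clamps the film term at 1
  d <- 15e-6
  E_deep <- impact_energy(1000, 0.01, d, 0.03, h_o = 10 * d,
                          delta_bl = dbl)
  expect_equal(E_deep, sqrt(1000 * 1e-4 * d / 0.03 / (1 + dbl / d)),
               tolerance = 1e-12)
  expect_error(impact_energy(1000, 0.01, d, 0.03, 0, 0), "degenerate")
  # literal bracket reading is exposed for sensitivity checks
  E_lit <- impact_energy(1000, 0.01, d, 0.03, h_o = 10 * d,
                         delta_bl = dbl, form = "literal")
  expect_equal(E_lit, sqrt(1000 * 1e-4 * d / 0.03 * (1 + dbl / d)),
               tolerance = 1e-12)
})

test_that("regime classification partitions at 16 and 57.7", {
  cold <- thermal_context() # 37 C wall < T_c
  expect_equal(as.character(classify_regime(10, cold)), "stick")
  expect_equal(as.character(classify_regime(30, cold)), "spread")
  expect_equal(as.character(classify_regime(70, cold)), "splash")
  hot <- thermal_context(T_wall = 400)
  expect_equal(as.character(classify_regime(30, hot)), "rebound")
  expect_equal(as.character(classify_regime(70, hot)), "splash")
  # boundary values and totality over a grid of inputs
  expect_equal(as.character(classify_regime(16, cold)), "spread")
  expect_equal(as.character(classify_regime(57.7, cold)), "spread")
  expect_equal(as.character(classify_regime(57.700001, cold)), "splash")
  expect_equal(as.character(classify_regime(15.9999, cold)), "stick")
  grid <- expand.grid(E = c(0, 1, 16, 20, 57.7, 58, 1e3),
                      Tw = c(300, 373.15, 380))
  reg <- mapply(function(E, Tw)
    as.character(classify_regime(E, thermal_context(T_wall = Tw))),
    grid$E, grid$Tw)
  expect_true(all(reg %in% c("stick", "rebound", "spread", "splash")))
  expect_error(classify_regime(-1, cold))
})

test_that("critical temperature is Tc_star times saturation", {
  expect_equal(critical_temperature(thermal_context()), 373.15)
  expect_equal(critical_temperature(thermal_context(Tc_star = 1.5)),
               559.725)
  expect_equal(critical_temperature(thermal_context(T_s = 300)), 300)
  expect_error(thermal_context(Tc_star = 0.5), "Tc_star")
  expect_error(thermal_context(Tc_star = 2), "Tc_star")
})

test_that("regimes update particle state as described", {
  p <- list(position = c(0, 0, 0), velocity = c(0.02, 0, -0.05),
            diam = 15e-6, status = "suspended")
  n <- c(0, 0, 1)
  st <- apply_regime(p, "stick", n, element_area = 1e-8)
  expect_equal(st$particle$velocity, c(0, 0, 0))
  expect_equal(st$particle$status, "attached")
  sp <- apply_regime(p, "spread", n, element_area = 1e-8)
  expect_equal(sp$film_increment, pi / 6 * (15e-6)^3 / 1e-8,
               tolerance = 1e-12)
  expect_equal(sp$film_increment, 1.77e-7, tolerance = 0.01)
  rb <- apply_regime(p, "rebound", n, 1e-8, e_n = 0.9, e_t = 1)
  expect_equal(rb$particle$velocity, c(0.02, 0, 0.045), tolerance = 1e-12)
  expect_equal(rb$particle$status, "suspended")
  set.seed(1)
  sl <- apply_regime(p, "splash", n, 1e-8, n_fragments = 6)
  expect_equal(nrow(sl$fragments), 5) # five fly, one stays as dead matter
  m <- function(d) pi / 6 * d^3
  expect_equal(m(sl$particle$diam) + 5 * m(sl$fragments$diam[1]),
               m(15e-6), tolerance = 1e-12)
  expect_equal(sl$particle$status, "dead_attached")
})

test_that("well walls reflect specularly without trapping", {
  well <- well_domain(NULL)
  # normal incidence on the flat bottom
  r <- reflect_well_wall(c(5.5e-3, 5.5e-3, 0), c(0, 0, -0.1), well)
  expect_equal(r$velocity, c(0, 0, 0.1))
  # tangential component unchanged on the cylinder wall
  pos <- c(11e-3, 5.5e-3, 7e-3) # on the wall, +x side
  r2 <- reflect_well_wall(pos, c(0.05, 0.02, -0.01), well)
  expect_equal(r2$velocity[2], 0.02)
  expect_equal(r2$velocity[3], -0.01)
  expect_equal(r2$velocity[1], -0.05)
  # partial restitution
  r3 <- reflect_well_wall(c(5.5e-3, 5.5e-3, 0), c(0, 0, -0.1), well,
                          restitution = 0.5)
  expect_equal(r3$velocity[3], 0.05)
})

test_that("compiled impingement agrees with the reference formulas", {
  # a solid slab occupying the upper half of the occupancy grid; one
  # particle fired straight up at it in still fluid
  dims <- c(20L, 20L, 20L)
  occ_arr <- array(0L, dims)
  occ_arr[, , 11:20] <- 1L
  eng <- bare_engine(occ_dims = dims, occ = as.raw(occ_arr),
                     params = list(rho_cell = 1e9, g = 0, prewet_h = 0))
  fl <- still_flow(grid_n = 8)
  ps <- new_particle_set()
  v0 <- 0.04
  add_particles(ps, matrix(c(4.25e-3, 4.25e-3, 1e-4), 1),
                matrix(c(0, 0, v0), 1), 15e-6)
  ev <- step_particles(ps, fl, eng, 0, 0.05)
  expect_equal(nrow(ev), 1)
  # impact speed = v0 minus the (tiny) drag decay over the step
  expect_equal(ev$v_pn, v0, tolerance = 5e-3)
  Re <- particle_reynolds(fluid_properties(), ev$v_pn, 15e-6)
  E_ref <- impact_energy(1000, ev$v_pn, 15e-6, 0.03, h_o = 0,
                         delta_bl = boundary_layer_thickness(15e-6, Re))
  expect_equal(ev$E, E_ref, tolerance = 1e-9)
  expect_equal(as.character(ev$regime),
               as.character(classify_regime(E_ref)))
  expect_equal(ps$status[1], 1L) # stuck, zero velocity, below the slab
  expect_equal(ps$vz[1], 0)
  expect_lte(ps$z[1], 0.25e-3 * 10 + 1e-6)
})

test_that("forced splash conserves mass and emits six equal drops", {
  dims <- c(20L, 20L, 20L)
  occ_arr <- array(0L, dims)
  occ_arr[, , 11:20] <- 1L
  eng <- bare_engine(occ_dims = dims, occ = as.raw(occ_arr),
                     params = list(rho_cell = 1e9, g = 0, e_stick = 1e-9,
                                   e_splash = 1e-8))
  fl <- still_flow(grid_n = 8)
  cellp <- cell_properties()
  ps <- new_particle_set()
  set.seed(5)
  add_particles(ps, matrix(c(4.25e-3, 4.25e-3, 1e-4), 1),
                matrix(c(0, 0, 0.04), 1), cellp$d_cell)
  m0 <- sum(particle_mass_by_status(ps, cellp))
  ev <- step_particles(ps, fl, eng, 0, 0.05)
  expect_equal(as.character(ev$regime), "splash")
  expect_equal(length(ps$x), 6) # parent piece + 5 airborne fragments
  expect_equal(sum(ps$status == 3L), 1)
  expect_equal(sum(ps$status == 4L), 5)
  expect_true(all(abs(ps$diam - cellp$d_cell / 6^(1 / 3)) < 1e-12))
  m1 <- sum(particle_mass_by_status(ps, cellp))
  expect_equal(m1, m0, tolerance = 1e-12)
})

test_that("hot walls rebound cells instead of capturing them", {
  dims <- c(20L, 20L, 20L)
  occ_arr <- array(0L, dims)
  occ_arr[, , 11:20] <- 1L
  eng <- bare_engine(occ_dims = dims, occ = as.raw(occ_arr),
                     params = list(rho_cell = 1e9, g = 0, T_wall = 400,
                                   restitution_n = 0.9))
  fl <- still_flow(grid_n = 8)
  ps <- new_particle_set()
  add_particles(ps, matrix(c(4.25e-3, 4.25e-3, 1e-4), 1),
                matrix(c(0, 0, 0.04), 1), 15e-6)
  ev <- step_particles(ps, fl, eng, 0, 0.005)
  expect_equal(as.character(ev$regime), "rebound")
  expect_equal(ps$status[1], 0L)
  expect_equal(ps$vz[1], -0.9 * ev$v_pn, tolerance = 1e-9)
})
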