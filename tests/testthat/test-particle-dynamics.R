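# Drag law, relaxation time, exponential integrator, injection bookkeeping.

fluid <- fluid_properties()
cell <- cell_properties()

test_that("particle Reynolds number is linear in slip speed", {
  expect_equal(particle_reynolds(fluid, 0.01, 15e-6), 0.15)
  expect_equal(particle_reynolds(fluid, 0, 15e-6), 0)
  expect_equal(particle_reynolds(fluid, 0.02, 15e-6),
               2 * particle_reynolds(fluid, 0.01, 15e-6))
  expect_error(particle_reynolds(fluid, 1, 0), "diameter")
})

test_that("drag coefficient follows the piecewise sphere bands", {
  expect_equal(drag_coefficient(0.05), 24 / 0.05) # Stokes band
  # C_D * Re -> 24 as Re -> 0
  Re <- 10^seq(-6, -2, by = 1)
  expect_true(all(abs(drag_coefficient(Re) * Re - 24) < 1e-9))
  # monotone decreasing through the sub-laminar range
  Re <- 10^seq(-3, 2, length.out = 200)
  expect_true(all(diff(drag_coefficient(Re)) < 0))
  expect_error(drag_coefficient(0), "Stokes")
})

test_that("relaxation time reduces to the Stokes formula", {
  tau <- relaxation_time(cell, fluid, Re = 0)
  stokes <- cell$rho_cell * cell$d_cell^2 / (18 * fluid$mu)
  expect_equal(tau, stokes, tolerance = 1e-13)
  expect_equal(stokes, 1.25e-5)
  # the band formula with C_D Re = 24 is algebraically the Stokes formula
  Re <- 0.5
  CD <- 24 / Re # pretend Stokes band
  expect_equal(4 * cell$rho_cell * cell$d_cell^2 / (3 * fluid$mu * CD * Re),
               stokes, tolerance = 1e-13)
  # tau ~ d^2 at fixed band
  c2 <- cell_properties(d_cell = 30e-6)
  expect_equal(relaxation_time(c2, fluid, 0) / tau, 4, tolerance = 1e-12)
})

test_that("exponential drag integrator matches the closed-form decay", {
  tau <- relaxation_time(cell, fluid, 0)
  v0 <- c(0.005, 0, 0) # Re = 0.075: inside the Stokes band throughout
  dt <- tau / 3
  pos <- c(0, 0, 0); v <- v0
  for (i in 1:30) {
    st <- step_particle(pos, v, c(0, 0, 0), cell, fluid, dt,
                        gravity = FALSE)
    pos <- st$position; v <- st$velocity
    expect_equal(v[1], v0[1] * exp(-i * dt / tau), tolerance = 1e-6)
  }
})

test_that("neutrally buoyant particles feel no gravity, dense ones settle", {
  st <- step_particle(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), cell, fluid, 1)
  expect_equal(st$velocity, c(0, 0, 0)) # rho_cell == rho_fluid
  dense <- cell_properties(rho_cell = 1100)
  tau_d <- relaxation_time(dense, fluid, 0)
  vterm <- fluid$g * tau_d * (dense$rho_cell - fluid$rho_fluid) /
    dense$rho_cell
  st <- step_particle(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), dense, fluid,
                      5 * tau_d)
  expect_equal(-st$velocity[3], vterm, tolerance = 0.01)
  # relaxation toward a uniform stream
  st <- step_particle(c(0, 0, 0), c(0, 0, 0), c(0.01, 0, 0), cell, fluid,
                      20 * relaxation_time(cell, fluid, 0), gravity = FALSE)
  expect_equal(st$velocity[1], 0.01, tolerance = 1e-8)
})

test_that("injection count is exact over the full window", {
  fl <- small_flow(grid_n = 16)
  spec <- injection_spec() # 8.18e-10 kg/s for 5 s
  carry <- new.env(); carry$carry <- 0
  ps <- new_particle_set()
  dt <- 0.01
  for (s in seq_len(600)) { # 6 s > duration
    inject_cells(spec, cell, fl, ps, (s - 1) * dt, dt, carry_env = carry)
  }
  m_cell <- cell$rho_cell * pi / 6 * cell$d_cell^3
  expected_total <- spec$mass_flow_rate * spec$duration / m_cell
  n <- length(ps$x)
  expect_equal(n, floor(expected_total))
  expect_equal(n + carry$carry, expected_total, tolerance = 1e-9)
  expect_equal(n, 2314) # ~2.3e3 cells at the reference injection rate
  # all released on the inlet disk, inside the well
  expect_true(all(ps$z > 0 & ps$z < 0.015))
  # zero rate injects nothing
  ps0 <- new_particle_set()
  inject_cells(injection_spec(0, 5), cell, fl, ps0, 0, 1)
  expect_equal(length(ps0$x), 0)
})

test_that("random-walk kicks are zero-mean with the configured variance", {
  expect_equal(random_walk_kick(5, 0), matrix(0, 5, 3))
  set.seed(42)
  k <- random_walk_kick(1e5, 0.01)
  expect_lt(abs(mean(k)), 3 * 0.01 / sqrt(3e5))
  expect_equal(var(as.numeric(k)), 1e-4, tolerance = 3 * sqrt(2 / 3e5))
})

test_that("tracked particles are passive tracers at these Stokes numbers", {
  fl <- still_flow(grid_n = 8)
  fl$u[] <- 0.01
  eng <- bare_engine()
  ps <- new_particle_set()
  add_particles(ps, matrix(c(2e-3, 5.5e-3, 7e-3), 1), matrix(0, 1, 3),
                cell$d_cell)
  step_particles(ps, fl, eng, 0, 1e-3)
  expect_equal(ps$vx[1], 0.01, tolerance = 1e-6) # fully relaxed in one step
  expect_equal(ps$x[1], 2e-3 + 0.01 * 1e-3, tolerance = 1e-6)
})

test_that("particles never escape the well (reflecting boundaries)", {
  fl <- still_flow(grid_n = 8)
  eng <- bare_engine()
  set.seed(7)
  n <- 300
  ps <- new_particle_set()
  pos <- cbind(runif(n, 3e-3, 8e-3), runif(n, 3e-3, 8e-3),
               runif(n, 1e-3, 14e-3))
  # big random velocities and a still fluid: pure ballistic bouncing
  vel <- matrix(runif(3 * n, -0.5, 0.5), n)
  heavy <- cell_properties(rho_cell = 1e9) # huge tau: keeps its velocity
  add_particles(ps, pos, vel, heavy$d_cell)
  eng$params$rho_cell <- 1e9
  for (s in 1:50) step_particles(ps, fl, eng, s * 1e-3, 1e-3)
  r <- sqrt((ps$x - 5.5e-3)^2 + (ps$y - 5.5e-3)^2)
  expect_true(all(r <= 5.5e-3 + 1e-9))
  expect_true(all(ps$z >= -1e-9 & ps$z <= 0.015 + 1e-9))
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  run_once <- function() {
    set.seed(123)
    fl <- small_flow(grid_n = 12)
    eng <- bare_engine(params = list(drw_rms = 0.005))
    ps <- new_particle_set()
    add_particles(ps, matrix(c(3e-3, 5e-3, 8e-3), 1), matrix(0, 1, 3),
                  15e-6)
    for (s in 1:20) {
      advance_flow(fl, 2e-3)
      step_particles(ps, fl, eng, s * 2e-3, 2e-3)
    }
    c(ps$x, ps$y, ps$z, ps$vx, ps$vy, ps$vz)
  }
  expect_identical(run_once(), run_once())
})
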