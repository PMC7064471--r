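# Filling flow solver: initial conditions, conservation, projection.

test_that("initial state is dry and at rest, grid spacing as designed", {
  fl <- still_flow(grid_n = 64)
  expect_equal(total_liquid_volume(fl), 0)
  expect_true(all(fl$u == 0) && all(fl$v == 0) && all(fl$w == 0))
  # 64 cells over the 15 mm well depth ~ 0.23 mm
  expect_equal(fl$spacing[3], 0.015 / 64)
})

test_that("zero inflow leaves the trivial rest state unchanged", {
  fl <- still_flow(grid_n = 12)
  advance_flow(fl, 1e-3)
  expect_true(all(fl$u == 0) && all(fl$w == 0))
  expect_equal(total_liquid_volume(fl), 0)
})

test_that("inlet rate converts volume and duration as specified", {
  fl <- small_flow(grid_n = 16)
  inlet_flow(fl, 0.5e-6 / 3, 3) # 0.5 ml over 3 s
  expect_equal(fl$inlet_rate, 1.666667e-7, tolerance = 1e-6)
  area <- length(fl$inlet_idx) * fl$spacing[2] * fl$spacing[3]
  expect_equal(fl$u_in * area, fl$inlet_rate, tolerance = 1e-12)
  # zero-duration injection admits no liquid
  fl0 <- small_flow(grid_n = 16)
  inlet_flow(fl0, 1e-7, 0)
  for (i in 1:20) advance_flow(fl0, 2e-3)
  expect_equal(total_liquid_volume(fl0), 0)
})

test_that("liquid volume tracks the injected volume within 1 percent", {
  fl <- small_flow(grid_n = 24)
  for (i in 1:250) advance_flow(fl, 2e-3) # 0.5 s of filling
  inj <- fl$injected_volume
  expect_equal(inj, 1e-7 * 0.5, tolerance = 0.01)
  expect_equal(total_liquid_volume(fl), inj, tolerance = 0.01)
  expect_true(all(fl$alpha >= 0 & fl$alpha <= 1))
})

test_that("projection drives the divergence down every step", {
  fl <- small_flow(grid_n = 24)
  for (i in 1:30) {
    advance_flow(fl, 2e-3)
    d <- fl$last_diag
    expect_lt(d$div_after, 1e-3 * max(d$div_before, 1e-12) + 1e-8)
  }
  expect_lt(fl$last_diag$relres, fl$cg_tol)
})

test_that("solid cells never acquire velocity", {
  sc <- coarse_cubic_scaffold()
  fl <- init_flow(well_domain(sc), grid_n = 32)
  inlet_flow(fl, 1e-7, 5)
  for (i in 1:25) advance_flow(fl, 2e-3)
  # faces adjacent to solid cells on both sides are zero
  n <- fl$dims
  solid <- fl$flag != 0L
  both <- solid[-n[1], , ] & solid[-1, , ]
  expect_true(all(fl$u[-c(1, n[1] + 1), , ][both] == 0))
})

test_that("velocity sampling is exact on nodes and linear between them", {
  fl <- still_flow(grid_n = 8)
  fl$u[] <- 0.01 # uniform x velocity
  mid <- c(0.0055, 0.0055, 0.0075)
  expect_equal(sample_velocity(fl, mid)[1, ], c(0.01, 0, 0))
  # linear profile in x: u(x) = x / L * 0.02
  nx <- fl$dims[1]
  xs <- (0:nx) * fl$spacing[1]
  for (k in seq_len(fl$dims[3])) for (j in seq_len(fl$dims[2]))
    fl$u[, j, k] <- xs / max(xs) * 0.02
  p1 <- c(xs[3], 0.0055, 0.0075)
  p2 <- c(xs[4], 0.0055, 0.0075)
  vmidp <- sample_velocity(fl, (p1 + p2) / 2)[1, 1]
  v1 <- sample_velocity(fl, p1)[1, 1]
  v2 <- sample_velocity(fl, p2)[1, 1]
  expect_equal(vmidp, (v1 + v2) / 2, tolerance = 1e-12)
  expect_error(sample_velocity(fl, c(-1, 0, 0)), "outside")
})

test_that("refining the grid self-converges the filling velocity field", {
  err <- sapply(c(8, 16, 32), function(n) {
    fl <- small_flow(grid_n = n)
    for (i in 1:50) advance_flow(fl, 2e-3) # 0.1 s
    pts <- as.matrix(expand.grid(x = seq(2e-3, 9e-3, length.out = 6),
                                 y = seq(2e-3, 9e-3, length.out = 6),
                                 z = seq(2e-3, 13e-3, length.out = 6)))
    sample_velocity(fl, pts)
  }, simplify = FALSE)
  d12 <- sqrt(mean((err[[1]] - err[[2]])^2))
  d23 <- sqrt(mean((err[[2]] - err[[3]])^2))
  expect_lt(d23, d12) # coarse-to-fine differences shrink
})

test_that("VTK snapshots carry the advertised fields", {
  fl <- small_flow(grid_n = 8)
  for (i in 1:5) advance_flow(fl, 2e-3)
  path <- tempfile(fileext = ".vtk")
  write_vtk(fl, path)
  txt <- readLines(path)
  expect_true(any(grepl("STRUCTURED_POINTS", txt)))
  expect_true(any(grepl("SCALARS alpha", txt)))
  expect_true(any(grepl("VECTORS velocity", txt)))
  expect_true(any(grepl(sprintf("CELL_DATA %d", prod(fl$dims)), txt)))
})
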