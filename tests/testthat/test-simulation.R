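# Coupled driver at reduced scale: bookkeeping invariants that must hold
# regardless of grid resolution.

small_run <- function() {
  fixture("small_run", function() {
    run_seeding(seeding_config("cubic", grid_n = 24, t_end = 0.6,
                               dt = 2.5e-3, voxel = 0.05, seed = 42,
                               record_every = 20))
  })
}

test_that("a reduced run injects, attaches and conserves mass", {
  res <- small_run()
  last <- res$series[nrow(res$series), ]
  expect_gt(last$injected, 100)
  expect_gt(last$attached_live, 0)
  # every particle is accounted for
  expect_equal(last$attached_live + last$dead_attached +
                 last$fragments_mobile + last$suspended,
               nrow(res$particles))
  # injected mass equals the mass held by all particles (machine precision)
  cellp <- cell_properties()
  m_cell <- cellp$rho_cell * pi / 6 * cellp$d_cell^3
  expect_equal(sum(res$mass), last$injected * m_cell,
               tolerance = 1e-12)
})

test_that("attachment and efficiency are monotone without detachment", {
  res <- small_run()
  expect_true(all(diff(res$series$attached_live) >= 0))
  expect_true(all(diff(res$series$efficiency /
                         pmax(res$series$injected, 1)) >= -1e-12 |
                  diff(res$series$attached_live) >= 0))
  expect_true(all(res$series$efficiency >= 0 &
                  res$series$efficiency <= 100))
})

test_that("culture-temperature runs stick or spread only", {
  res <- small_run()
  expect_true(all(res$events$regime %in% c("stick", "spread")))
  expect_equal(sum(res$events$regime == "splash"), 0)
  expect_equal(sum(res$events$regime == "rebound"), 0)
})

test_that("bin counts partition the attached population", {
  res <- small_run()
  b <- lateral_bin_counts(res$particles, origin = res$scaffold_origin[1])
  last <- res$series[nrow(res$series), ]
  expect_equal(sum(b$live) + sum(b$dead) + attr(b, "overflow"),
               last$attached_live + last$dead_attached)
})

test_that("the same seed reproduces the run exactly", {
  cfg <- seeding_config("cubic", grid_n = 16, t_end = 0.2, dt = 2.5e-3,
                        voxel = 0.1, seed = 7, record_every = 20)
  r1 <- run_seeding(cfg)
  r2 <- run_seeding(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$particles, r2$particles)
})

test_that("results export to the documented CSV schema", {
  res <- small_run()
  dir <- tempfile()
  write_results_csv(res, dir)
  r <- read.csv(file.path(dir, "results.csv"))
  expect_identical(names(r), c("t", "N_i", "N_a", "Phi_pct", "dead"))
  b <- read.csv(file.path(dir, "bins.csv"))
  expect_identical(names(b), c("bin_lo_mm", "bin_hi_mm", "live", "dead"))
  e <- read.csv(file.path(dir, "events.csv"))
  expect_identical(names(e),
                   c("t", "particle_id", "E", "regime", "element_id"))
  expect_equal(nrow(read.csv(file.path(dir, "particles.csv"))),
               nrow(res$particles))
})
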