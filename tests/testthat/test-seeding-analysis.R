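# Efficiency, lateral bins, replicate comparisons.

test_that("seeding efficiency is the attached percentage", {
  expect_equal(seeding_efficiency(100, 200), 50)
  expect_equal(seeding_efficiency(0, 10), 0)
  expect_equal(seeding_efficiency(10, 10), 100)
  expect_error(seeding_efficiency(1, 0), "n_injected")
  expect_error(seeding_efficiency(-1, 10))
})

make_particles <- function(x_mm, status) {
  data.frame(x = x_mm / 1000, status = factor(
    status, levels = c("suspended", "attached", "attached_spread",
                       "dead_attached", "fragment")))
}

test_that("lateral bins are half-open from the injection side", {
  p <- make_particles(c(0, 0, 0), rep("attached", 3))
  b <- lateral_bin_counts(p)
  expect_equal(b$live, c(3, 0, 0, 0, 0, 0))
  # a particle exactly on the 1.3 mm edge belongs to bin 2
  p2 <- make_particles(1.3, "attached")
  expect_equal(lateral_bin_counts(p2)$live, c(0, 1, 0, 0, 0, 0))
  # dead and live are tallied separately; suspended cells are ignored
  p3 <- make_particles(c(0.5, 0.5, 2.0), c("attached", "dead_attached",
                                           "suspended"))
  b3 <- lateral_bin_counts(p3)
  expect_equal(sum(b3$live), 1)
  expect_equal(sum(b3$dead), 1)
  # outside the last edge counts as overflow, reported not dropped
  p4 <- make_particles(9.9, "attached")
  b4 <- lateral_bin_counts(p4)
  expect_equal(sum(b4$live), 0)
  expect_equal(attr(b4, "overflow"), 1)
  expect_error(lateral_bin_counts(p, bin_edges = c(0, 1, 1)), "increasing")
})

test_that("uniform attachment spreads evenly over the six bins", {
  set.seed(11)
  p <- make_particles(runif(600, 0, 7.8), rep("attached", 600))
  b <- lateral_bin_counts(p)
  expect_equal(sum(b$live), 600)
  # each bin ~ 100 with Poisson noise
  expect_true(all(abs(b$live - 100) < 4 * sqrt(100)))
})

test_that("replicate comparison behaves like a Welch t test", {
  same <- compare_bins(c(5, 5, 5) + c(-1e-9, 0, 1e-9), c(5, 5, 5) + c(0, 1e-9, -1e-9))
  expect_gt(same$p_value, 0.9)
  id <- compare_bins(c(5, 5, 5), c(5, 5, 5))
  expect_equal(id$p_value, 1)
  jit <- c(-1e-3, 0, 1e-3)
  far <- compare_bins(c(0, 0, 0) + jit, c(10, 10, 10) + jit)
  expect_lt(far$p_value, 0.001)
  sw <- compare_bins(c(10, 10, 10) + jit, c(0, 0, 0) + jit)
  expect_equal(far$p_value, sw$p_value)
  expect_error(compare_bins(c(1, 1), c(2, 2)), "degenerate")
  expect_error(compare_bins(1, c(1, 2)), "replicates")
})

test_that("efficiency curve is flat zero without attachments", {
  fake <- list(series = data.frame(t = seq(0.1, 1, by = 0.1),
                                   efficiency = 0))
  ec <- efficiency_curve(fake)
  expect_true(all(ec$efficiency == 0))
  expect_true(is.na(attr(ec, "plateau_onset")))
  expect_equal(attr(ec, "steady_value"), 0)
})

test_that("plateau detection finds where the slope falls off", {
  tt <- seq(0.1, 3, by = 0.1)
  phi <- pmin(40, 40 * tt / 1) # rises to 2 %/s * 40... saturates at t=1
  fake <- list(series = data.frame(t = tt, efficiency = phi))
  ec <- efficiency_curve(fake, dphi_threshold = 1, window = 0.2)
  onset <- attr(ec, "plateau_onset")
  expect_gte(onset, 1.0)
  expect_lte(onset, 1.4)
  expect_equal(attr(ec, "steady_value"), 40)
})
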