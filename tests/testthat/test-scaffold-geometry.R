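# Lattice construction and geometric metrics.

test_that("pore diagonal follows square / hexagon geometry", {
  expect_equal(round(pore_diagonal("square", 1000)), 1414)
  expect_equal(pore_diagonal("hexagon", 240), 480)
  expect_equal(pore_diagonal("square", 1), sqrt(2))
  expect_error(pore_diagonal("triangle", 1))
  expect_error(pore_diagonal("square", -1), "side")
})

test_that("porosity and SA:V arithmetic validate their inputs", {
  expect_equal(porosity_pct(0, 10), 100)
  expect_equal(porosity_pct(10, 10), 0)
  expect_error(porosity_pct(5, 0), "V_overall")
  expect_error(porosity_pct(11, 10))
  expect_equal(sa_to_v(6, 1), 6)
  expect_error(sa_to_v(6, 0))
})

test_that("unit cell specs reject impossible dimensions", {
  expect_error(unit_cell_spec("cubic", strut_diameter = 0), "lengths")
  expect_error(unit_cell_spec("cubic", pore_side = -5), "lengths")
  expect_error(unit_cell_spec("truncated_octahedron", wall_offset = 0),
               "wall_offset")
  expect_error(unit_cell_spec("cubic", wall_offset = 0.1), "wall_offset")
  expect_equal(unit_cell_spec("cubic")$pitch, 1.5)
})

test_that("cubic unit cell has the designed window and strut sections", {
  cell <- coarse_cubic_cell()
  occ <- scaffseed:::.occupancy_array(cell)
  h <- cell$voxel
  # mid-height slice holds only the four corner quarter-struts of the
  # z-family: solid area = pi r^2
  k <- round(dim(occ)[3] / 2)
  slice_area <- sum(occ[, , k]) * h^2
  expect_lt(abs(slice_area - pi * 0.25^2) / (pi * 0.25^2), 0.05)
  # window: along the cell face (x = 0 strut plane) the open gap between
  # the two corner strut surfaces spans pore_side = 1 mm
  run <- rle(occ[1, , k])
  gap_mm <- max(run$lengths[!run$values]) * h
  expect_lt(abs(gap_mm - 1.0), 3 * h)
  # porosity strictly between 0 and 100
  met <- measure_geometry(cell)
  expect_gt(met$porosity, 0)
  expect_lt(met$porosity, 100)
})

test_that("TO unit cell matches hexagonal pore bookkeeping", {
  cell <- coarse_to_cell()
  met <- measure_geometry(cell)
  expect_gt(met$porosity, 50)
  expect_lt(met$porosity, 100)
  expect_equal(met$max_pore_side, 240)
  expect_equal(met$max_pore_diagonal, 480)
  # cell centre lies in the open interior, strut axis inside solid
  p <- cell$spec$pitch
  expect_gt(scaffold_sdf(cell, c(p, p, p) / 2), 0)
})

test_that("tiling is periodic and clips at the box", {
  cell <- coarse_cubic_cell()
  p <- cell$spec$pitch
  # 1x1x1 tiling with the cell's own alignment reproduces the cell
  tiled <- tile_scaffold(cell, bounding_box = c(p, p, p),
                         offset = 0, offset_z = 0)
  expect_identical(tiled$occupancy, cell$occupancy)
  # porosity of an untruncated periodic block matches the unit cell
  block <- tile_scaffold(cell, bounding_box = c(2 * p, 2 * p, 2 * p),
                         offset = 0, offset_z = 0)
  expect_lt(abs(measure_geometry(block)$porosity -
                measure_geometry(cell)$porosity), 1.0)
  expect_error(tile_scaffold(cell, bounding_box = c(0.1, 0.1, 0.1)),
               "empty")
})

test_that("cubic scaffold shows 5 full windows across its width", {
  sc <- coarse_cubic_scaffold()
  occ <- scaffseed:::.occupancy_array(sc)
  h <- sc$voxel
  # a line along x through a z-strut column (y = 1.25 mm) between the
  # horizontal strut planes (z = 0.75 mm)
  j <- round(1.25 / h); k <- round(0.75 / h)
  run <- rle(occ[, j, k])
  gaps <- run$lengths[!run$values] * h
  expect_equal(sum(gaps >= 0.95), 5)        # five full 1-mm windows
  expect_equal(sum(gaps > 0.2 & gaps < 0.95), 1) # one clipped partial
})

test_that("scaling a primitive scales V by k^3 and S by k^2", {
  meas <- function(r, h, vox) {
    spec <- list(design_code = 2L, radius = r, bbox = c(4 * r, 4 * r, h),
                 center = c(2 * r, 2 * r, 0), cyl_z0 = 0, cyl_h = h)
    scaffseed:::.cpp_voxelize_metrics(spec, vox, TRUE, FALSE)
  }
  m1 <- meas(0.25, 1, 0.02)
  m2 <- meas(0.50, 2, 0.04) # same relative resolution, k = 2
  expect_lt(abs(m2$V / m1$V - 8) / 8, 0.02)
  expect_lt(abs(m2$S / m1$S - 4) / 4, 0.02)
})

test_that("geometry metrics round-trip through the CSV export", {
  sc <- coarse_cubic_scaffold()
  met <- measure_geometry(sc)
  path <- tempfile(fileext = ".csv")
  df <- write_metrics_csv(met, path)
  back <- read.csv(path)
  expect_equal(back$V_mm3, met$V_structure, tolerance = 1e-8)
  expect_equal(back$sa_to_v_per_mm, met$sa_to_v, tolerance = 1e-8)
  expect_identical(names(back),
                   c("design", "V_mm3", "S_mm2", "porosity_pct",
                     "sa_to_v_per_mm", "pore_side_um", "pore_diag_um"))
})
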