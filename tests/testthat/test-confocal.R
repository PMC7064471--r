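# Synthetic confocal images and the grid-count pipeline.

scatter_cells <- function(n, w = 240, h = 240, margin = 16, seed = 1) {
  # non-overlapping centres on a jittered grid, in um (1 um/px default)
  set.seed(seed)
  gx <- seq(margin, w - margin, by = 24)
  gy <- seq(margin, h - margin, by = 24)
  grid <- as.matrix(expand.grid(gx, gy))
  idx <- sample(nrow(grid), n)
  grid[idx, , drop = FALSE] + matrix(runif(2 * n, -4, 4), n)
}

test_that("image synthesis is deterministic and channel-correct", {
  pos <- scatter_cells(5)
  st <- c("live", "live", "dead", "live", "dead")
  img1 <- synthesize_confocal(pos, st, seed = 99)
  img2 <- synthesize_confocal(pos, st, seed = 99)
  expect_identical(img1$green, img2$green)
  expect_identical(img1$red, img2$red)
  # spots land in the matching channel
  expect_gt(max(img1$green), 0.5)
  expect_gt(max(img1$red), 0.5)
})

test_that("an empty field yields no detections above threshold", {
  img <- synthesize_confocal(matrix(numeric(0), 0, 2), character(0),
                             image_size = c(128, 128), noise_sd = 0.02,
                             seed = 3)
  # threshold at 5 sigma over the noise floor: nothing survives
  masks <- split_and_clean(img, threshold = 5 * 0.02 + 0.02)
  counts <- count_by_grid(masks$green)
  expect_equal(sum(counts$count), 0)
})

test_that("a single live cell produces exactly one green component", {
  img <- synthesize_confocal(matrix(c(100, 120), 1), "live",
                             image_size = c(240, 240), seed = 4)
  df <- count_cells(img)
  expect_equal(sum(df$live), 1)
  expect_equal(sum(df$dead), 0)
})

test_that("morphology with zero radii is the identity on the mask", {
  img <- synthesize_confocal(scatter_cells(4), rep("live", 4), seed = 5,
                             noise_sd = 0)
  m0 <- split_and_clean(img, threshold = 0.5, erode_px = 0, dilate_px = 0)
  expect_identical(m0$green, (img$green > 0.5) * 1)
})

test_that("erosion removes specks and splits bridged cells", {
  # two disks joined by a thin 2-px isthmus, plus a lone 2-px speck
  w <- 120
  mat <- matrix(0, w, w)
  disk <- function(cx, cy, r) {
    for (x in (cx - r):(cx + r)) for (y in (cy - r):(cy + r))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) mat[x, y] <<- 1
  }
  disk(40, 60, 8); disk(70, 60, 8)
  mat[48:62, 60:61] <- 1          # bridge
  mat[100, 100] <- 1; mat[101, 100] <- 1 # speck
  img <- two_channel_image(mat, matrix(0, w, w))
  masks <- split_and_clean(img, threshold = 0.5, erode_px = 2,
                           dilate_px = 3)
  counts <- count_by_grid(masks$green, grid_rows = 1)
  expect_equal(counts$count, 2) # bridge cut, speck erased
})

test_that("grid counts recover generator ground truth by row", {
  n <- 60
  pos <- scatter_cells(n, seed = 8)
  # keep centres clear of row boundaries (rows of 40 px) so truth rows
  # are unambiguous against +/- 1 px centroid shifts
  row_w <- 240 / 6
  ok <- abs((pos[, 1] %% row_w) - row_w / 2) < row_w / 2 - 6
  pos <- pos[ok, , drop = FALSE]
  n <- nrow(pos)
  st <- rep(c("live", "dead"), length.out = n)
  img <- synthesize_confocal(pos, st, image_size = c(240, 240),
                             noise_sd = 0.01, seed = 8)
  df <- count_cells(img, grid_rows = 6)
  expect_equal(sum(df$live), sum(st == "live"))
  expect_equal(sum(df$dead), sum(st == "dead"))
  rows <- pmin(floor(pos[, 1] / 240 * 6), 5) + 1
  expect_equal(df$live, tabulate(rows[st == "live"], 6))
  expect_equal(df$dead, tabulate(rows[st == "dead"], 6))
})

test_that("adding dead cells never changes the live counts", {
  pos <- scatter_cells(20, seed = 9)
  img_a <- synthesize_confocal(pos[1:10, ], rep("live", 10),
                               image_size = c(240, 240), noise_sd = 0,
                               seed = 10)
  img_b <- synthesize_confocal(pos, c(rep("live", 10), rep("dead", 10)),
                               image_size = c(240, 240), noise_sd = 0,
                               seed = 10)
  a <- count_cells(img_a, threshold = 0.3)
  b <- count_cells(img_b, threshold = 0.3)
  expect_equal(a$live, b$live)
  expect_equal(sum(b$dead), 10)
})

test_that("all centroids in the first row pile into row one", {
  mat <- matrix(0, 120, 120)
  mat[5:9, c(20, 60, 100)] <- 1
  counts <- count_by_grid(mat, grid_rows = 6)
  expect_equal(counts$count, c(3, 0, 0, 0, 0, 0))
  expect_equal(sum(counts$count), 3) # row sums = component count
  # inlet on the other side reverses the ordering
  rev <- count_by_grid(mat, grid_rows = 6, inlet_side = "right")
  expect_equal(rev$count, c(0, 0, 0, 0, 0, 3))
})

test_that("TIFF round trip preserves the counts", {
  pos <- scatter_cells(12, seed = 12)
  st <- rep(c("live", "dead"), 6)
  img <- synthesize_confocal(pos, st, image_size = c(240, 240),
                             noise_sd = 0.01, seed = 12)
  path <- tempfile(fileext = ".tif")
  write_confocal(img, path)
  back <- read_confocal(path)
  expect_equal(count_cells(back), count_cells(img))
})
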