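# Confocal-image cell counting: synthetic two-channel (live/dead) image
# generation, channel cleanup by thresholding + morphology, and grid-based
# row counts from the inlet side.  Built on EBImage.

#' Two-channel confocal-like image container
#'
#' @param green,red Numeric matrices of equal shape (live = Calcein-AM
#'   green channel, dead = PI red channel), intensities >= 0.
#' @param pixel_size Pixel edge in um.
#' @export
two_channel_image <- function(green, red, pixel_size = 1) {
  if (!all(dim(green) == dim(red))) stop("channel shapes differ")
  if (min(green) < 0 || min(red) < 0) stop("intensities must be >= 0")
  structure(list(green = green, red = red, pixel_size = pixel_size),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("Two-channel image %d x %d px (%g um/px)\n",
              nrow(x$green), ncol(x$green), x$pixel_size))
  invisible(x)
}

#' Synthesize a two-channel confocal-like image
#'
#' Gaussian bright spots on a dark background with additive Gaussian
#' noise; live cells render into the green channel, dead cells into the
#' red channel.  Deterministic for a fixed seed.
#'
#' @param positions n x 2 matrix of cell centres, um (x across the image
#'   width from the inlet side, y down the height).
#' @param statuses Character or factor: `"live"` or `"dead"` per cell.
#' @param image_size `c(width, height)` in pixels.
#' @param pixel_size um per pixel (default 1).
#' @param spot_radius Rendered cell radius in um (Gaussian sigma =
#'   radius/2; default 7.5, a 15-um cell).
#' @param noise_sd Additive Gaussian noise SD (default 0.02 on a unit
#'   intensity scale).
#' @param peak Peak spot intensity (default 1).
#' @param seed Optional RNG seed for reproducibility.
#' @return A [two_channel_image()].
#' @export
synthesize_confocal <- function(positions, statuses,
                                image_size = c(256, 256), pixel_size = 1,
                                spot_radius = 7.5, noise_sd = 0.02,
                                peak = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  positions <- rbind(positions)
  n <- nrow(positions)
  statuses <- as.character(statuses)
  if (n > 0 && length(statuses) != n) stop("one status per position")
  w <- image_size[1]; h <- image_size[2]
  green <- matrix(0, w, h); red <- matrix(0, w, h)
  sig <- spot_radius / (2 * pixel_size)
  half <- ceiling(4 * sig)
  for (m in seq_len(n)) {
    cxp <- positions[m, 1] / pixel_size + 0.5
    cyp <- positions[m, 2] / pixel_size + 0.5
    ix <- max(1, floor(cxp - half)):min(w, ceiling(cxp + half))
    iy <- max(1, floor(cyp - half)):min(h, ceiling(cyp + half))
    if (length(ix) == 0 || length(iy) == 0) next
    spot <- peak * outer(exp(-(ix - cxp)^2 / (2 * sig^2)),
                         exp(-(iy - cyp)^2 / (2 * sig^2)))
    if (statuses[m] == "dead") {
      red[ix, iy] <- red[ix, iy] + spot
    } else {
      green[ix, iy] <- green[ix, iy] + spot
    }
  }
  if (noise_sd > 0) {
    green <- green + matrix(abs(rnorm(w * h, sd = noise_sd)), w, h)
    red <- red + matrix(abs(rnorm(w * h, sd = noise_sd)), w, h)
  }
  two_channel_image(green, red, pixel_size)
}

#' Split channels and clean by threshold + morphology
#'
#' Per channel: intensity threshold (Otsu by default), then morphological
#' erosion (etches away sub-cell specks and thin adhesions bridging
#' neighbouring cells) followed by dilation (re-expands the detected cell
#' bodies).
#'
#' @param img A [two_channel_image()].
#' @param threshold `"otsu"` or a numeric threshold applied to both
#'   channels.
#' @param erode_px,dilate_px Disc radii in pixels (defaults 2 and 3).
#' @return List of binary masks `green` and `red` (matrices of 0/1).
#' @export
split_and_clean <- function(img, threshold = "otsu", erode_px = 2,
                            dilate_px = 3) {
  stopifnot(inherits(img, "two_channel_image"))
  if (erode_px < 0 || dilate_px < 0) stop("radii must be >= 0")
  clean1 <- function(ch) {
    mx <- max(ch)
    chn <- if (mx > 0) ch / mx else ch
    thr <- if (identical(threshold, "otsu")) {
      EBImage::otsu(EBImage::Image(chn), range = c(0, 1))
    } else threshold / max(mx, .Machine$double.eps)
    mask <- EBImage::Image(chn > thr)
    pre_n <- sum(mask)
    if (erode_px > 0)
      mask <- EBImage::erode(mask, EBImage::makeBrush(2 * erode_px + 1,
                                                      "disc"))
    if (pre_n > 0 && sum(mask) == 0)
      warning("erosion removed all foreground; counts will be 0")
    if (dilate_px > 0)
      mask <- EBImage::dilate(mask, EBImage::makeBrush(2 * dilate_px + 1,
                                                       "disc"))
    EBImage::imageData(mask) * 1
  }
  list(green = clean1(img$green), red = clean1(img$red))
}

#' Count detected cells per grid row from the inlet
#'
#' Connected components of the binary mask are located by their centroids
#' and assigned to `grid_rows` equal rows (half-open intervals) ordered
#' from the inlet side.
#'
#' @param mask Binary matrix (as from [split_and_clean()]).
#' @param grid_rows Number of rows (default 6).
#' @param inlet_side Side the inlet faces: `"left"` (x = first image
#'   axis increasing away from the inlet, default) or `"right"`.
#' @return Data frame `row, count` (class `grid_count_table`).
#' @export
count_by_grid <- function(mask, grid_rows = 6,
                          inlet_side = c("left", "right")) {
  inlet_side <- match.arg(inlet_side)
  if (grid_rows < 1) stop("grid_rows must be >= 1")
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  nobj <- max(lab)
  counts <- integer(grid_rows)
  if (nobj > 0) {
    labv <- as.integer(EBImage::imageData(lab))
    xs <- rep(seq_len(nrow(mask)), times = ncol(mask))
    cx <- vapply(seq_len(nobj), function(o) mean(xs[labv == o]), numeric(1))
    if (inlet_side == "right") cx <- nrow(mask) + 1 - cx
    row <- pmin(pmax(floor((cx - 0.5) / nrow(mask) * grid_rows), 0),
                grid_rows - 1) + 1
    counts <- tabulate(row, nbins = grid_rows)
  }
  structure(data.frame(row = seq_len(grid_rows), count = counts),
            class = c("grid_count_table", "data.frame"))
}

#' Full image-counting pipeline for both channels
#'
#' Split, clean, and grid-count live and dead channels; emits a table in
#' the same layout as the simulated lateral bins so imaged and simulated
#' distributions compare directly.
#'
#' @inheritParams split_and_clean
#' @inheritParams count_by_grid
#' @return Data frame `row, live, dead`.
#' @export
count_cells <- function(img, threshold = "otsu", erode_px = 2,
                        dilate_px = 3, grid_rows = 6,
                        inlet_side = "left") {
  masks <- split_and_clean(img, threshold, erode_px, dilate_px)
  g <- count_by_grid(masks$green, grid_rows, inlet_side)
  r <- count_by_grid(masks$red, grid_rows, inlet_side)
  data.frame(row = g$row, live = g$count, dead = r$count)
}

#' Read / write two-channel images
#'
#' TIFF (16-bit) or PNG (8-bit) via EBImage; channels are stored as the
#' first two frames (green, red).
#'
#' @param img A [two_channel_image()].
#' @param path File path (`.tif` or `.png`).
#' @param pixel_size um per pixel to attach on read.
#' @export
write_confocal <- function(img, path) {
  mx <- max(img$green, img$red, 1e-12)
  arr <- EBImage::Image(array(c(img$green / mx, img$red / mx),
                              dim = c(dim(img$green), 2)))
  EBImage::writeImage(arr, path,
                      type = if (grepl("\\.png$", path)) "png" else "tiff",
                      bits.per.sample = if (grepl("\\.png$", path)) 8L
                                        else 16L)
  invisible(path)
}

#' @rdname write_confocal
#' @export
read_confocal <- function(path, pixel_size = 1) {
  arr <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(arr)) == 2) {
    two_channel_image(arr, matrix(0, nrow(arr), ncol(arr)), pixel_size)
  } else {
    two_channel_image(arr[, , 1], arr[, , 2], pixel_size)
  }
}
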