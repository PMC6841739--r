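#' Image stacks
#'
#' A multi-frame grayscale image stack: brightness rescaled to `[0, 100]`,
#' square pixels of `pixel_size` micrometres (default 5), frames
#' `frame_interval` minutes apart (default 2). Internally an array
#' `[row, col, frame]`; pixel coordinates are 0-based with `x` = column
#' and `y` = row, pixel centres at integer coordinates, so micrometre
#' coordinates are `pixel * pixel_size`.
#'
#' @param frames numeric array `[height, width, n_frames]` in `[0, 100]`.
#' @param pixel_size um per pixel.
#' @param frame_interval min between frames.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size = 5, frame_interval = 2) {
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L) stop_("frames must be a h x w x n array")
  if (min(frames) < 0 || max(frames) > 100)
    stop_("brightness must lie in [0, 100]")
  if (pixel_size <= 0) stop_("pixel_size must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %dx%d px (%g um/px, every %g min), brightness [%.1f, %.1f]\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval,
              min(x$frames), max(x$frames)))
  invisible(x)
}

# radial brightness profile of one rendered nucleus: a flat dark core
# rising quartically to a bright rim at the nucleus radius, then blending
# back to background over half a radius.  The quartic keeps a several-pixel
# near-uniform dark core, which the threshold score S3 carves out for the
# weighted centroid.
blob_profile <- function(d, R, nucleus, rim, background) {
  b <- rep(background, length(d))
  core <- d <= R
  b[core] <- nucleus + (rim - nucleus) * (d[core] / R)^4
  edge <- d > R & d <= 1.5 * R
  b[edge] <- rim + (background - rim) * ((d[edge] - R) / (0.5 * R))
  b
}

#' Render a synthetic image stack from a trajectory table
#'
#' Draws, for each cell and frame, a radially symmetric nucleus: a dark
#' centre (phase-contrast nuclei image darker than the cell body) rising to
#' a brighter rim, on a mid-brightness background, plus independent
#' per-pixel Gaussian noise clipped to `[0, 100]`. All cells must share a
#' regular time grid; the grid spacing becomes the frame interval.
#'
#' @param traj a [trajectory_table()]; positions in um.
#' @param height,width image size in pixels.
#' @param blob list with `nucleus_radius` (um), `nucleus_brightness`,
#'   `rim_brightness`, `background` (brightness units, 0-100) and
#'   `noise_sd` (brightness units).
#' @param pixel_size um per pixel (default 5).
#' @param seed integer seed or NULL (noise only).
#' @return an [image_stack()].
#' @export
gen_image_stack <- function(traj, height = 120, width = 120,
                            blob = list(nucleus_radius = 20,
                                        nucleus_brightness = 5,
                                        rim_brightness = 90,
                                        background = 55,
                                        noise_sd = 0),
                            pixel_size = 5, seed = NULL) {
  times <- sort(unique(traj$t_min))
  cl <- split_cells(traj)
  for (tc in cl) {
    if (nrow(tc) != length(times) || any(abs(tc$t_min - times) > 1e-9))
      stop_("all cells must share one regular time grid for rendering")
  }
  R_px <- blob$nucleus_radius / pixel_size
  margin <- 1.5 * R_px
  n_f <- length(times)
  frames <- array(blob$background, dim = c(height, width, n_f))
  for (f in seq_len(n_f)) {
    img <- frames[, , f]
    for (tc in cl) {
      cx <- tc$x_um[f] / pixel_size          # 0-based pixel coords
      cy <- tc$y_um[f] / pixel_size
      if (cx < margin || cx > width - 1 - margin ||
          cy < margin || cy > height - 1 - margin)
        stop_("cell %s leaves the image bounds (margin %.1f px) at frame %d",
              tc$cell_id[1], margin, f)
      xs <- max(0, floor(cx - margin)):min(width - 1, ceiling(cx + margin))
      ys <- max(0, floor(cy - margin)):min(height - 1, ceiling(cy + margin))
      gx <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
      gy <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
      d <- sqrt((gx - cx)^2 + (gy - cy)^2)
      patch <- blob_profile(as.vector(d), R_px, blob$nucleus_brightness,
                            blob$rim_brightness, blob$background)
      img[cbind(as.vector(gy) + 1L, as.vector(gx) + 1L)] <- patch
    }
    frames[, , f] <- img
  }
  if ((blob$noise_sd %||% 0) > 0) {
    frames <- with_seed(seed,
      frames + rnorm(length(frames), sd = blob$noise_sd))
    frames[frames < 0] <- 0
    frames[frames > 100] <- 100
  }
  interval <- if (n_f > 1) diff(times[1:2]) else 2
  image_stack(frames, pixel_size = pixel_size, frame_interval = interval)
}

#' Read / write image stacks as multi-frame TIFF
#'
#' Brightness is stored as 16-bit values scaled from `[0, 100]` to
#' `[0, 1]`, single channel, one TIFF directory per frame. Pixel size and
#' frame interval are not stored in the file and must be supplied on read.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[3]
  imgs <- lapply(seq_len(n), function(f) stack$frames[, , f] / 100)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @param pixel_size,frame_interval metadata to attach on read.
#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, pixel_size = 5, frame_interval = 2) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  frames <- array(0, dim = c(nrow(imgs[[1]]), ncol(imgs[[1]]), length(imgs)))
  for (f in seq_along(imgs)) frames[, , f] <- imgs[[f]] * 100
  image_stack(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}
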