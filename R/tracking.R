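#' Tracker parameters
#'
#' Parameters of the weighted-centroid nucleus tracker: `sigma1` (px) sets
#' the width of the proximity score, `sigma2` (brightness units) the
#' darkness preference, `brightness_threshold` the exclusion of pixels
#' brighter than the previous nucleus centre by more than this amount, and
#' `cutoff` (um) the radius of the scoring window around the previous
#' position.
#'
#' @param sigma1 proximity score width (px, default 12).
#' @param sigma2 brightness score width (brightness units, default 10).
#' @param brightness_threshold outside-cell exclusion (default 10).
#' @param cutoff scoring window radius (um, default 50).
#' @param pixel_size um per pixel (default 5).
#' @param min_score numerical floor: scores below it are treated as zero,
#'   so a window containing no plausibly dark nucleus pixel (e.g. pure
#'   background, `S2 ~ exp(-30)`) registers as a lost track instead of
#'   averaging over vanishing weights. The default `1e-8` keeps every pixel
#'   within ~4 darkness sigmas while zeroing background.
#' @return list of class `tracker_params`.
#' @export
tracker_params <- function(sigma1 = 12, sigma2 = 10,
                           brightness_threshold = 10, cutoff = 50,
                           pixel_size = 5, min_score = 1e-8) {
  vals <- c(sigma1, sigma2, brightness_threshold, cutoff, pixel_size)
  if (any(vals <= 0)) stop_("all tracker parameters must be positive")
  if (min_score < 0) stop_("min_score must be >= 0")
  structure(list(sigma1 = sigma1, sigma2 = sigma2,
                 brightness_threshold = brightness_threshold,
                 cutoff = cutoff, pixel_size = pixel_size,
                 min_score = min_score),
            class = "tracker_params")
}

#' Score pixels around a previous cell position
#'
#' Evaluates the product score `S = S1 * S2 * S3` on every pixel within the
#' cutoff radius of the previous position: `S1 = exp(-d^2 / sigma1^2)`
#' (proximity; cells barely move between consecutive frames),
#' `S2 = exp(-f^2 / sigma2^2)` (darkness; the nucleus centre is the darkest
#' part of the cell), and `S3 = 0` where the pixel is brighter than the
#' previous centre pixel by more than the threshold (outside the cell),
#' else 1. Normalisation constants cancel in the weighted centroid and are
#' set to 1. Scores are zero outside the cutoff disc.
#'
#' @param frame brightness matrix (rows = y, cols = x), values in 0-100.
#' @param prev_pos previous position `c(x, y)` in 0-based pixel
#'   coordinates.
#' @param params a [tracker_params()].
#' @return object of class `score_field`: list with `score` (matrix over
#'   the window), `xs`, `ys` (0-based pixel coordinates of the window
#'   columns and rows) and `prev_pos`.
#' @export
score_pixels <- function(frame, prev_pos, params = tracker_params()) {
  h <- nrow(frame); w <- ncol(frame)
  x0 <- prev_pos[1]; y0 <- prev_pos[2]
  if (x0 < 0 || x0 > w - 1 || y0 < 0 || y0 > h - 1)
    stop_("prev_pos (%.1f, %.1f) lies outside the %dx%d frame", x0, y0, w, h)
  cut_px <- params$cutoff / params$pixel_size
  xs <- max(0, floor(x0 - cut_px)):min(w - 1, ceiling(x0 + cut_px))
  ys <- max(0, floor(y0 - cut_px)):min(h - 1, ceiling(y0 + cut_px))
  sub <- frame[ys + 1L, xs + 1L, drop = FALSE]
  gx <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  gy <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  d2 <- (gx - x0)^2 + (gy - y0)^2
  f0 <- frame[round(y0) + 1L, round(x0) + 1L]
  s1 <- exp(-d2 / params$sigma1^2)
  s2 <- exp(-sub^2 / params$sigma2^2)
  s3 <- (sub - f0 <= params$brightness_threshold) * 1
  score <- s1 * s2 * s3
  score[d2 > cut_px^2] <- 0
  score[score < (params$min_score %||% 0)] <- 0
  structure(list(score = score, xs = xs, ys = ys, prev_pos = prev_pos),
            class = "score_field")
}

#' Weighted centroid of a score field
#'
#' `x_hat = sum(x * S) / sum(S)` (and likewise y), reported to 1/10 pixel,
#' the first uncertain digit of the estimate. An all-zero field means the
#' track is lost (the cell moved beyond the cutoff or no pixel passed the
#' scores) and raises an error.
#'
#' @param field a `score_field` from [score_pixels()].
#' @return `c(x, y)` in 0-based pixel coordinates.
#' @export
weighted_centroid <- function(field) {
  stopifnot(inherits(field, "score_field"))
  tot <- sum(field$score)
  if (tot <= 0)
    stop_("lost track: no positive scores around (%.1f, %.1f)",
          field$prev_pos[1], field$prev_pos[2])
  gx <- matrix(rep(field$xs, each = length(field$ys)), nrow = length(field$ys))
  gy <- matrix(rep(field$ys, times = length(field$xs)), nrow = length(field$ys))
  round(c(sum(gx * field$score), sum(gy * field$score)) / tot, 1)
}

#' Track cells through an image stack
#'
#' Frame-by-frame weighted-centroid tracking: each cell's estimate in one
#' frame is the scoring centre for the next. Cells are scored
#' independently (no arbitration between overlapping windows; keep
#' neighbours further apart than twice the cutoff if identity swaps are a
#' concern). If every score is zero the track ends there: the trajectory
#' is truncated at the last good frame and the cell is flagged in the
#' `lost` attribute (with a warning), not silently dropped.
#'
#' @param stack an [image_stack()].
#' @param initial_positions matrix (or list) of starting `(x, y)` pixel
#'   coordinates, one row per cell (the manual initialisation).
#' @param params a [tracker_params()].
#' @param output_sampling trajectory sampling interval (min); must be a
#'   multiple of the stack's frame interval (default 34).
#' @return a [trajectory_table()] in um (positions = pixel * pixel_size,
#'   reported to 0.1 px = 0.5 um at 5 um/px); frame 1 is t = 0. Attribute
#'   `lost` is a data.frame of truncated cells and their last good frame.
#' @export
track_stack <- function(stack, initial_positions, params = tracker_params(),
                        output_sampling = 34) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.list(initial_positions) && !is.matrix(initial_positions))
    initial_positions <- do.call(rbind, initial_positions)
  initial_positions <- as.matrix(initial_positions)
  if (!is_multiple(output_sampling, stack$frame_interval) ||
      output_sampling < stack$frame_interval)
    stop_("output_sampling must be a multiple of the frame interval (%g min)",
          stack$frame_interval)
  n_f <- dim(stack$frames)[3]
  n_cells <- nrow(initial_positions)
  pos_x <- matrix(NA_real_, n_f, n_cells)
  pos_y <- matrix(NA_real_, n_f, n_cells)
  lost <- data.frame(cell_id = integer(0), last_frame = integer(0))
  for (c_i in seq_len(n_cells)) {
    prev <- initial_positions[c_i, ]
    for (f in seq_len(n_f)) {
      est <- tryCatch(
        weighted_centroid(score_pixels(stack$frames[, , f], prev, params)),
        error = function(e) NULL)
      if (is.null(est)) {
        lost <- rbind(lost, data.frame(cell_id = c_i, last_frame = f - 1L))
        break
      }
      pos_x[f, c_i] <- est[1]; pos_y[f, c_i] <- est[2]
      prev <- est
    }
  }
  if (nrow(lost))
    warning(sprintf("track lost for cell(s) %s (trajectories truncated)",
                    paste(lost$cell_id, collapse = ", ")))
  stride <- as.integer(round(output_sampling / stack$frame_interval))
  keep_f <- seq(1L, n_f, by = stride)
  pieces <- lapply(seq_len(n_cells), function(c_i) {
    good <- keep_f[!is.na(pos_x[keep_f, c_i])]
    if (!length(good)) return(NULL)
    data.frame(cell_id = c_i,
               t_min = (good - 1L) * stack$frame_interval,
               x_um = pos_x[good, c_i] * params$pixel_size,
               y_um = pos_y[good, c_i] * params$pixel_size)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) stop_("every track was lost at the first frame")
  out <- trajectory_table(do.call(rbind, pieces))
  attr(out, "lost") <- lost
  out
}
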