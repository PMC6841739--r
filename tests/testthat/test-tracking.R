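frame_with_blob <- function(h = 60, w = 60, cx = 30, cy = 30) {
  traj <- trajectory_table(data.frame(cell_id = 1, t_min = 0,
                                      x_um = cx * 5, y_um = cy * 5))
  gen_image_stack(traj, h, w,
                  blob = list(nucleus_radius = 20, nucleus_brightness = 5,
                              rim_brightness = 90, background = 55,
                              noise_sd = 0))$frames[, , 1]
}

test_that("proximity score decays by e^-1 at sigma1 and the threshold zeroes bright pixels", {
  # uniform dark frame isolates S1; brightness 0 everywhere
  frame <- matrix(0, 60, 60)
  fld <- score_pixels(frame, c(30, 30), tracker_params(cutoff = 75))
  s_at <- function(x, y) fld$score[match(y, fld$ys), match(x, fld$xs)]
  expect_equal(s_at(42, 30) / s_at(30, 30), exp(-1), tolerance = 1e-12)
  expect_equal(s_at(30, 30), max(fld$score))

  # pixel brighter than the centre by 11 > threshold 10 gets zero score
  frame2 <- matrix(20, 60, 60)
  frame2[31, 33] <- 31        # (x=32, y=30), f - f0 = 11
  frame2[31, 35] <- 30        # (x=34, y=30), f - f0 = 10, allowed
  fld2 <- score_pixels(frame2, c(30, 30))
  expect_equal(fld2$score[match(30, fld2$ys), match(32, fld2$xs)], 0)
  expect_gt(fld2$score[match(30, fld2$ys), match(34, fld2$xs)], 0)

  expect_error(score_pixels(frame, c(200, 30)), "outside")
})

test_that("weighted centroid matches hand-computed means and edge cases", {
  fld <- structure(list(score = matrix(c(1, 3), nrow = 1),
                        xs = c(10, 20), ys = 0, prev_pos = c(15, 0)),
                   class = "score_field")
  expect_equal(weighted_centroid(fld), c(17.5, 0))

  # uniform scores symmetric about (20, 20)
  fld2 <- structure(list(score = matrix(1, 5, 5), xs = 18:22, ys = 18:22,
                         prev_pos = c(20, 20)), class = "score_field")
  expect_equal(weighted_centroid(fld2), c(20, 20))

  # single positive pixel
  sc <- matrix(0, 3, 3); sc[2, 2] <- 5
  fld3 <- structure(list(score = sc, xs = 4:6, ys = 7:9, prev_pos = c(5, 8)),
                    class = "score_field")
  expect_equal(weighted_centroid(fld3), c(5, 8))

  fld4 <- structure(list(score = matrix(0, 2, 2), xs = 1:2, ys = 1:2,
                         prev_pos = c(1, 1)), class = "score_field")
  expect_error(weighted_centroid(fld4), "lost track")
})

test_that("centroid lies inside the hull of positive-score pixels", {
  set.seed(42)
  for (i in 1:20) {
    frame <- matrix(runif(900, 0, 30), 30, 30)
    fld <- score_pixels(frame, c(runif(1, 8, 22), runif(1, 8, 22)))
    ct <- weighted_centroid(fld)
    pos <- which(fld$score > 0, arr.ind = TRUE)
    xs <- fld$xs[pos[, 2]]; ys <- fld$ys[pos[, 1]]
    expect_true(ct[1] >= min(xs) - 0.05 && ct[1] <= max(xs) + 0.05)
    expect_true(ct[2] >= min(ys) - 0.05 && ct[2] <= max(ys) + 0.05)
  }
})

test_that("a noise-free static cell is recovered within 0.5 um in every frame", {
  # off-grid centre: subpixel accuracy required
  truth <- c(101.3, 148.9)  # um
  traj <- trajectory_table(data.frame(cell_id = 1, t_min = seq(0, 8, by = 2),
                                      x_um = truth[1], y_um = truth[2]))
  st <- gen_image_stack(traj, 70, 70,
                        blob = list(nucleus_radius = 20, nucleus_brightness = 5,
                                    rim_brightness = 90, background = 55,
                                    noise_sd = 0))
  tracked <- track_stack(st, rbind(truth / 5 + c(0.4, -0.3)),
                         output_sampling = 2)
  expect_equal(nrow(tracked), 5L)
  expect_lt(max(abs(tracked$x_um - truth[1])), 0.5)
  expect_lt(max(abs(tracked$y_um - truth[2])), 0.5)
})

test_that("a moving cell under moderate noise is tracked with sub-pixel RMS error", {
  set.seed(6)
  n_f <- 40
  # random walk at ~1 um/frame, well within the 50-um cutoff
  x <- 150 + cumsum(rnorm(n_f, sd = 1))
  y <- 150 + cumsum(rnorm(n_f, sd = 1))
  traj <- trajectory_table(data.frame(cell_id = 1, t_min = 2 * (0:(n_f - 1)),
                                      x_um = x, y_um = y))
  st <- gen_image_stack(traj, 60, 60,
                        blob = list(nucleus_radius = 20, nucleus_brightness = 5,
                                    rim_brightness = 90, background = 55,
                                    noise_sd = 3), seed = 8)
  tracked <- track_stack(st, rbind(c(x[1], y[1]) / 5), output_sampling = 2)
  expect_equal(nrow(tracked), n_f)
  err_px <- sqrt(mean(((tracked$x_um - x)^2 + (tracked$y_um - y)^2) / 25))
  expect_lt(err_px, 1)
})

test_that("distant cells never swap identities; tracked MSD matches the input MSD", {
  set.seed(9)
  n_f <- 30
  mk <- function(x0, y0) data.frame(x = x0 + cumsum(rnorm(n_f, sd = 0.8)),
                                    y = y0 + cumsum(rnorm(n_f, sd = 0.8)))
  a <- mk(100, 100); b <- mk(250, 220)   # >= 100 um apart throughout
  traj <- trajectory_table(rbind(
    data.frame(cell_id = 1, t_min = 2 * (0:(n_f - 1)), x_um = a$x, y_um = a$y),
    data.frame(cell_id = 2, t_min = 2 * (0:(n_f - 1)), x_um = b$x, y_um = b$y)))
  st <- gen_image_stack(traj, 80, 80,
                        blob = list(nucleus_radius = 20, nucleus_brightness = 5,
                                    rim_brightness = 90, background = 55,
                                    noise_sd = 0))
  tracked <- track_stack(st, rbind(c(a$x[1], a$y[1]) / 5,
                                   c(b$x[1], b$y[1]) / 5),
                         output_sampling = 2)
  t1 <- tracked[tracked$cell_id == 1, ]
  t2 <- tracked[tracked$cell_id == 2, ]
  expect_lt(max(abs(t1$x_um - a$x)), 5)   # never jumps to the other cell
  expect_lt(max(abs(t2$x_um - b$x)), 5)
  # MSD reconstruction: tracker noise is far below the 4*sigma^2 scale here
  lags <- 2 * (1:10)
  m_in <- msd(traj, lags = lags)$msd_um2
  m_tr <- msd(tracked, lags = lags)$msd_um2
  expect_lt(max(abs(m_in - m_tr)), 0.5)
})

test_that("a cell that disappears is truncated and flagged, not dropped", {
  # frame 1 holds a trackable nucleus; frames 2-3 are pure background, so
  # every remaining score falls below the numerical floor => lost track
  blob_frame <- frame_with_blob(40, 40, cx = 20, cy = 20)
  frames <- array(55, dim = c(40, 40, 3))
  frames[, , 1] <- blob_frame
  st <- image_stack(frames, pixel_size = 5, frame_interval = 2)
  expect_warning(
    tracked <- track_stack(st, rbind(c(20, 20)), output_sampling = 2),
    "lost")
  expect_equal(attr(tracked, "lost")$cell_id, 1L)
  expect_equal(attr(tracked, "lost")$last_frame, 1L)
  expect_equal(nrow(tracked), 1L)  # only the first frame survived
})
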