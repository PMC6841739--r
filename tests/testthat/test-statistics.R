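three_point <- trajectory_table(data.frame(
  cell_id = 1, t_min = c(0, 34, 68), x_um = c(0, 3, 6), y_um = c(0, 4, 8)))

test_that("velocities match hand arithmetic and degenerate cases", {
  v <- velocities(three_point)
  expect_equal(v$vx, c(3, 3) / 34)
  expect_equal(v$vy, c(4, 4) / 34)
  expect_equal(v$speed, c(5, 5) / 34)
  expect_equal(nrow(v), 2L)  # frames - 1

  static <- trajectory_table(data.frame(cell_id = 1, t_min = 34 * (0:3),
                                        x_um = 1, y_um = 2))
  expect_true(all(velocities(static)$speed == 0))
  expect_error(velocities(three_point, dt = 50), "multiple")
})

test_that("msd reproduces brute-force origin averaging and rejects bad lags", {
  m <- msd(three_point, lags = c(34, 68))
  expect_equal(m$msd_um2, c(25, 100))  # 2 origins then 1 origin
  expect_error(msd(three_point, lags = 136), "lags")

  static <- trajectory_table(data.frame(cell_id = rep(1:2, each = 4),
                                        t_min = rep(34 * (0:3), 2),
                                        x_um = 5, y_um = -1))
  expect_true(all(msd(static, lags = c(34, 68))$msd_um2 == 0))
})

test_that("all statistics agree exactly with naive double-loop references", {
  traj <- fixture_cohort(n_cells = 5, n_frames = 6)
  lags <- 34 * (1:4)
  expect_equal(msd(traj, lags = lags)$msd_um2, naive_msd(traj, lags))

  edges <- seq(0, 40, by = 2.5)
  for (id in c(1, 4)) {
    got <- self_correlation_single(traj, 34, bin_edges = edges, cell_id = id)
    expect_equal(got$density_per_um2,
                 naive_gi(traj[traj$cell_id == id, ], 34, edges))
  }
  G <- self_correlation_ensemble(traj, 34, bin_edges = edges)
  ref_G <- rowMeans(sapply(1:5, function(id)
    naive_gi(traj[traj$cell_id == id, ], 34, edges)))
  expect_equal(G$density_per_um2, ref_G)

  vc <- vacf(traj, cell_id = 3)
  expect_equal(vc$vacf, naive_vacf(traj[traj$cell_id == 3, ]))

  acc <- acceleration_stats(traj, speed_bin_width = 1, min_count = 1)
  ref <- do.call(rbind, lapply(1:5, function(id)
    naive_accel(traj[traj$cell_id == id, ])))
  bin <- floor(ref$speed / 1)
  for (b in unique(bin)) {
    row <- acc[abs(acc$speed_mid - (b + 0.5)) < 1e-9, ]
    expect_equal(row$a_p_mean, mean(ref$a_p[bin == b]))
    expect_equal(row$a_np_mean, mean(ref$a_np[bin == b]))
    expect_equal(row$a_p_mean_dev,
                 mean(abs(ref$a_p[bin == b] - mean(ref$a_p[bin == b]))))
  }
})

test_that("correlation curves integrate to one under the 2*pi*r measure", {
  traj <- fixture_cohort(n_cells = 6, n_frames = 8)
  for (lag in c(34, 68)) {
    G <- self_correlation_ensemble(traj, lag)
    mass <- sum(G$density_per_um2 * pi * (G$bin_hi_um^2 - G$bin_lo_um^2))
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  one <- self_correlation_single(traj, 34, cell_id = 2)
  expect_equal(sum(one$density_per_um2 *
                     pi * (one$bin_hi_um^2 - one$bin_lo_um^2)), 1,
               tolerance = 1e-6)
  # second moment of the underlying histogram equals the MSD within binning
  mags <- displacement_magnitudes(traj, 34)
  expect_equal(mean(mags^2), msd(traj, lags = 34)$msd_um2, tolerance = 1e-9)
})

test_that("a static cell puts all correlation mass in the first bin", {
  static <- trajectory_table(data.frame(cell_id = 1, t_min = 34 * (0:5),
                                        x_um = 0, y_um = 0))
  g <- self_correlation_single(static, 34, bin_edges = seq(0, 5, 2.5))
  expect_equal(g$density_per_um2[1] * pi * 2.5^2, 1)
  expect_true(all(g$density_per_um2[-1] == 0))
})

test_that("the three-point trajectory concentrates g_i at r = 5", {
  g <- self_correlation_single(three_point, 34, bin_edges = seq(0, 10, 2.5))
  in_bin <- g$bin_lo_um <= 5 & g$bin_hi_um > 5
  expect_equal(sum(g$density_per_um2[in_bin] *
                     pi * (g$bin_hi_um[in_bin]^2 - g$bin_lo_um[in_bin]^2)), 1)
})

test_that("gaussian_reference evaluates the 2-D Gaussian and is normalized", {
  edges <- seq(0, 60, by = 0.05)
  G <- gaussian_reference(68, 100, edges)
  # value near r = 0 is 1/(pi * msd) ~ 3.183e-3 um^-2
  expect_equal(G$density_per_um2[1], 1 / (100 * pi), tolerance = 1e-4)
  mass <- sum(G$density_per_um2 * pi * (G$bin_hi_um^2 - G$bin_lo_um^2))
  expect_equal(mass, 1, tolerance = 1e-4)
  expect_error(gaussian_reference(68, 0, edges), "> 0")
})

test_that("rescaling collapses Gaussian cells onto exp(-u^2) and flags r* = 0", {
  # analytic Gaussian curves with very different r*, fine bins
  mk_gauss <- function(msd_val) {
    edges <- seq(0, 6 * sqrt(msd_val), length.out = 400)
    gaussian_reference(68, msd_val, edges)
  }
  curves <- lapply(c(4, 25, 400), mk_gauss)
  r_star <- sqrt(c(4, 25, 400))
  rc <- rescale_correlation(curves, r_star, x_bin_width = 0.25)
  expect_lt(max(abs(rc$mean - exp(-rc$u_mid^2))), 0.02)

  expect_warning(rescale_correlation(curves, c(0, 5, 20)), "r\\* = 0")

  # single cell: zero SEM everywhere
  rc1 <- rescale_correlation(curves[1], 2)
  expect_true(all(rc1$sem == 0))
})

test_that("rescaled g_i of a CH cohort collapses onto the Gaussian; CTH does not", {
  ch <- gen_reference_cohort("cellular", seed = 41, n_cells = 80,
                             duration = 1292, integration_dt = 1,
                             add_error = FALSE)
  rc <- rescaled_gi(ch$trajectories, 68, bin_width = 1, x_bin_width = 0.25)
  sub <- rc[rc$u_mid <= 2 & rc$n >= 10, ]
  expect_lt(max(abs(sub$mean - exp(-sub$u_mid^2))), 0.15)

  cth <- gen_reference_cohort("combined", seed = 42, n_cells = 80,
                              duration = 1292, integration_dt = 1,
                              add_error = FALSE)
  lag_cth <- 68
  rcc <- rescaled_gi(cth$trajectories, lag_cth, bin_width = 1,
                     x_bin_width = 0.25)
  # systematic excess over the Gaussian in the tail
  tail_c <- rcc[rcc$u_mid >= 2 & rcc$n >= 10, ]
  expect_gt(mean(tail_c$mean - exp(-tail_c$u_mid^2)), 0)
})

test_that("vacf handles straight lines, zig-zags and errors", {
  straight <- trajectory_table(data.frame(cell_id = 1, t_min = 34 * (0:5),
                                          x_um = 2 * (0:5), y_um = 34 * (0:5)))
  expect_true(all(abs(vacf(straight)$vacf - 1) < 1e-12))

  zig <- trajectory_table(data.frame(cell_id = 1, t_min = 34 * (0:6),
                                     x_um = c(0, 1, 0, 1, 0, 1, 0), y_um = 0))
  expect_equal(vacf(zig)$vacf[2], -1)

  static <- trajectory_table(data.frame(cell_id = 1, t_min = 34 * (0:4),
                                        x_um = 0, y_um = 0))
  expect_error(vacf(static), "zero-variance")
})

test_that("acceleration decomposition matches hand arithmetic", {
  # v(0) = (1, 0), v(34) = (0, 1) um/min
  tr <- trajectory_table(data.frame(
    cell_id = 1, t_min = c(0, 34, 68),
    x_um = c(0, 34, 34), y_um = c(0, 0, 34)))
  acc <- acceleration_stats(tr, speed_bin_width = 2, min_count = 1)
  expect_equal(acc$a_p_mean, -1 / 34)
  expect_equal(acc$a_np_mean, 1 / 34)

  const <- trajectory_table(data.frame(cell_id = 1, t_min = 34 * (0:4),
                                       x_um = 3 * (0:4), y_um = 4 * (0:4)))
  acc2 <- acceleration_stats(const, speed_bin_width = 2, min_count = 1)
  expect_equal(acc2$a_p_mean, 0)
  expect_equal(acc2$a_np_mean, 0)
})

test_that("finite-difference VACF of an HO cohort matches the exact sampling closed form", {
  # finite sampling inflates the first-lag autocorrelation relative to
  # exp(-dt/P); the oracle is the integrated-OU increment correlation
  tr <- simulate_ho(1200, 1292, S = 0.125, P = 78, sampling_dt = 34,
                    integration_dt = 0.1, seed = 44)
  ids <- unique(tr$cell_id)
  v <- velocities(tr)
  vx <- matrix(v$vx, ncol = length(ids))
  vy <- matrix(v$vy, ncol = length(ids))
  vc <- velocity_autocorrelation(vx, vy, 34, max_lag = 3)
  theory <- vapply(0:3, fd_vacf_theory, numeric(1), dt = 34, P = 78, S = 0.125)
  expect_lt(max(abs(vc$vacf - theory)), 0.01)
  # and the first-lag value is distinctly above exp(-34/78)
  expect_gt(vc$vacf[2], exp(-34 / 78) + 0.05)
})
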