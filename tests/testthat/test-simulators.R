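test_that("zero speed freezes the cohort; invalid parameters are rejected", {
  tr <- simulate_ho(5, duration = 340, S = 0, P = 78, integration_dt = 1,
                    seed = 1)
  expect_true(all(tr$x_um == 0) && all(tr$y_um == 0))
  expect_error(simulate_ho(5, S = -0.1, P = 78), ">= 0")
  expect_error(simulate_ho(5, S = 0.1, P = 0), "> 0")
  expect_error(simulate_ch(c(0.1, 0.2), 78), "per cell")
  expect_error(simulate_ho(5, duration = 30, S = 0.1, P = 78), "duration")
})

test_that("the OU velocity process is stationary with mean-square speed S^2", {
  tr <- simulate_ho(3000, 1292, S = 0.125, P = 78, sampling_dt = 34,
                    integration_dt = 0.1, seed = 2, return_velocities = TRUE)
  v2 <- mean(attr(tr, "vx")^2 + attr(tr, "vy")^2)
  expect_lt(abs(v2 / 0.125^2 - 1), 0.01)
})

test_that("instantaneous velocity autocorrelation follows exp(-t/P)", {
  tr <- simulate_ho(2000, 1292, S = 0.125, P = 78, sampling_dt = 34,
                    integration_dt = 0.1, seed = 3, return_velocities = TRUE)
  vc <- velocity_autocorrelation(attr(tr, "vx"), attr(tr, "vy"), 34,
                                 max_lag = 5)
  expect_lt(max(abs(vc$vacf - exp(-vc$lag_min / 78))), 0.015)
})

test_that("the HO ensemble MSD matches the analytic PRW curve at every lag", {
  tr <- simulate_ho(1500, 1292, S = 0.125, P = 78, sampling_dt = 34,
                    integration_dt = 0.1, seed = 2)
  m <- msd(tr)
  theory <- eval_prw_msd(0.125, 78, 0, m$lag_min)
  expect_lt(max(abs(m$msd_um2 - theory) / m$sem_um2), 3)
})

test_that("CH reduces to HO for identical parameters and honours per-cell MSDs", {
  a <- simulate_ho(300, 680, S = 0.1, P = 60, integration_dt = 0.5, seed = 4)
  b <- simulate_ch(rep(0.1, 300), rep(60, 300), 680, integration_dt = 0.5,
                   seed = 4)
  expect_identical(a, b)  # same code path, same RNG stream

  # a cell's own time-averaged MSD matches the analytic curve built from
  # its own parameters (long single trajectory, sigma_err = 0)
  long <- simulate_ch(c(0.2, 0.05), c(40, 120), duration = 40000,
                      sampling_dt = 34, integration_dt = 0.5, seed = 5)
  m1 <- msd_one <- msd(long[long$cell_id == 1, ], lags = 34 * (1:4))
  expect_lt(max(abs(m1$msd_um2 / eval_prw_msd(0.2, 40, 0, m1$lag_min) - 1)),
            0.15)
  m2 <- msd(long[long$cell_id == 2, ], lags = 34 * (1:4))
  expect_lt(max(abs(m2$msd_um2 / eval_prw_msd(0.05, 120, 0, m2$lag_min) - 1)),
            0.15)
})

test_that("a two-speed CH cohort has non-Gaussian G but Gaussian per-cell g_i", {
  n <- 400
  S_i <- rep(c(0.05, 0.25), each = n / 2)
  tr <- simulate_ch(S_i, rep(78, n), 1292, integration_dt = 1, seed = 6)
  pooled <- displacement_magnitudes(tr, 68)
  expect_gt(non_gaussian_parameter(pooled), 0.2)
  # per-cell displacements are Gaussian: pool alpha2 over cells
  a2 <- vapply(unique(tr$cell_id)[seq(1, n, by = 8)], function(id)
    non_gaussian_parameter(displacement_magnitudes(tr, 68, cells = id)),
    numeric(1))
  expect_lt(abs(median(a2)), 0.15)
})

test_that("TH degenerate cases obey closed forms", {
  still <- displacement_sampler(rep(0, 5), lag = 68)
  tr <- simulate_th(10, 680, still, A = 2.5, step_dt = 68, seed = 7)
  expect_true(all(tr$x_um == 0) && all(tr$y_um == 0))

  # no memory (A huge), fixed step length b: MSD(n dt) = n b^2
  fixed <- displacement_sampler(rep(3, 5), lag = 68)
  tr2 <- simulate_th(4000, 1292, fixed, A = 1e9, step_dt = 68, seed = 8)
  m <- msd(tr2, lags = 68 * c(1, 3, 10))
  expect_lt(max(abs(m$msd_um2 / (9 * c(1, 3, 10)) - 1)), 0.05)
})

test_that("TH/CTH production simulators match the naive step-by-step reference bit for bit", {
  set.seed(31)
  samp <- displacement_sampler(rgamma(200, 3, 1), lag = 68)
  prod <- simulate_th(7, 1292, samp, A = 2.5, step_dt = 68, seed = 32)
  ref <- naive_th(7, 1292, samp, A = 2.5, step_dt = 68, seed = 32)
  expect_identical(prod$x_um, ref$x_um)
  expect_identical(prod$y_um, ref$y_um)

  samplers <- list(samp, displacement_sampler(rgamma(150, 2, 0.5), lag = 34),
                   displacement_sampler(runif(80, 1, 6), lag = 102))
  P_i <- c(68, 34, 102)
  prodc <- simulate_cth(samplers, P_i, 1292, A = 2.4, seed = 33)
  refc <- naive_cth(samplers, P_i, 1292, A = 2.4, seed = 33)
  expect_identical(prodc$x_um, refc$x_um)
  expect_identical(prodc$y_um, refc$y_um)
  expect_identical(prodc$t_min, refc$t_min)
})

test_that("CTH reduces to TH and scales per-cell MSDs by b^2", {
  samp <- displacement_sampler(rgamma(100, 3, 1), lag = 68)
  th <- simulate_th(5, 1292, samp, A = 2.5, step_dt = 68, seed = 34)
  cth <- simulate_cth(rep(list(samp), 5), rep(68, 5), 1292, A = 2.5, seed = 34)
  # same per-cell RNG consumption order differs (block vs per-cell), so
  # compare distributions via ensemble MSD over many cells
  th_big <- simulate_th(800, 1292, samp, A = 2.5, step_dt = 68, seed = 35)
  cth_big <- simulate_cth(rep(list(samp), 800), rep(68, 800), 1292, A = 2.5,
                          seed = 36)
  m1 <- msd(th_big, lags = 68 * c(1, 5, 15))$msd_um2
  m2 <- msd(cth_big, lags = 68 * c(1, 5, 15))$msd_um2
  expect_lt(max(abs(m1 / m2 - 1)), 0.15)

  # two cells, fixed betas b1, b2, no memory: per-cell MSD ratio b1^2/b2^2
  s1 <- displacement_sampler(rep(2, 4), lag = 68)
  s2 <- displacement_sampler(rep(5, 4), lag = 68)
  tr <- simulate_cth(list(s1, s2), c(68, 68), 40000, A = 1e9, seed = 37)
  m_1 <- msd(tr[tr$cell_id == 1, ], lags = 68 * c(1, 4))$msd_um2
  m_2 <- msd(tr[tr$cell_id == 2, ], lags = 68 * c(1, 4))$msd_um2
  expect_lt(max(abs(m_1 / m_2 - 4 / 25)), 0.05 * 4 / 25 + 0.02)
})

test_that("localization error is identity at zero and adds 4 sigma^2 to the MSD", {
  tr <- fixture_cohort(n_cells = 4, n_frames = 6)
  expect_identical(add_localization_error(tr, 0), tr)
  expect_error(add_localization_error(tr, -1), ">= 0")

  # static cohort: expected MSD at every lag is 4 sigma^2 = 11.0224
  static <- trajectory_table(data.frame(
    cell_id = rep(1:400, each = 39),
    t_min = rep(34 * (0:38), times = 400), x_um = 0, y_um = 0))
  noisy <- add_localization_error(static, 1.66, seed = 12)
  m <- msd(noisy, lags = 34 * c(1, 5, 20))
  expect_lt(max(abs(m$msd_um2 / (4 * 1.66^2) - 1)), 0.05)

  # per-coordinate noise variance check
  dev <- noisy$x_um - static$x_um
  expect_lt(abs(var(dev) / 1.66^2 - 1), 0.05)
})
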