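# Naive, loop-based reference implementations used as independent oracles.
# Deliberately written without vectorisation or shared code with the package
# (plain double loops over cells and time origins).

naive_msd <- function(traj, lags) {
  ids <- unique(traj$cell_id)
  out <- numeric(length(lags))
  for (li in seq_along(lags)) {
    lag <- lags[li]
    per_cell <- c()
    for (id in ids) {
      tc <- traj[traj$cell_id == id, ]
      tc <- tc[order(tc$t_min), ]
      dt <- tc$t_min[2] - tc$t_min[1]
      k <- lag / dt
      if (abs(k - round(k)) > 1e-9) next
      k <- round(k)
      if (k >= nrow(tc)) next
      acc <- c()
      for (i in 1:(nrow(tc) - k)) {
        acc <- c(acc, (tc$x_um[i + k] - tc$x_um[i])^2 +
                      (tc$y_um[i + k] - tc$y_um[i])^2)
      }
      per_cell <- c(per_cell, mean(acc))
    }
    out[li] <- mean(per_cell)
  }
  out
}

naive_displacements <- function(tc, lag) {
  tc <- tc[order(tc$t_min), ]
  dt <- tc$t_min[2] - tc$t_min[1]
  k <- round(lag / dt)
  d <- c()
  for (i in 1:(nrow(tc) - k)) {
    d <- c(d, sqrt((tc$x_um[i + k] - tc$x_um[i])^2 +
                   (tc$y_um[i + k] - tc$y_um[i])^2))
  }
  d
}

naive_gi <- function(tc, lag, edges) {
  d <- naive_displacements(tc, lag)
  dens <- numeric(length(edges) - 1)
  for (b in 1:(length(edges) - 1)) {
    n_in <- sum(d >= edges[b] & d < edges[b + 1])
    area <- pi * (edges[b + 1]^2 - edges[b]^2)
    dens[b] <- (n_in / length(d)) / area
  }
  dens
}

naive_vacf <- function(tc) {
  tc <- tc[order(tc$t_min), ]
  dt <- tc$t_min[2] - tc$t_min[1]
  n <- nrow(tc)
  vx <- vy <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    vx[i] <- (tc$x_um[i + 1] - tc$x_um[i]) / dt
    vy[i] <- (tc$y_um[i + 1] - tc$y_um[i]) / dt
  }
  m <- length(vx)
  ck <- numeric(m)
  for (k in 0:(m - 1)) {
    acc <- c()
    for (i in 1:(m - k)) acc <- c(acc, vx[i + k] * vx[i] + vy[i + k] * vy[i])
    ck[k + 1] <- mean(acc)
  }
  ck / ck[1]
}

naive_accel <- function(tc) {
  tc <- tc[order(tc$t_min), ]
  dt <- tc$t_min[2] - tc$t_min[1]
  n <- nrow(tc)
  vx <- vy <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    vx[i] <- (tc$x_um[i + 1] - tc$x_um[i]) / dt
    vy[i] <- (tc$y_um[i + 1] - tc$y_um[i]) / dt
  }
  rows <- NULL
  for (i in 1:(length(vx) - 1)) {
    ax <- (vx[i + 1] - vx[i]) / dt
    ay <- (vy[i + 1] - vy[i]) / dt
    sp <- sqrt(vx[i]^2 + vy[i]^2)
    if (sp == 0) next
    rows <- rbind(rows, data.frame(
      speed = sp,
      a_p  = (ax * vx[i] + ay * vy[i]) / sp,
      a_np = (vx[i] * ay - vy[i] * ax) / sp))
  }
  rows
}

# step-by-step TH reference sharing only the documented RNG consumption
# order (one uniform block for beta, one for angles, cells in column order)
naive_th <- function(n_cells, duration, sampler, A, step_dt, seed) {
  set.seed(seed)
  n_steps <- floor(duration / step_dt)
  u  <- matrix(runif(n_steps * n_cells), n_steps, n_cells)
  th <- matrix(runif(n_steps * n_cells) * 2 * pi, n_steps, n_cells)
  beta <- matrix(quantile(sampler$magnitudes, probs = as.vector(u),
                          names = FALSE, type = 7), n_steps, n_cells)
  rows <- NULL
  for (c_i in 1:n_cells) {
    px <- py <- 0            # previous step vector
    x <- y <- 0
    rows <- rbind(rows, data.frame(cell_id = c_i, t_min = 0, x_um = 0, y_um = 0))
    for (s in 1:n_steps) {
      px <- px / A + beta[s, c_i] * cos(th[s, c_i])
      py <- py / A + beta[s, c_i] * sin(th[s, c_i])
      x <- x + px; y <- y + py
      rows <- rbind(rows, data.frame(cell_id = c_i, t_min = s * step_dt,
                                     x_um = x, y_um = y))
    }
  }
  rows
}

naive_cth <- function(samplers, P_i, duration, A, seed) {
  set.seed(seed)
  rows <- NULL
  for (c_i in seq_along(samplers)) {
    n_steps <- floor(duration / P_i[c_i])
    u  <- runif(n_steps)
    th <- runif(n_steps) * 2 * pi
    beta <- quantile(samplers[[c_i]]$magnitudes, probs = u,
                     names = FALSE, type = 7)
    px <- py <- 0; x <- y <- 0
    rows <- rbind(rows, data.frame(cell_id = c_i, t_min = 0, x_um = 0, y_um = 0))
    for (s in 1:n_steps) {
      px <- px / A + beta[s] * cos(th[s])
      py <- py / A + beta[s] * sin(th[s])
      x <- x + px; y <- y + py
      rows <- rbind(rows, data.frame(cell_id = c_i, t_min = s * P_i[c_i],
                                     x_um = x, y_um = y))
    }
  }
  rows
}

# closed-form autocorrelation of finite-difference velocities of an
# integrated OU process sampled at interval dt, with localization error
fd_vacf_theory <- function(k, dt, P, S, sigma_err = 0) {
  c_ <- exp(-dt / P)
  sv2 <- S^2 / 2
  v0 <- 2 * sv2 * P * (dt - P * (1 - c_)) + 2 * sigma_err^2
  if (k == 0) return(1)
  cov_k <- sv2 * P^2 * (1 - c_)^2 * c_^(k - 1) -
    (k == 1) * sigma_err^2
  cov_k / v0   # per-component covariance over per-component variance
}

# small deterministic multi-cell trajectory for oracle-equivalence tests
fixture_cohort <- function(n_cells = 5, n_frames = 6, dt = 34, seed = 99) {
  set.seed(seed)
  rows <- NULL
  for (c_i in 1:n_cells) {
    x <- cumsum(c(0, rnorm(n_frames - 1, sd = 4)))
    y <- cumsum(c(0, rnorm(n_frames - 1, sd = 4)))
    rows <- rbind(rows, data.frame(cell_id = c_i, t_min = (0:(n_frames - 1)) * dt,
                                   x_um = x, y_um = y))
  }
  trajectory_table(rows)
}
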