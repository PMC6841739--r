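#' Simulate the homogeneous persistent random walk (HO model)
#'
#' Every cell follows the same Ornstein-Uhlenbeck velocity process
#' `dv = -v/P dt + (S/sqrt(P)) dW` per component, integrated with the exact
#' discrete velocity update and Euler position accumulation at
#' `integration_dt`, then subsampled to `sampling_dt`. Initial velocities
#' are drawn from the stationary distribution (per-component variance
#' `S^2/2`, so the stationary mean-square speed is `S^2`), initial positions
#' are at the origin. Localization error is *not* applied here; see
#' [add_localization_error()].
#'
#' @param n_cells number of cells.
#' @param duration total simulated time (min, >= 2 * sampling_dt).
#' @param S speed scale (um/min, >= 0).
#' @param P persistence time (min, > 0).
#' @param sampling_dt output sampling interval (min).
#' @param integration_dt integrator step (min); must divide `sampling_dt`.
#' @param seed integer seed or NULL.
#' @param return_velocities if TRUE, attach the instantaneous velocity
#'   components at the sampled instants as attributes `vx`, `vy`
#'   (matrices, time x cell).
#' @return a [trajectory_table()] with positions at t = 0, sampling_dt, ...
#' @export
simulate_ho <- function(n_cells, duration = 1292, S = 0.125, P = 78,
                        sampling_dt = 34, integration_dt = 0.01,
                        seed = NULL, return_velocities = FALSE) {
  if (length(S) != 1L || length(P) != 1L)
    stop_("simulate_ho takes scalar S and P; use simulate_ch for per-cell values")
  simulate_ch(rep(S, n_cells), rep(P, n_cells), duration,
              sampling_dt = sampling_dt, integration_dt = integration_dt,
              seed = seed, return_velocities = return_velocities)
}

#' Simulate the cellular-heterogeneity (CH) model
#'
#' Each cell i follows its own PRW `dv_i = -v_i/P_i dt + (S_i/sqrt(P_i)) dW`
#' with time-independent per-cell parameters; see [simulate_ho()] for the
#' integrator and conventions.
#'
#' @param S,P numeric vectors of per-cell speed scales (um/min, >= 0) and
#'   persistence times (min, > 0); one entry per cell.
#' @inheritParams simulate_ho
#' @return a [trajectory_table()].
#' @export
simulate_ch <- function(S, P, duration = 1292, sampling_dt = 34,
                        integration_dt = 0.01, seed = NULL,
                        return_velocities = FALSE) {
  n_cells <- length(S)
  if (length(P) != n_cells) stop_("S and P must have one value per cell")
  if (n_cells < 1) stop_("need at least one cell")
  if (any(S < 0)) stop_("S must be >= 0")
  if (any(P <= 0)) stop_("P must be > 0")
  if (duration < 2 * sampling_dt) stop_("duration must be >= 2 * sampling_dt")
  if (!is_multiple(sampling_dt, integration_dt))
    stop_("integration_dt must divide sampling_dt")
  substeps <- as.integer(round(sampling_dt / integration_dt))
  n_samples <- as.integer(floor(duration / sampling_dt + 1e-9))
  res <- with_seed(seed,
    ou_integrate_cpp(as.numeric(S), as.numeric(P), n_samples, substeps,
                     integration_dt, return_velocities))
  times <- (0:n_samples) * sampling_dt
  traj <- traj_from_matrices(res$x, res$y, times)
  if (return_velocities) {
    attr(traj, "vx") <- res$vx
    attr(traj, "vy") <- res$vy
  }
  traj
}

#' Simulate the temporal-heterogeneity (TH) model
#'
#' A step process on a fixed clock: every `step_dt` minutes each cell takes
#' a step `dr(t + dt) = dr(t)/A + beta(t) * xi`, where `xi` is a unit
#' vector with uniformly random orientation, independent of the past, and
#' `beta(t)` is redrawn each step from `beta_sampler` (an empirical
#' displacement-magnitude distribution, see
#' [build_displacement_sampler()]). The first step has no memory
#' contribution. All cells share the sampler and the clock, so the cohort
#' is cellularly homogeneous while each cell's step magnitude switches over
#' time.
#'
#' RNG convention (relied on by the step-by-step reference implementation
#' used in the tests): one `runif` block of `n_steps * n_cells` uniforms for
#' beta (cells in column order), then one block of the same shape for the
#' step orientations.
#'
#' @param n_cells number of cells.
#' @param duration total time (min, >= 2 * step_dt).
#' @param beta_sampler a `displacement_sampler`.
#' @param A memory parameter (> 0); larger A = weaker persistence.
#' @param step_dt step clock (min); default 68, the canonical discretized
#'   persistence for 34-min sampling.
#' @param seed integer seed or NULL.
#' @return a [trajectory_table()] with positions at t = 0, step_dt, ...
#' @export
simulate_th <- function(n_cells, duration = 1292, beta_sampler, A = 2.5,
                        step_dt = 68, seed = NULL) {
  if (!inherits(beta_sampler, "displacement_sampler"))
    stop_("beta_sampler must be a displacement_sampler")
  if (A <= 0) stop_("A must be > 0")
  if (duration < 2 * step_dt) stop_("duration must be >= 2 * step_dt")
  n_steps <- as.integer(floor(duration / step_dt + 1e-9))
  with_seed(seed, {
    u  <- matrix(runif(n_steps * n_cells), n_steps, n_cells)
    th <- matrix(runif(n_steps * n_cells) * 2 * pi, n_steps, n_cells)
    beta <- matrix(draw_displacements(beta_sampler, u = as.vector(u)),
                   n_steps, n_cells)
    x <- matrix(0, n_steps + 1L, n_cells)
    y <- matrix(0, n_steps + 1L, n_cells)
    prev_x <- prev_y <- numeric(n_cells)
    for (s in seq_len(n_steps)) {
      prev_x <- prev_x / A + beta[s, ] * cos(th[s, ])
      prev_y <- prev_y / A + beta[s, ] * sin(th[s, ])
      x[s + 1L, ] <- x[s, ] + prev_x
      y[s + 1L, ] <- y[s, ] + prev_y
    }
    traj_from_matrices(x, y, (0:n_steps) * step_dt)
  })
}

#' Simulate the combined cellular-and-temporal heterogeneity (CTH) model
#'
#' As [simulate_th()], but cell i advances on its own clock `P_i` and draws
#' its step magnitudes `beta_i(t)` from its own sampler, so both the step
#' statistics and the step clock differ across cells.
#'
#' RNG convention: cells are processed in order; for each cell one `runif`
#' block for beta then one for orientations.
#'
#' @param samplers list of `displacement_sampler`s, one per cell.
#' @param P_i per-cell step clocks (min); `samplers[[i]]` should have been
#'   built at lag `P_i[i]`.
#' @param duration total time (min); every cell needs at least 2 steps.
#' @param A memory parameter (> 0), shared by all cells.
#' @param seed integer seed or NULL.
#' @return a [trajectory_table()]; cell i has positions at t = 0, P_i, 2 P_i, ...
#' @export
simulate_cth <- function(samplers, P_i, duration = 1292, A = 2.4,
                         seed = NULL) {
  n_cells <- length(samplers)
  if (length(P_i) != n_cells) stop_("need one step clock per sampler")
  if (!all(vapply(samplers, inherits, TRUE, "displacement_sampler")))
    stop_("samplers must all be displacement_samplers")
  if (A <= 0) stop_("A must be > 0")
  if (any(duration < 2 * P_i))
    stop_("duration must allow >= 2 steps for every cell (max P_i = %g)",
          max(P_i))
  with_seed(seed, {
    pieces <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      n_steps <- as.integer(floor(duration / P_i[i] + 1e-9))
      u  <- runif(n_steps)
      th <- runif(n_steps) * 2 * pi
      beta <- draw_displacements(samplers[[i]], u = u)
      xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
      px <- py <- 0
      for (s in seq_len(n_steps)) {
        px <- px / A + beta[s] * cos(th[s])
        py <- py / A + beta[s] * sin(th[s])
        xs[s + 1L] <- xs[s] + px
        ys[s + 1L] <- ys[s] + py
      }
      pieces[[i]] <- data.frame(
        cell_id = i,
        t_min   = (0:n_steps) * P_i[i],
        x_um    = xs,
        y_um    = ys
      )
    }
    df <- do.call(rbind, pieces)
    class(df) <- c("trajectory_table", "data.frame")
    df
  })
}

#' Add localization error to sampled positions
#'
#' Models measurement noise: each coordinate of each sampled position gets
#' independent zero-mean Gaussian noise of standard deviation `sigma_err`,
#' mirroring how a microscope's spatial resolution corrupts real tracks.
#' The expected MSD of a static trajectory becomes `4 * sigma_err^2` at
#' every positive lag (two coordinates, difference of two noisy positions).
#'
#' @param traj a [trajectory_table()].
#' @param sigma_err noise sd (um, >= 0).
#' @param seed integer seed or NULL.
#' @return the noisy trajectory table.
#' @export
add_localization_error <- function(traj, sigma_err, seed = NULL) {
  if (sigma_err < 0) stop_("sigma_err must be >= 0")
  if (sigma_err == 0) return(traj)
  with_seed(seed, {
    n <- nrow(traj)
    traj$x_um <- traj$x_um + rnorm(n, sd = sigma_err)
    traj$y_um <- traj$y_um + rnorm(n, sd = sigma_err)
    traj
  })
}
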