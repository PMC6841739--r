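#' Generate a synthetic cohort of per-cell migration parameters
#'
#' Draws per-cell speeds `S_i` (um/min) and persistence times `P_i` (min)
#' from the given laws. Persistences are snapped to the nearest positive
#' multiple of `sampling_dt` (see [discretize_persistence()]) because the
#' step-process models advance each cell on a clock commensurate with the
#' sampling grid, and are capped at `p_max` so every cell completes several
#' steps within `duration`.
#'
#' Defaults emulate the design of a time-lapse experiment on a lung-cancer
#' cell cohort: 212 cells observed for 1292 min at 34-min sampling, mean
#' speed 0.125 um/min, mean persistence 78 min, localization error 1.66 um.
#'
#' @param n_cells number of cells (>= 1).
#' @param speed_law,persistence_law [dist_spec()] objects for `S_i` and the
#'   continuous `P_i` (before snapping).
#' @param sigma_err localization error (um, >= 0).
#' @param sampling_dt sampling interval (min).
#' @param duration total observation time (min, >= 2 * sampling_dt).
#' @param p_max cap applied to snapped persistences (min); default
#'   `duration / 4`.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return an object of class `population_params`: a list with fields
#'   `n_cells`, `S` (vector), `P` (snapped vector), `P_continuous`,
#'   `sigma_err`, `sampling_dt`, `duration`.
#' @export
gen_population <- function(n_cells = 212,
                           speed_law = dist_spec("lognormal", mean = 0.125, cv = 0.45),
                           persistence_law = dist_spec("lognormal", mean = 78, cv = 0.5),
                           sigma_err = 1.66,
                           sampling_dt = 34,
                           duration = 1292,
                           p_max = duration / 4,
                           seed = NULL) {
  if (!is_count(n_cells)) stop_("n_cells must be a positive integer")
  if (sigma_err < 0) stop_("sigma_err must be >= 0")
  if (sampling_dt <= 0) stop_("sampling_dt must be > 0")
  if (duration < 2 * sampling_dt) stop_("duration must be >= 2 * sampling_dt")
  with_seed(seed, {
    S <- draw_dist(speed_law, n_cells)
    P_cont <- draw_dist(persistence_law, n_cells)
    if (any(S <= 0) || any(P_cont <= 0))
      stop_("speed and persistence laws must produce positive values")
    P <- discretize_persistence(P_cont, sampling_dt)
    cap <- max(sampling_dt, sampling_dt * floor(p_max / sampling_dt))
    P <- pmin(P, cap)
    structure(list(n_cells = n_cells, S = S, P = P, P_continuous = P_cont,
                   sigma_err = sigma_err, sampling_dt = sampling_dt,
                   duration = duration),
              class = "population_params")
  })
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(paste0("<population_params> %d cells, dt = %g min, tau = %g min\n",
                     "  S_i: mean %.4g um/min (range %.4g-%.4g)\n",
                     "  P_i: mean %.4g min (range %g-%g), sigma_err = %g um\n"),
              x$n_cells, x$sampling_dt, x$duration,
              mean(x$S), min(x$S), max(x$S),
              mean(x$P), min(x$P), max(x$P), x$sigma_err))
  invisible(x)
}

#' Generate a reference cohort under one of the four migration scenarios
#'
#' Convenience front end to the four simulators with the canonical study
#' design: `n_cells = 212`, `duration = 1292` min, `sampling_dt = 34` min,
#' `S = 0.125` um/min, `P = 78` min, `sigma_err = 1.66` um. Scenarios:
#' `"homogeneous"` (single PRW), `"cellular"` (per-cell `(S_i, P_i)`),
#' `"temporal"` (step process, shared empirical step-magnitude sampler built
#' from an internally simulated homogeneous cohort, memory `A = 2.5`) and
#' `"combined"` (per-cell clocks and samplers from an internally simulated
#' heterogeneous cohort, `A = 2.4`).
#'
#' @param scenario one of `"homogeneous"`, `"cellular"`, `"temporal"`,
#'   `"combined"`.
#' @param seed integer seed (all internal stages derive their seeds from it).
#' @param n_cells,duration,sampling_dt,sigma_err cohort design.
#' @param S,P canonical homogeneous parameters.
#' @param add_error add localization error to the returned trajectories?
#' @param integration_dt integrator step for the OU-based scenarios (min).
#' @return list with elements `trajectories` (a [trajectory_table()]) and
#'   `params` (ground truth: a `population_params` for the OU scenarios, or
#'   a list with samplers, step clocks and the memory parameter for the step
#'   scenarios).
#' @export
gen_reference_cohort <- function(scenario = c("homogeneous", "cellular",
                                              "temporal", "combined"),
                                 seed = NULL,
                                 n_cells = 212, duration = 1292,
                                 sampling_dt = 34, sigma_err = 1.66,
                                 S = 0.125, P = 78,
                                 add_error = TRUE,
                                 integration_dt = 0.01) {
  scenario <- match.arg(scenario)
  base <- if (is.null(seed)) NULL else as.integer(seed)
  sub <- function(k) if (is.null(base)) NULL else base + k
  out <- switch(scenario,
    homogeneous = {
      traj <- simulate_ho(n_cells, duration, S = S, P = P,
                          sampling_dt = sampling_dt,
                          integration_dt = integration_dt, seed = sub(1L))
      pop <- list(n_cells = n_cells, S = rep(S, n_cells), P = rep(P, n_cells),
                  P_continuous = rep(P, n_cells), sigma_err = sigma_err,
                  sampling_dt = sampling_dt, duration = duration)
      class(pop) <- "population_params"
      list(trajectories = traj, params = pop)
    },
    cellular = {
      pop <- gen_population(n_cells, sigma_err = sigma_err,
                            sampling_dt = sampling_dt, duration = duration,
                            seed = sub(1L))
      traj <- simulate_ch(pop$S, pop$P, duration, sampling_dt = sampling_dt,
                          integration_dt = integration_dt, seed = sub(2L))
      list(trajectories = traj, params = pop)
    },
    temporal = {
      # the shared step-magnitude source must itself be non-Rayleigh for
      # the temporal switching to be visible (a Rayleigh beta would make
      # beta*xi exactly Gaussian), so the donor ensemble is cellularly
      # heterogeneous -- the step process then mixes its scales over time
      donor_pop <- gen_population(n_cells, sigma_err = sigma_err,
                                  sampling_dt = sampling_dt,
                                  duration = duration, seed = sub(1L))
      donor <- simulate_ch(donor_pop$S, donor_pop$P, duration,
                           sampling_dt = sampling_dt,
                           integration_dt = integration_dt, seed = sub(2L))
      step_dt <- discretize_persistence(P, sampling_dt)
      sampler <- build_displacement_sampler(donor, lag = step_dt)
      traj <- simulate_th(n_cells, duration, sampler, A = 2.5,
                          step_dt = step_dt, seed = sub(3L))
      list(trajectories = traj,
           params = list(A = 2.5, step_dt = step_dt, sampler = sampler,
                         sigma_err = sigma_err, n_cells = n_cells,
                         duration = duration))
    },
    combined = {
      # per-cell two-state (fast/slow) step-magnitude mixtures: cell i
      # pools displacement magnitudes from donors migrating at
      # state_ratio * S_i and S_i / state_ratio, emulating temporal
      # switching of migration capacity within each cell
      state_ratio <- 2
      pop <- gen_population(n_cells, sigma_err = sigma_err,
                            sampling_dt = sampling_dt, duration = duration,
                            seed = sub(1L))
      fast <- simulate_ch(pop$S * state_ratio, pop$P, duration,
                          sampling_dt = sampling_dt,
                          integration_dt = integration_dt, seed = sub(2L))
      slow <- simulate_ch(pop$S / state_ratio, pop$P, duration,
                          sampling_dt = sampling_dt,
                          integration_dt = integration_dt, seed = sub(3L))
      ids <- unique(fast$cell_id)
      samplers <- lapply(seq_along(ids), function(i)
        displacement_sampler(
          c(displacement_magnitudes(fast, pop$P[i], cells = ids[i]),
            displacement_magnitudes(slow, pop$P[i], cells = ids[i])),
          lag = pop$P[i], scope = ids[i]))
      traj <- simulate_cth(samplers, pop$P, duration, A = 2.4, seed = sub(4L))
      list(trajectories = traj,
           params = list(A = 2.4, step_dt = pop$P, samplers = samplers,
                         population = pop, sigma_err = sigma_err,
                         duration = duration))
    }
  )
  if (add_error && sigma_err > 0)
    out$trajectories <- add_localization_error(out$trajectories, sigma_err,
                                               seed = sub(9L))
  out
}
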