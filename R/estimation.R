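#' Analytic PRW mean-square displacement
#'
#' The two-dimensional MSD of the persistent random walk with localization
#' error: `2 S^2 P^2 (exp(-t/P) + t/P - 1) + 4 sigma_err^2`. At `t = 0` the
#' first term vanishes and the curve starts at the static noise floor
#' `4 sigma_err^2`; at `t >> P` the slope approaches the Fickian limit
#' `2 S^2 P`.
#'
#' @param S speed scale (um/min).
#' @param P persistence time (min, > 0).
#' @param sigma_err localization error (um).
#' @param t lag(s) in min (>= 0), vectorised.
#' @return MSD values in um^2.
#' @export
eval_prw_msd <- function(S, P, sigma_err, t) {
  if (P <= 0) stop_("P must be > 0")
  if (any(t < 0)) stop_("t must be >= 0")
  2 * S^2 * P^2 * (exp(-t / P) + t / P - 1) + 4 * sigma_err^2
}

#' Fit the analytic PRW MSD to a measured curve
#'
#' Nonlinear least squares of [eval_prw_msd()] over `(S, P, sigma_err)`
#' with positivity constraints, multi-start initialisation (tail-slope /
#' short-lag heuristics plus jittered restarts). When the curve carries
#' per-lag SEMs the fit is weighted by `1/SEM^2` (generalized least
#' squares; the cell-to-cell variance of time-averaged MSDs grows steeply
#' with lag, so unweighted fits are dominated by the noisiest points);
#' noise-free curves without SEMs are fitted unweighted.
#'
#' @param curve an `msd_curve` from [msd()], or a data.frame with columns
#'   `lag_min` and `msd_um2` (optional `sem_um2`).
#' @param exclude_lags lags (min) to drop before fitting.
#' @param weights `"sem"` (default when SEMs are available) or `"none"`.
#' @param n_restarts extra jittered starts per heuristic start.
#' @return an object of class `prw_fit`: list with `S`, `P`, `sigma_err`,
#'   `rss`, `lags`, `fitted`, `convergence`.
#' @export
fit_prw_msd <- function(curve, exclude_lags = numeric(0),
                        weights = NULL, n_restarts = 3L) {
  lag <- curve$lag_min
  val <- curve$msd_um2
  keep <- !vapply(lag, function(l) any(abs(l - exclude_lags) < 1e-9), TRUE)
  keep <- keep & lag > 0
  lag <- lag[keep]; val <- val[keep]
  if (length(lag) < 4) stop_("need >= 4 lags after exclusion to fit 3 parameters")
  has_sem <- "sem_um2" %in% names(curve) &&
    all(is.finite(curve$sem_um2[keep])) && all(curve$sem_um2[keep] > 0)
  weights <- weights %||% (if (has_sem) "sem" else "none")
  w <- if (weights == "sem") 1 / curve$sem_um2[keep]^2 else rep(1, length(lag))

  # heuristic starts: linear tail gives slope b = 2 S^2 P and intercept
  # a = 4 sigma^2 - 2 S^2 P^2; try several persistence guesses
  tail_i <- lag >= stats::median(lag)
  lf <- stats::lm.fit(cbind(1, lag[tail_i]), val[tail_i])
  b <- max(lf$coefficients[2], 1e-8)
  a <- lf$coefficients[1]
  p_guesses <- unique(pmax(c(lag[1], mean(lag) / 4, mean(lag)), 1e-3))
  starts <- lapply(p_guesses, function(P0) {
    S0 <- sqrt(b / (2 * P0))
    s0 <- sqrt(max(a + b * P0, 0) / 4)
    c(S = S0, P = P0, sigma_err = max(s0, 1e-3))
  })
  # fixed perturbation grid (not RNG draws) so the fit is a pure function
  # of the curve
  factor_grid <- list(c(0.5, 0.7, 1.6), c(1.8, 0.45, 0.9), c(0.6, 2.0, 1.4),
                      c(1.3, 1.3, 0.5), c(0.4, 1.0, 2.2))
  jitters <- unlist(lapply(starts, function(st) {
    lapply(seq_len(min(n_restarts, length(factor_grid))), function(j)
      st * factor_grid[[j]])
  }), recursive = FALSE)
  starts <- c(starts, jitters)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ eval_prw_msd(S, P, sigma_err, l),
        data = list(v = val, l = lag),
        start = as.list(st),
        lower = c(S = 0, P = 1e-6, sigma_err = 0),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(S = unname(cf["S"]), P = unname(cf["P"]),
                   sigma_err = unname(cf["sigma_err"]), rss = rss,
                   lags = lag,
                   fitted = eval_prw_msd(cf["S"], cf["P"], cf["sigma_err"], lag),
                   convergence = TRUE)
    }
  }
  if (is.null(best)) {
    if (weights == "sem") {
      # strongly uneven SEMs (e.g. mixed-clock cohorts) can make the
      # weighted Jacobian numerically singular; fall back to ordinary LSQ
      warning("weighted PRW fit is singular; falling back to unweighted")
      return(fit_prw_msd(curve, exclude_lags = exclude_lags,
                         weights = "none", n_restarts = n_restarts))
    }
    stop_("PRW MSD fit failed to converge from all %d starts", length(starts))
  }
  class(best) <- "prw_fit"
  best
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf("<prw_fit> S = %.4g um/min, P = %.4g min, sigma_err = %.4g um (rss %.4g, %d lags)\n",
              x$S, x$P, x$sigma_err, x$rss, length(x$lags)))
  invisible(x)
}

#' Snap a continuous persistence time onto the sampling grid
#'
#' Returns the nearest positive multiple of `sampling_dt` (never below one
#' sampling interval; midpoints round up). The step-process models advance
#' on clocks commensurate with the sampling grid, so a fitted continuous
#' persistence of 78 min becomes 68 min on a 34-min grid.
#'
#' @param p_continuous continuous persistence time(s) in min (> 0).
#' @param sampling_dt sampling interval (min).
#' @return discretized persistence(s), multiples of `sampling_dt`.
#' @export
discretize_persistence <- function(p_continuous, sampling_dt) {
  if (any(p_continuous <= 0)) stop_("persistence must be > 0")
  if (sampling_dt <= 0) stop_("sampling_dt must be > 0")
  sampling_dt * pmax(1, floor(p_continuous / sampling_dt + 0.5))
}

#' Per-cell speed and persistence estimates
#'
#' For each cell: `S_i` is the time-mean of the finite-difference speed;
#' the continuous persistence is the lag of the first downward crossing of
#' the cell's normalized velocity autocorrelation through `1/e`, located by
#' linear interpolation between the bracketing lags, then snapped to the
#' sampling grid with [discretize_persistence()]. Cells whose VACF never
#' drops below `1/e` within the observed lags are flagged and assigned the
#' maximum observed lag. The first crossing is used because single-cell
#' VACFs are noisy and may recross.
#'
#' @param traj a [trajectory_table()].
#' @param dt velocity interval (min), see [velocities()].
#' @param sampling_dt grid for the discretization (default: `dt` or the
#'   cell grid spacing).
#' @return data.frame of class `ch_params` with columns `cell_id`, `S_i`,
#'   `P_continuous`, `P_i`, `flagged`.
#' @export
estimate_percell <- function(traj, dt = NULL, sampling_dt = NULL) {
  cl <- split_cells(traj)
  rows <- lapply(cl, function(tc) {
    if (nrow(tc) < 3) stop_("cell %s has fewer than 3 frames", tc$cell_id[1])
    g <- dt %||% cell_dt(tc)
    grid <- sampling_dt %||% g
    vc <- vacf(trajectory_table(tc), dt = dt)
    v <- velocities(trajectory_table(tc), dt = dt)
    S_i <- mean(v$speed)
    thr <- exp(-1)
    below <- which(vc$vacf < thr)
    if (!length(below)) {
      p_cont <- max(vc$lag_min)
      flagged <- TRUE
    } else {
      k <- below[1L]                       # first lag strictly below 1/e
      l1 <- vc$lag_min[k - 1L]; l2 <- vc$lag_min[k]
      c1 <- vc$vacf[k - 1L];   c2 <- vc$vacf[k]
      p_cont <- l1 + (l2 - l1) * (c1 - thr) / (c1 - c2)
      flagged <- FALSE
    }
    data.frame(cell_id = tc$cell_id[1], S_i = S_i, P_continuous = p_cont,
               P_i = discretize_persistence(p_cont, grid), flagged = flagged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$flagged))
    warning(sprintf("%d cell(s) never crossed 1/e; persistence set to the maximum observed lag",
                    sum(out$flagged)))
  class(out) <- c("ch_params", "data.frame")
  out
}

#' Empirical displacement-magnitude sampler
#'
#' Stores the displacement magnitudes observed at a reference lag and draws
#' from them by inverse-transform sampling: a uniform variate is mapped
#' through the sample quantile function with linear interpolation between
#' order statistics (so draws always lie within the observed range). This
#' is the step-magnitude source `beta(t)` of the TH/CTH models: sampling
#' from the distribution of `2*pi*r*G(r, t = P)` (ensemble scope) or
#' `2*pi*r*g_i(r, t = P_i)` (single-cell scope).
#'
#' @param traj a [trajectory_table()].
#' @param lag reference lag (min).
#' @param scope `"ensemble"` (pool all cells) or a single cell id.
#' @return an object of class `displacement_sampler`.
#' @export
build_displacement_sampler <- function(traj, lag, scope = "ensemble") {
  mags <- if (identical(scope, "ensemble")) {
    displacement_magnitudes(traj, lag)
  } else {
    displacement_magnitudes(traj, lag, cells = scope)
  }
  if (length(mags) < 2)
    stop_("need >= 2 displacement samples at lag %g in scope '%s'",
          lag, paste(scope, collapse = ","))
  displacement_sampler(mags, lag, scope = scope)
}

#' @param magnitudes raw displacement magnitudes (um, >= 0).
#' @rdname build_displacement_sampler
#' @export
displacement_sampler <- function(magnitudes, lag, scope = "custom") {
  if (!length(magnitudes) || any(!is.finite(magnitudes)) || any(magnitudes < 0))
    stop_("magnitudes must be finite and >= 0")
  structure(list(magnitudes = sort(as.numeric(magnitudes)), lag = lag,
                 scope = scope),
            class = "displacement_sampler")
}

#' Draw from a displacement sampler
#'
#' @param sampler a `displacement_sampler`.
#' @param n number of draws (uniforms generated internally), or
#' @param u explicit uniforms in `[0, 1]` to push through the inverse CDF.
#' @param seed integer seed or NULL.
#' @return numeric vector of magnitudes.
#' @export
draw_displacements <- function(sampler, n = NULL, u = NULL, seed = NULL) {
  stopifnot(inherits(sampler, "displacement_sampler"))
  if (is.null(u)) {
    if (is.null(n)) stop_("give either n or u")
    u <- with_seed(seed, runif(n))
  }
  if (any(u < 0 | u > 1)) stop_("u must lie in [0, 1]")
  quantile(sampler$magnitudes, probs = u, names = FALSE, type = 7)
}

#' @export
print.displacement_sampler <- function(x, ...) {
  cat(sprintf("<displacement_sampler> %d magnitudes at lag %g min (scope %s), range [%.3g, %.3g] um\n",
              length(x$magnitudes), x$lag, x$scope,
              min(x$magnitudes), max(x$magnitudes)))
  invisible(x)
}

# ensemble-mean MSD of the step models at the reference lags, averaged over
# replicates with fixed per-replicate seeds (smooth in A)
step_model_msd <- function(A, model, sampler, step_dt, n_cells, duration,
                           lags, n_replicates, seed_base) {
  acc <- 0
  for (r in seq_len(n_replicates)) {
    traj <- if (model == "th") {
      simulate_th(n_cells, duration, sampler, A = A, step_dt = step_dt,
                  seed = seed_base + r)
    } else {
      simulate_cth(sampler, step_dt, duration, A = A, seed = seed_base + r)
    }
    acc <- acc + msd(traj, lags = lags)$msd_um2
  }
  acc / n_replicates
}

#' Calibrate the memory parameter of a step model against a reference MSD
#'
#' Golden-section search over the memory parameter `A`, minimising the
#' squared deviation between the replicate-averaged ensemble MSD of the
#' simulated step model and the reference MSD at the reference lags. When
#' the reference curve carries per-lag SEMs (as [msd()] reports) the
#' deviations are weighted by `1/SEM^2` — the same generalized
#' least-squares convention as [fit_prw_msd()], since the sampling
#' variance of a cohort MSD grows steeply with lag. The per-replicate
#' seeds are held fixed across evaluations so the objective is smooth in
#' `A`.
#'
#' @param reference an `msd_curve` (or data.frame with `lag_min`,
#'   `msd_um2`); lags incommensurate with the step clock(s) are dropped.
#' @param sampler a `displacement_sampler` (TH) or list of per-cell
#'   samplers (CTH).
#' @param step_dt step clock in min (TH) or per-cell vector (CTH).
#' @param model `"th"` or `"cth"`.
#' @param n_cells cells per replicate (TH; for CTH it is `length(sampler)`).
#' @param duration simulated time per replicate (min).
#' @param n_replicates replicates averaged per objective evaluation.
#' @param A_range search interval.
#' @param tol absolute tolerance on A.
#' @param seed integer seed (fixes the replicate seeds).
#' @return list of class `memory_fit`: `A`, `objective`, `lags`, `model`.
#' @export
calibrate_memory <- function(reference, sampler, step_dt,
                             model = c("th", "cth"),
                             n_cells = NULL, duration = 1292,
                             n_replicates = 50, A_range = c(1.01, 20),
                             tol = 0.01, seed = 1L) {
  model <- match.arg(model)
  if (model == "th") {
    stopifnot(inherits(sampler, "displacement_sampler"), length(step_dt) == 1L)
    if (is.null(n_cells)) stop_("n_cells is required for the TH model")
    lag_ok <- vapply(reference$lag_min, is_multiple, TRUE, base = step_dt)
  } else {
    stopifnot(is.list(sampler), length(sampler) == length(step_dt))
    n_cells <- length(sampler)
    lag_ok <- vapply(reference$lag_min, function(l)
      any(vapply(step_dt, function(p) is_multiple(l, p) && l <= duration - p,
                 TRUE)), TRUE)
  }
  lag_ok <- lag_ok & reference$lag_min > 0 &
    reference$lag_min <= duration - min(step_dt)
  lags <- reference$lag_min[lag_ok]
  ref <- reference$msd_um2[lag_ok]
  if (length(lags) < 2) stop_("fewer than 2 usable reference lags")
  w <- if ("sem_um2" %in% names(reference) &&
           all(is.finite(reference$sem_um2[lag_ok])) &&
           all(reference$sem_um2[lag_ok] > 0)) {
    1 / reference$sem_um2[lag_ok]^2
  } else rep(1, length(lags))
  seed_base <- as.integer(seed) * 1000L
  obj <- function(A) {
    m <- step_model_msd(A, model, sampler, step_dt, n_cells, duration,
                        lags, n_replicates, seed_base)
    v <- sum(w * (m - ref)^2)
    if (!is.finite(v)) stop_("non-finite calibration objective at A = %g", A)
    v
  }
  phi <- (sqrt(5) - 1) / 2
  a <- A_range[1]; b <- A_range[2]
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- obj(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- obj(x2)
    }
  }
  A_hat <- (a + b) / 2
  structure(list(A = A_hat, objective = obj(A_hat), lags = lags,
                 model = model),
            class = "memory_fit")
}

#' @export
print.memory_fit <- function(x, ...) {
  cat(sprintf("<memory_fit> %s model: A = %.3f (objective %.4g over %d lags)\n",
              toupper(x$model), x$A, x$objective, length(x$lags)))
  invisible(x)
}
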