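#' Finite-difference velocities
#'
#' `v(t) = (r(t + dt) - r(t)) / dt` per cell. By default `dt` is each
#' cell's own sampling interval; a larger `dt` must be an integer multiple
#' of it (positions are then subsampled first).
#'
#' @param traj a [trajectory_table()].
#' @param dt velocity interval (min) or NULL for each cell's grid spacing.
#' @return data.frame with columns `cell_id`, `t_min` (interval start),
#'   `vx`, `vy`, `speed` (um/min).
#' @export
velocities <- function(traj, dt = NULL) {
  cells <- split_cells(traj)
  out <- lapply(cells, function(tc) {
    g <- cell_dt(tc)
    use_dt <- dt %||% g
    if (!is_multiple(use_dt, g) || use_dt < g)
      stop_("dt = %g is not a multiple of cell %s's grid spacing (%g)",
            use_dt, tc$cell_id[1], g)
    k <- as.integer(round(use_dt / g))
    idx <- seq(1L, nrow(tc), by = k)
    if (length(idx) < 2) return(NULL)
    x <- tc$x_um[idx]; y <- tc$y_um[idx]
    vx <- diff(x) / use_dt; vy <- diff(y) / use_dt
    data.frame(cell_id = tc$cell_id[1], t_min = tc$t_min[idx[-length(idx)]],
               vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

# per-cell time-averaged MSD of one cell at the requested lags;
# NA where the lag is not a positive multiple of the cell's grid or exceeds
# its span (the commensurate-lag rule used for mixed-clock cohorts)
msd_one_cell <- function(tc, lags) {
  g <- cell_dt(tc)
  n <- nrow(tc)
  vapply(lags, function(lag) {
    if (lag == 0) return(0)
    if (!is_multiple(lag, g)) return(NA_real_)
    k <- as.integer(round(lag / g))
    if (k >= n) return(NA_real_)
    i <- seq_len(n - k)
    mean((tc$x_um[i + k] - tc$x_um[i])^2 + (tc$y_um[i + k] - tc$y_um[i])^2)
  }, numeric(1))
}

#' Mean-square displacement
#'
#' Time-origin-averaged MSD per cell (all overlapping origins), then
#' averaged over cells; the per-lag standard error is the SEM across cells.
#' For cohorts in which cells sit on different step clocks, a cell
#' contributes at a lag only if the lag is a multiple of its own clock
#' (`n_cells` is reported per lag).
#'
#' @param traj a [trajectory_table()].
#' @param lags lags in min; default: all multiples of the finest cell grid
#'   up to the shortest cell span.
#' @return a data.frame of class `msd_curve` with columns `lag_min`,
#'   `msd_um2`, `sem_um2`, `n_cells`.
#' @export
msd <- function(traj, lags = NULL) {
  cells <- split_cells(traj)
  if (is.null(lags)) {
    g <- min(vapply(cells, cell_dt, numeric(1)))
    span <- min(vapply(cells, function(tc) diff(range(tc$t_min)), numeric(1)))
    lags <- g * seq_len(floor(span / g - 1e-9))
    if (!length(lags)) lags <- g
  }
  if (any(lags < 0)) stop_("lags must be >= 0")
  span_max <- max(vapply(cells, function(tc) diff(range(tc$t_min)), numeric(1)))
  if (any(lags >= span_max + 1e-9) && all(lags >= span_max + 1e-9))
    stop_("all requested lags exceed the trajectory duration")
  per_cell <- vapply(cells, msd_one_cell, numeric(length(lags)), lags = lags)
  per_cell <- matrix(per_cell, nrow = length(lags))
  m   <- apply(per_cell, 1, function(z) mean(z, na.rm = TRUE))
  nc  <- apply(per_cell, 1, function(z) sum(!is.na(z)))
  sem <- apply(per_cell, 1, function(z) {
    z <- z[!is.na(z)]
    if (length(z) < 2) return(NA_real_)
    sd(z) / sqrt(length(z))
  })
  if (any(nc == 0))
    stop_("no cell supports lag(s): %s",
          paste(lags[nc == 0], collapse = ", "))
  out <- data.frame(lag_min = lags, msd_um2 = m, sem_um2 = sem, n_cells = nc)
  class(out) <- c("msd_curve", "data.frame")
  out
}

# fast MSD for regular-grid position matrices ((n_t+1) x n_cells, spacing dt)
msd_matrix <- function(x, y, dt, lags) {
  n <- nrow(x)
  vapply(lags, function(lag) {
    k <- as.integer(round(lag / dt))
    if (k <= 0 || k >= n) return(NA_real_)
    i <- seq_len(n - k)
    mean(colMeans((x[i + k, , drop = FALSE] - x[i, , drop = FALSE])^2 +
                  (y[i + k, , drop = FALSE] - y[i, , drop = FALSE])^2))
  }, numeric(1))
}

# displacement magnitudes of one cell at a lag (all overlapping origins)
displ_one_cell <- function(tc, lag) {
  g <- cell_dt(tc)
  if (!is_multiple(lag, g)) return(numeric(0))
  k <- as.integer(round(lag / g))
  n <- nrow(tc)
  if (k >= n) return(numeric(0))
  i <- seq_len(n - k)
  sqrt((tc$x_um[i + k] - tc$x_um[i])^2 + (tc$y_um[i + k] - tc$y_um[i])^2)
}

#' Displacement magnitudes at a lag
#'
#' Pools `|r(t + lag) - r(t)|` over all overlapping time origins, for one
#' cell or the whole cohort. Cells whose step clock is incommensurate with
#' the lag are skipped.
#'
#' @param traj a [trajectory_table()].
#' @param lag lag in min.
#' @param cells cell ids to include (default: all).
#' @return numeric vector of magnitudes (um).
#' @export
displacement_magnitudes <- function(traj, lag, cells = NULL) {
  cl <- split_cells(traj)
  if (!is.null(cells)) cl <- cl[as.character(cells)]
  unlist(lapply(cl, displ_one_cell, lag = lag), use.names = FALSE)
}

default_bin_edges <- function(max_r, bin_width) {
  hi <- max(bin_width, ceiling((max_r + 1e-9) / bin_width) * bin_width)
  seq(0, hi, by = bin_width)
}

make_correlation_curve <- function(mags, lag, bin_edges, cell_id) {
  if (!length(mags)) stop_("no displacement origins available at lag %g", lag)
  if (max(mags) >= max(bin_edges))
    stop_("bin_edges do not cover the largest displacement (%.3g um)", max(mags))
  counts <- graphics::hist(mags, breaks = bin_edges, plot = FALSE,
                           right = FALSE)$counts
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  p <- counts / length(mags)
  density <- p / (pi * (hi^2 - lo^2))   # per-area density; 2*pi*r*g is radial
  out <- data.frame(lag_min = lag, bin_lo_um = lo, bin_hi_um = hi,
                    r_um = (lo + hi) / 2, density_per_um2 = density)
  attr(out, "cell_id") <- cell_id
  attr(out, "n_origins") <- length(mags)
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Self-correlation function of a single cell, g_i(r, t)
#'
#' Radial probability density of the displacement magnitude of one cell at
#' a fixed lag, averaged over time origins: `2*pi*r*g_i(r, t)` integrates
#' to 1 over r. Densities are reported per area (um^-2) at bin
#' mid-radius, with annulus-area normalisation, so the binned curve obeys
#' `sum(density * pi * (hi^2 - lo^2)) = 1` exactly.
#'
#' @param traj a [trajectory_table()] (one cell, or use `cell_id`).
#' @param lag lag in min (multiple of the cell's grid).
#' @param bin_edges radial bin edges (um), or NULL to build them from
#'   `bin_width`.
#' @param bin_width default radial bin width (um); 2.5 um (half a pixel)
#'   resolves the far tail while keeping counts per bin reasonable.
#' @param cell_id which cell to use when `traj` holds several.
#' @return a data.frame of class `correlation_curve`.
#' @export
self_correlation_single <- function(traj, lag, bin_edges = NULL,
                                    bin_width = 2.5, cell_id = NULL) {
  cl <- split_cells(traj)
  if (is.null(cell_id)) {
    if (length(cl) != 1L)
      stop_("traj has %d cells; pass cell_id", length(cl))
    tc <- cl[[1L]]
  } else {
    tc <- cl[[as.character(cell_id)]]
    if (is.null(tc)) stop_("no cell '%s' in trajectory table", cell_id)
  }
  mags <- displ_one_cell(tc, lag)
  if (!length(mags))
    stop_("cell %s has no origins at lag %g (incommensurate or too long)",
          tc$cell_id[1], lag)
  bin_edges <- bin_edges %||% default_bin_edges(max(mags), bin_width)
  make_correlation_curve(mags, lag, bin_edges, tc$cell_id[1])
}

#' Ensemble self-correlation function G(r, t)
#'
#' Unweighted mean of the per-cell curves `g_i(r, t)` over the cells that
#' support the lag, on a common set of radial bins. Shares the
#' normalisation invariant of [self_correlation_single()].
#'
#' @inheritParams self_correlation_single
#' @return a data.frame of class `correlation_curve` with attribute
#'   `n_cells`.
#' @export
self_correlation_ensemble <- function(traj, lag, bin_edges = NULL,
                                      bin_width = 2.5) {
  cl <- split_cells(traj)
  mags_list <- lapply(cl, displ_one_cell, lag = lag)
  keep <- vapply(mags_list, length, 0L) > 0
  if (!any(keep)) stop_("no cells support lag %g", lag)
  mags_all <- unlist(mags_list[keep], use.names = FALSE)
  bin_edges <- bin_edges %||% default_bin_edges(max(mags_all), bin_width)
  curves <- lapply(which(keep), function(i)
    make_correlation_curve(mags_list[[i]], lag, bin_edges, names(cl)[i]))
  dens <- rowMeans(vapply(curves, function(cv) cv$density_per_um2,
                          numeric(length(bin_edges) - 1L)))
  out <- curves[[1L]]
  out$density_per_um2 <- dens
  attr(out, "cell_id") <- "ensemble"
  attr(out, "n_cells") <- sum(keep)
  attr(out, "n_origins") <- length(mags_all)
  out
}

#' Gaussian reference correlation curve
#'
#' The 2-D Gaussian self-correlation with the given mean-square
#' displacement, `G(r) = exp(-r^2 / msd) / (pi * msd)`, evaluated at bin
#' mid-radii. This is the curve a homogeneous random walk would follow;
#' plotted alongside measured curves it serves as the Gaussian guideline.
#'
#' @param lag lag in min (stored in the output).
#' @param msd_value mean-square displacement at the lag (um^2, > 0).
#' @param bin_edges radial bin edges (um).
#' @return a data.frame of class `correlation_curve`.
#' @export
gaussian_reference <- function(lag, msd_value, bin_edges) {
  if (msd_value <= 0) stop_("msd_value must be > 0")
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  r <- (lo + hi) / 2
  out <- data.frame(lag_min = lag, bin_lo_um = lo, bin_hi_um = hi, r_um = r,
                    density_per_um2 = exp(-r^2 / msd_value) / (pi * msd_value))
  attr(out, "cell_id") <- "gaussian"
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Rescaled per-cell correlation curves
#'
#' Transforms each per-cell curve to dimensionless coordinates
#' `u = r / r*` and `pi * r*^2 * g_i` (with `r*` the cell's root-mean-square
#' displacement at the lag), pools the transformed points of all cells, and
#' bins them on the x axis. A Gaussian cell maps onto `exp(-u^2)` for any
#' `r*`, so homogeneous-statistics cohorts collapse onto that single curve.
#'
#' @param curves list of per-cell `correlation_curve`s at a common lag.
#' @param r_star per-cell RMS displacement at the lag (um, > 0); cells with
#'   `r_star == 0` are dropped with a warning.
#' @param x_bin_width bin width on the dimensionless `u = r/r*` axis
#'   (default 0.25).
#' @return data.frame of class `rescaled_curve` with columns `u_mid`,
#'   `mean`, `sem` and `n`: per x-bin, each contributing cell's points are
#'   first averaged, then the mean, SEM and count are taken over cells
#'   (empty bins are dropped).
#' @export
rescale_correlation <- function(curves, r_star, x_bin_width = 0.25) {
  if (length(curves) != length(r_star))
    stop_("need one r_star per curve")
  drop <- !(r_star > 0)
  if (any(drop)) {
    warning(sprintf("%d cell(s) with r* = 0 excluded from rescaling", sum(drop)))
    curves <- curves[!drop]; r_star <- r_star[!drop]
  }
  if (!length(curves)) stop_("no cells left to rescale")
  u <- unlist(mapply(function(cv, rs) cv$r_um / rs, curves, r_star,
                     SIMPLIFY = FALSE))
  v <- unlist(mapply(function(cv, rs) pi * rs^2 * cv$density_per_um2,
                     curves, r_star, SIMPLIFY = FALSE))
  cell <- rep(seq_along(curves), vapply(curves, nrow, 0L))
  edges <- seq(0, max(u) + x_bin_width, by = x_bin_width)
  bin <- findInterval(u, edges, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    # one value per cell per bin (its mean there), then mean/SEM over cells
    vb <- tapply(v[bin == b], cell[bin == b], mean)
    data.frame(u_mid = (edges[b] + edges[b + 1]) / 2,
               mean = mean(vb),
               sem = if (length(vb) > 1) sd(vb) / sqrt(length(vb)) else 0,
               n = length(vb))
  }))
  class(out) <- c("rescaled_curve", "data.frame")
  out
}

#' Rescaled g_i curves straight from a trajectory table
#'
#' Convenience wrapper: per-cell correlation curves at `lag`, per-cell
#' `r*` from the time-averaged MSD, then [rescale_correlation()]. Cells
#' that do not support the lag are skipped.
#'
#' @inheritParams self_correlation_single
#' @inheritParams rescale_correlation
#' @return a `rescaled_curve` data.frame.
#' @export
rescaled_gi <- function(traj, lag, bin_width = 2.5, x_bin_width = 0.25) {
  cl <- split_cells(traj)
  mags_list <- lapply(cl, displ_one_cell, lag = lag)
  keep <- vapply(mags_list, length, 0L) > 0
  if (!any(keep)) stop_("no cells support lag %g", lag)
  curves <- list(); r_star <- numeric(0)
  for (i in which(keep)) {
    mags <- mags_list[[i]]
    edges <- default_bin_edges(max(mags), bin_width)
    curves[[length(curves) + 1L]] <-
      make_correlation_curve(mags, lag, edges, names(cl)[i])
    r_star <- c(r_star, sqrt(mean(mags^2)))
  }
  rescale_correlation(curves, r_star, x_bin_width)
}

#' Normalized velocity autocorrelation of one cell
#'
#' `C(k dt) = <v(t + k dt) . v(t)>_t / <v(t) . v(t)>_t` from
#' finite-difference velocities on the cell's grid; `C(0) = 1` by
#' construction. Note that for an OU velocity process sampled at finite
#' `dt` the autocorrelation of finite-difference velocities decays with the
#' same rate `exp(-dt/P)` as the instantaneous process but with a different
#' amplitude at the first lag; the instantaneous law `exp(-t/P)` is tested
#' with [velocity_autocorrelation()] on simulator-provided velocities.
#'
#' @param traj a [trajectory_table()] holding one cell (or use `cell_id`).
#' @param dt velocity interval, see [velocities()].
#' @param cell_id which cell if `traj` holds several.
#' @return data.frame with columns `lag_min`, `vacf`.
#' @export
vacf <- function(traj, dt = NULL, cell_id = NULL) {
  cl <- split_cells(traj)
  tc <- if (is.null(cell_id)) {
    if (length(cl) != 1L) stop_("traj has %d cells; pass cell_id", length(cl))
    cl[[1L]]
  } else cl[[as.character(cell_id)]]
  if (is.null(tc)) stop_("no cell '%s' in trajectory table", cell_id)
  if (nrow(tc) < 3) stop_("need >= 3 frames for a VACF")
  v <- velocities(trajectory_table(tc), dt = dt)
  vx <- v$vx; vy <- v$vy
  n <- length(vx)
  c0 <- mean(vx^2 + vy^2)
  if (c0 == 0) stop_("zero-variance velocity; VACF undefined")
  use_dt <- (dt %||% cell_dt(tc))
  ck <- vapply(0:(n - 1L), function(k) {
    i <- seq_len(n - k)
    mean(vx[i + k] * vx[i] + vy[i + k] * vy[i])
  }, numeric(1))
  data.frame(lag_min = (0:(n - 1L)) * use_dt, vacf = ck / c0)
}

#' Cohort-mean velocity autocorrelation from velocity matrices
#'
#' Normalized autocorrelation pooled over cells and time origins, for
#' velocity component matrices (time x cell) such as the instantaneous
#' velocities returned by [simulate_ho()] with `return_velocities = TRUE`.
#' For the OU process this estimates `exp(-t/P)` without the
#' finite-difference amplitude bias.
#'
#' @param vx,vy velocity component matrices (time x cell).
#' @param dt spacing of the velocity samples (min).
#' @param max_lag largest lag index to report.
#' @return data.frame with columns `lag_min`, `vacf`.
#' @export
velocity_autocorrelation <- function(vx, vy, dt, max_lag = nrow(vx) - 1L) {
  n <- nrow(vx)
  max_lag <- min(max_lag, n - 1L)
  c0 <- mean(vx^2 + vy^2)
  ck <- vapply(0:max_lag, function(k) {
    i <- seq_len(n - k)
    mean(vx[i + k, ] * vx[i, ] + vy[i + k, ] * vy[i, ])
  }, numeric(1))
  data.frame(lag_min = (0:max_lag) * dt, vacf = ck / c0)
}

# acceleration decomposition from velocity component matrices
# (time x cell); returns pooled samples
accel_samples <- function(vx, vy, dt) {
  n <- nrow(vx)
  if (n < 2) stop_("need >= 2 velocity samples per cell")
  i <- seq_len(n - 1L)
  ax <- (vx[i + 1L, , drop = FALSE] - vx[i, , drop = FALSE]) / dt
  ay <- (vy[i + 1L, , drop = FALSE] - vy[i, , drop = FALSE]) / dt
  vx0 <- vx[i, , drop = FALSE]; vy0 <- vy[i, , drop = FALSE]
  sp <- sqrt(vx0^2 + vy0^2)
  ok <- sp > 0
  data.frame(speed = sp[ok],
             a_p  = (ax[ok] * vx0[ok] + ay[ok] * vy0[ok]) / sp[ok],
             a_np = (vx0[ok] * ay[ok] - vy0[ok] * ax[ok]) / sp[ok])
}

bin_accel <- function(samples, speed_bin_width, min_count) {
  bin <- floor(samples$speed / speed_bin_width)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    s <- samples[bin == b, ]
    if (nrow(s) < min_count) return(NULL)
    mp <- mean(s$a_p); mn <- mean(s$a_np)
    data.frame(speed_mid = (b + 0.5) * speed_bin_width,
               a_p_mean = mp, a_np_mean = mn,
               a_p_mean_dev = mean(abs(s$a_p - mp)),
               a_np_mean_dev = mean(abs(s$a_np - mn)),
               a_p_sem = sd(s$a_p) / sqrt(nrow(s)),
               a_np_sem = sd(s$a_np) / sqrt(nrow(s)),
               n = nrow(s))
  }))
  class(out) <- c("accel_stats", "data.frame")
  out
}

#' Speed-conditioned acceleration decomposition
#'
#' Finite-difference acceleration `a(t) = (v(t + dt) - v(t)) / dt` split
#' into the component along the current velocity (`a_p`, the deterministic
#' relaxation, which for a PRW follows `-v/P`) and the signed orthogonal
#' component (`a_np`, zero-mean noise). Samples are pooled over cells and
#' binned by speed; per bin the conditional means, mean absolute
#' deviations, SEMs and counts are reported. Samples with zero speed are
#' skipped (the projection is undefined there).
#'
#' @param traj a [trajectory_table()].
#' @param dt velocity interval, see [velocities()].
#' @param speed_bin_width bin width in um/min (default 0.05).
#' @param min_count bins with fewer samples are suppressed (default 10).
#' @return data.frame of class `accel_stats`.
#' @export
acceleration_stats <- function(traj, dt = NULL, speed_bin_width = 0.05,
                               min_count = 10L) {
  cl <- split_cells(traj)
  samples <- do.call(rbind, lapply(cl, function(tc) {
    if (nrow(tc) < 3) return(NULL)
    v <- velocities(trajectory_table(tc), dt = dt)
    use_dt <- dt %||% cell_dt(tc)
    accel_samples(matrix(v$vx, ncol = 1), matrix(v$vy, ncol = 1), use_dt)
  }))
  if (is.null(samples) || !nrow(samples))
    stop_("no usable acceleration samples (need >= 3 frames per cell)")
  bin_accel(samples, speed_bin_width, min_count)
}

#' @rdname acceleration_stats
#' @param vx,vy instantaneous velocity matrices (time x cell) and their
#'   sampling interval `dt`; use this form to measure the model's drift
#'   without finite-difference sampling bias.
#' @export
acceleration_stats_v <- function(vx, vy, dt, speed_bin_width = 0.05,
                                 min_count = 10L) {
  bin_accel(accel_samples(vx, vy, dt), speed_bin_width, min_count)
}
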