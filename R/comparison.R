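#' Replicate-ensemble MSD summary
#'
#' Simulates `n_replicates` cohorts with a user-supplied generator and
#' summarises the ensemble MSD per lag by its mean and sample standard
#' deviation across replicates (the spread a whole observed cohort is
#' compared against in [chi2_pvalue()]).
#'
#' @param sim_fun function(seed) returning a [trajectory_table()].
#' @param lags lags (min) at which to evaluate the MSD.
#' @param n_replicates number of replicate simulations (>= 2, default 50).
#' @param seed integer; replicate r uses seed `seed * 1000 + r`.
#' @return data.frame of class `ensemble_summary` with columns `lag_min`,
#'   `mean_um2`, `sd_um2`; attribute `n_replicates`.
#' @export
ensemble_msd <- function(sim_fun, lags, n_replicates = 50, seed = 1L) {
  if (n_replicates < 2) stop_("need >= 2 replicates")
  vals <- vapply(seq_len(n_replicates), function(r) {
    traj <- sim_fun(as.integer(seed) * 1000L + r)
    msd(traj, lags = lags)$msd_um2
  }, numeric(length(lags)))
  vals <- matrix(vals, nrow = length(lags))
  out <- data.frame(lag_min = lags,
                    mean_um2 = rowMeans(vals),
                    sd_um2 = apply(vals, 1, sd))
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' Chi-squared consistency of an observed MSD with a simulation ensemble
#'
#' `chi2 = sum((obs - mean)^2 / sd^2)` over the shared lags (after
#' exclusions), with the ensemble mean and replicate standard deviation
#' from [ensemble_msd()]; the p-value is the upper tail of the chi-squared
#' distribution with one degree of freedom per included lag (no
#' parameter-count correction, since model parameters are estimated from
#' the same data). Because one cohort's MSD deviations are correlated
#' across lags, the statistic is overdispersed relative to a true
#' chi-squared; treat the p-values comparatively across models rather than
#' as exact tail probabilities.
#'
#' @param observed an `msd_curve` (columns `lag_min`, `msd_um2`).
#' @param ensemble an `ensemble_summary`.
#' @param exclude_lags lags to drop (default 34 min, the lag at the
#'   spatial-resolution limit).
#' @return list with `chi2`, `dof`, `p`.
#' @export
chi2_pvalue <- function(observed, ensemble, exclude_lags = 34) {
  m <- merge(as.data.frame(observed)[, c("lag_min", "msd_um2")],
             as.data.frame(ensemble)[, c("lag_min", "mean_um2", "sd_um2")],
             by = "lag_min")
  keep <- !vapply(m$lag_min, function(l) any(abs(l - exclude_lags) < 1e-9), TRUE)
  m <- m[keep, ]
  if (!nrow(m)) stop_("no shared lags left after exclusion")
  bad <- m$sd_um2 <= 0
  if (any(bad))
    stop_("ensemble standard deviation is zero at lag(s): %s",
          paste(m$lag_min[bad], collapse = ", "))
  chi2 <- sum(((m$msd_um2 - m$mean_um2) / m$sd_um2)^2)
  dof <- nrow(m)
  list(chi2 = chi2, dof = dof, p = pchisq(chi2, dof, lower.tail = FALSE))
}

#' Root mean-squared logarithmic error between two curves
#'
#' `sqrt(mean((log(c + 1) - log(c_hat + 1))^2))` with natural logarithms;
#' symmetric in its arguments, zero iff the curves are identical.
#'
#' @param c_obs,c_hat nonnegative numeric vectors of equal length.
#' @return a nonnegative scalar.
#' @export
rmsle <- function(c_obs, c_hat) {
  if (length(c_obs) != length(c_hat)) stop_("curves must have equal length")
  if (any(c_obs < 0) || any(c_hat < 0)) stop_("RMSLE requires nonnegative values")
  sqrt(mean((log(c_obs + 1) - log(c_hat + 1))^2))
}

#' Non-Gaussian parameter of 2-D displacement magnitudes
#'
#' `alpha_2 = <r^4> / (2 <r^2>^2) - 1` (two-dimensional convention): zero
#' for Gaussian displacements, `-0.5` for fixed-magnitude steps, positive
#' for heavy-tailed (e.g. mixture) displacement distributions.
#'
#' @param r displacement magnitudes (>= 10 values, not all zero).
#' @return alpha_2, dimensionless.
#' @export
non_gaussian_parameter <- function(r) {
  if (length(r) < 10) stop_("need >= 10 displacement magnitudes")
  m2 <- mean(r^2)
  if (m2 == 0) stop_("all displacements are zero; alpha_2 undefined")
  mean(r^4) / (2 * m2^2) - 1
}
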