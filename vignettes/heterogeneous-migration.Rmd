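---
title: "Modelling stochastic and heterogeneous cell migration with cellmig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stochastic and heterogeneous cell migration with cellmig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmig)
```

## The scientific problem

Migrating cells are often described as persistent random walkers: over short
times they keep their direction, over long times they diffuse. Two
experimental observations break the simplest picture. First, the
mean-square displacement (MSD) can be Fickian (linear in time) while the
distribution of displacements is strongly non-Gaussian — heavy-tailed
relative to the diffusive expectation. Second, the non-Gaussianity shows up
not only in the population-averaged self-correlation function $G(r,t)$ but
also in the per-cell functions $g_i(r,t)$, which a population mixture alone
cannot explain.

`cellmig` implements four nested models of 2-D migration and the machinery
to estimate their parameters, simulate them, and rank them against an
observed cohort:

* **HO** (homogeneous): every cell follows the same persistent random walk,
  an Ornstein–Uhlenbeck (OU) velocity process
  $\dot v = -v/P + (S/\sqrt{P})\,\xi(t)$ with persistence time $P$ (min)
  and speed scale $S$ (µm/min). Its 2-D MSD is
  $\langle\Delta r^2(t)\rangle = 2S^2P^2(e^{-t/P} + t/P - 1) + 4\sigma_{err}^2$,
  where $\sigma_{err}$ is the localization error of the position
  measurement.
* **CH** (cellular heterogeneity): each cell has its own $(S_i, P_i)$,
  fixed in time. Per-cell statistics stay Gaussian; the ensemble $G$
  becomes a non-Gaussian mixture.
* **TH** (temporal heterogeneity): a step process on a fixed clock
  $dt = P$, $d\vec r(t+dt) = d\vec r(t)/A + \beta(t)\,\hat\xi$, with the
  step magnitude $\beta(t)$ redrawn every step from an empirical
  displacement distribution (inverse-transform sampling of the observed
  $2\pi r\,G(r, t\!=\!P)$) and $\hat\xi$ a uniformly random direction. The
  memory parameter $A > 1$ plays the role of $e^{dt/P}$ in an OU process.
  All cells are statistically identical, but each cell's step magnitude
  switches over time, making the per-cell $g_i$ non-Gaussian.
* **CTH** (combined): as TH, but cell $i$ advances on its own clock $P_i$
  and draws $\beta_i(t)$ from its own per-cell distribution
  $2\pi r\,g_i(r, t\!=\!P_i)$, so the cohort is heterogeneous both across
  cells and in time.

The canonical study design used throughout the defaults is a cohort of 212
cells observed for 1292 min at 34-min sampling, with
$S = 0.125\ \mu m/min$, $P = 78\ min$ and $\sigma_{err} = 1.66\ \mu m$ —
the parameter scale of a lung-carcinoma time-lapse experiment at 5 µm/pixel
resolution.

## Estimation pipeline

1. **Homogeneous fit.** `fit_prw_msd()` fits the analytic PRW MSD to the
   time-origin- and cell-averaged MSD by nonlinear least squares with
   positivity constraints and multi-start initialisation. When the curve
   carries per-lag SEMs (as `msd()` reports) the fit is weighted by
   $1/\mathrm{SEM}^2$: the cell-to-cell variance of time-averaged MSDs
   grows steeply with lag, and an unweighted fit would be dominated by the
   noisiest points. If the weighted Jacobian is numerically singular
   (possible for mixed-clock cohorts whose lag coverage is uneven) the fit
   falls back to ordinary least squares with a warning.
2. **Per-cell parameters.** `estimate_percell()` sets $S_i$ to the
   time-mean finite-difference speed and $P_i$ to the first downward
   crossing of the per-cell velocity autocorrelation through $1/e$,
   linearly interpolated between the bracketing lags, then snapped to the
   sampling grid. The *first* crossing is used because single-cell VACFs
   are noisy and may recross.
3. **Discretization.** `discretize_persistence()` maps a continuous
   persistence to the nearest positive multiple of the sampling interval
   (never below one interval). The nearest-multiple convention is chosen
   over literal rounding up because it reproduces the canonical mapping
   78 min → 68 min on a 34-min grid, which is what the step models use.
4. **Step-magnitude samplers.** `build_displacement_sampler()` collects
   displacement magnitudes at the reference lag and inverts the empirical
   CDF by the sample quantile function with linear interpolation between
   order statistics (draws therefore stay inside the observed range and
   no histogram bin width enters).
5. **Memory calibration.** `calibrate_memory()` finds $A$ by
   golden-section search on $[1.01, 20]$, minimising the squared deviation
   between the reference MSD and the model's ensemble MSD averaged over
   replicates; the per-replicate seeds are held fixed across evaluations
   so the objective is a smooth function of $A$.

## Finite-sampling effects, deliberately kept

Statistics computed from positions sampled every $\Delta t = 34$ min are
*not* the continuous-time statistics, and the package does not pretend
otherwise:

* The autocorrelation of finite-difference velocities of an integrated OU
  process decays at the rate $e^{-\Delta t/P}$ but with an inflated
  amplitude at the first lag
  ($\rho_1 = (1-c)^2 / (2(\Delta t/P - 1 + c))$ with $c = e^{-\Delta t/P}$;
  $\rho_1 \approx 0.755$ vs $e^{-34/78} \approx 0.647$ at the canonical
  parameters). Consequently the $1/e$-crossing estimator applied to HO
  data at 34-min sampling is biased above the true $P$, and localization
  error biases it down. The tests check the estimator against these exact
  finite-sampling expressions; the continuous-time laws
  ($\mathrm{VACF} = e^{-t/P}$, acceleration drift slope $-1/P$) are
  verified on instantaneous velocities, which the simulator can return.
* Similarly, the speed-conditioned mean parallel acceleration
  $\langle a_p\rangle_v$ of finite-difference velocities has slope
  $(\rho_1 - 1)/\Delta t$, which approaches $-\tfrac{2}{3P}$ (not $-1/P$)
  as $\Delta t \to 0$; the $-1/P$ law holds for instantaneous velocities.
  `acceleration_stats_v()` exists for exactly this purpose.

## The synthetic-data generator

`gen_population()` draws per-cell $(S_i, P_i)$ from configurable laws,
log-normal by default (positive support and right skew match the broad
per-cell parameter spreads of tracked cohorts): speed with mean
0.125 µm/min and CV 0.45, persistence with mean 78 min and CV 0.5, snapped
to the sampling grid and capped at `duration/4` so that every cell
completes several steps of the step-process models within the observation
window.

`gen_reference_cohort()` provides the four canonical scenarios. Two details
matter:

* **Step-magnitude sources must be non-Rayleigh.** If $\beta$ were drawn
  from the displacement distribution of a homogeneous OU cohort (a
  Rayleigh law), $\beta\hat\xi$ would be exactly Gaussian and the
  "temporal switching" would be statistically invisible. The TH scenario
  therefore builds its shared sampler from a cellularly heterogeneous
  donor ensemble (a scale mixture, as an experimental ensemble $G$ is),
  and the CTH scenario gives each cell a two-state fast/slow mixture
  (magnitudes pooled from donors migrating at $2S_i$ and $S_i/2$),
  emulating cells that switch between migration states.
* **Image stacks.** `gen_image_stack()` renders each cell as a radially
  symmetric nucleus: a flat dark core rising quartically to a bright rim
  at the nucleus radius (20 µm default), on a mid-brightness background,
  plus clipped per-pixel Gaussian noise. The contrast polarity (dark
  centre, bright rim) is what the tracker's darkness score $S^2$ and
  threshold score $S^3$ rely on; the flat quartic core keeps a
  several-pixel symmetric region above threshold so the weighted centroid
  is sub-pixel accurate (≈0.07 px worst-case bias noise-free). The
  generator does not attempt phase-contrast optics, cell shape, division
  or collisions; frames default to 2-min spacing with downstream
  subsampling to 34 min.

What passing tests on these cohorts do *not* show: recovery of any real
cell line's parameter values (no per-cell ground truth is published for
the motivating experiment), robustness to segmentation artefacts, shape
dynamics, or interactions — the generator's cells are ideal blobs with
ideal statistics.

## The tracker

`track_stack()` implements weighted-centroid tracking with the three-score
product $S = S^1 S^2 S^3$ evaluated within 50 µm of the previous position:
proximity ($\sigma_1 = 12$ px), darkness ($e^{-f^2/\sigma_2^2}$,
$\sigma_2 = 10$ on the 0–100 brightness scale) and a hard threshold
excluding pixels more than 10 units brighter than the previous centre
pixel. Normalisation constants cancel in the centroid and are set to 1.
Estimates are reported to 0.1 px (0.5 µm at 5 µm/px), the first uncertain
digit. Cells are scored independently; overlapping windows of nearby cells
are not arbitrated (documented behaviour — keep neighbours apart). A
numerical floor (`min_score = 1e-8`) declares a track lost when no pixel
in the window is plausibly nuclear (pure background scores
$\sim e^{-30}$); lost tracks are truncated and flagged, never re-seeded
nor silently dropped.

## Numerical choices

* **OU integration** uses the exact discrete velocity update
  $v \leftarrow v e^{-h/P} + \sqrt{(1 - e^{-2h/P})\,S^2/2}\;\mathcal N(0,1)$
  per component with Euler position accumulation at $h = 0.01$ min
  (velocity-exact at any $h$; the position quadrature error is
  $O(h^2/P^2)$ in the MSD). Initial velocities are stationary draws, so
  there is no equilibration transient; initial positions sit at the
  origin (all statistics are displacement-based). Tests use coarser $h$
  (0.1–1 min) where only sampled-position statistics matter — at
  $h = 1$, $h/P \approx 0.013$ and the MSD bias is below sampling noise
  at the cohort sizes used.
* **TH/CTH first step** has no memory contribution ($d\vec r$ before
  $t = 0$ is undefined).
* **Mixed-clock lags.** CTH trajectories exist only on each cell's own
  step grid. Ensemble statistics at a lag include a cell only when the
  lag is a multiple of its clock (no interpolation); `msd()` reports the
  per-lag cell count.
* **Binning.** Radial bins for $G$/$g_i$ default to 2.5 µm (half a
  pixel); densities are per area (µm⁻²) at bin mid-radius with
  annulus-area normalisation, so
  $\sum_b \mathrm{dens}_b\,\pi(r_{hi}^2 - r_{lo}^2) = 1$ exactly.
  Rescaled curves use $u = r/r^*$ bins of 0.25; within a bin each cell's
  points are averaged first, then mean/SEM are taken across cells. Speed
  bins for the acceleration statistics default to 0.05 µm/min with bins
  under 10 samples suppressed. The bin widths are package choices (the
  histogram conventions of the motivating analysis are not published).
* **Chi-squared comparison** uses the replicate standard deviation
  (sample, $n-1$) of 50-replicate ensembles, degrees of freedom equal to
  the number of included lags (no parameter-count correction, as the
  parameters are fitted on the same data), and excludes the 34-min lag at
  the spatial-resolution limit by default. Because per-lag deviations of
  one cohort are correlated across lags, the statistic is overdispersed
  relative to a true $\chi^2$: same-model p-values are U-shaped rather
  than uniform (the marginal calibration $E[\chi^2/\mathrm{dof}] = 1$
  holds, and the tests check exactly that). P-values should be read
  comparatively across models.
* **RMSLE** uses natural logarithms (the convention of the RMSLE
  literature), computed per curve.

## Problem sizes

The test-suite defaults are scaled to desk hardware as the package's own
choice of study sizes: closed-form checks use 1 500–3 000 cells at
$h = 0.1$ min; parameter-recovery checks use 300–500 cells at
$h = 0.01$ min; memory-parameter calibrations use the canonical 212-cell,
50-replicate design. With the 212-cell reference cohorts the recovered
memory parameter has a sampling standard deviation of roughly 0.1–0.15, so
the ±0.2 recovery band is met in expectation but individual seeds sit near
the edge occasionally — that spread is a property of the study design, not
of the search.

## Known limitations

* The HO/CH speed parameter $S$ is the OU stationary root-mean-square
  speed, while the per-cell estimator $S_i$ is the *mean*
  finite-difference speed; for a 2-D OU process the mean speed is
  $\sqrt{\pi}/2 \approx 0.886$ of the RMS speed, further attenuated by
  finite-difference sampling. The estimator follows the operational
  definition (mean speed per cell) rather than correcting the factor;
  parameter tables mixing the two conventions should be read accordingly.
* Calibration of $A$ compensates for the fact that sampled displacement
  magnitudes already contain memory effects; no analytic correction is
  attempted.
* 3-D migration, drift/chemotaxis, interactions, division and shape are
  out of scope.
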