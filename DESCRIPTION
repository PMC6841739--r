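Package: cellmig
Title: Stochastic and Heterogeneous Models of Two-Dimensional Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, tracking and statistical analysis of two-dimensional
    single-cell migration. Implements the persistent random walk
    (Ornstein-Uhlenbeck velocity) model and three heterogeneous extensions
    (cell-to-cell parameter variation, temporal switching of step magnitude,
    and their combination), a weighted-centroid nucleus tracker for time-lapse
    image stacks, ensemble and per-cell spatiotemporal statistics (mean-square
    displacement, self van Hove correlation functions, velocity
    autocorrelation, acceleration decomposition), parameter estimation
    (analytic PRW MSD fitting, per-cell speed and persistence, empirical
    displacement samplers, memory-parameter calibration), and quantitative
    model comparison via chi-squared p-values against simulation ensembles and
    root mean-squared logarithmic error. A synthetic-data generator produces
    cohorts of trajectories and rendered image stacks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    graphics,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
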