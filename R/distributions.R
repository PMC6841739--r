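#' Distribution specifications for population parameters
#'
#' Small declarative specs for the laws that cell-level parameters (speed,
#' persistence) are drawn from. Supported families: `"lognormal"`
#' (parameters `meanlog`/`sdlog`, or equivalently `mean`/`cv` which are
#' converted), `"gamma"` (`shape`/`rate`) and `"degenerate"` (all mass at
#' `value`). Log-normal is the package default for both speed and
#' persistence: positive support and right skew match the broad spread of
#' per-cell migration parameters seen in tracked cohorts.
#'
#' @param family one of `"lognormal"`, `"gamma"`, `"degenerate"`.
#' @param ... family parameters, see Details.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", mean = 0.125, cv = 0.45)
#' dist_spec("degenerate", value = 78)
#' @export
dist_spec <- function(family = c("lognormal", "gamma", "degenerate"), ...) {
  family <- match.arg(family)
  p <- list(...)
  spec <- switch(family,
    lognormal = {
      if (!is.null(p$mean)) {
        if (p$mean <= 0 || p$cv < 0) stop_("lognormal needs mean > 0 and cv >= 0")
        sdlog <- sqrt(log(1 + p$cv^2))
        list(meanlog = log(p$mean) - sdlog^2 / 2, sdlog = sdlog)
      } else {
        if (!is.numeric(p$meanlog) || p$sdlog < 0)
          stop_("lognormal needs meanlog and sdlog >= 0")
        list(meanlog = p$meanlog, sdlog = p$sdlog)
      }
    },
    gamma = {
      if (is.null(p$shape) || p$shape <= 0 || is.null(p$rate) || p$rate <= 0)
        stop_("gamma needs shape > 0 and rate > 0")
      list(shape = p$shape, rate = p$rate)
    },
    degenerate = {
      if (is.null(p$value) || !is.finite(p$value))
        stop_("degenerate needs a finite value")
      list(value = p$value)
    }
  )
  structure(c(list(family = family), spec), class = "dist_spec")
}

#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @rdname dist_spec
#' @export
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    lognormal  = rlnorm(n, spec$meanlog, spec$sdlog),
    gamma      = rgamma(n, shape = spec$shape, rate = spec$rate),
    degenerate = rep(spec$value, n)
  )
}

#' @rdname dist_spec
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    lognormal  = exp(spec$meanlog + spec$sdlog^2 / 2),
    gamma      = spec$shape / spec$rate,
    degenerate = spec$value
  )
}
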