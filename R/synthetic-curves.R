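#' Specification for a synthetic surface-tension concentration curve
#'
#' Emulates a tensiometer titration of a surface-active compound: surface
#' tension falls with concentration up to the critical micelle concentration
#' (CMC) and is nearly constant above it, i.e. a continuous two-segment
#' linear model with a break at `break_point`.
#'
#' @param break_point true CMC, mM; must lie strictly inside the
#'   concentration range with at least 3 points on each side.
#' @param slope_below,slope_above segment slopes (mN/m per mM in linear axis
#'   mode, per log10 mM in log mode). For a surfactant-like curve
#'   `slope_below < slope_above <= 0`.
#' @param intercept tension at zero concentration (linear mode), mN/m.
#' @param concentrations strictly increasing positive concentrations, mM.
#' @param noise_sigma Gaussian noise on tension, mN/m.
#' @param axis_mode `"linear"` (default) or `"log"`: the axis on which the
#'   two-segment model lives.
#' @param seed integer seed.
#' @return An `srf_tensiometry_spec`.
#' @export
tensiometry_spec <- function(break_point = 42,
                             slope_below = -0.5, slope_above = 0,
                             intercept = 72,
                             concentrations = seq(5, 100, length.out = 30),
                             noise_sigma = 0.3, axis_mode = "linear",
                             seed = 1L) {
  abort_if(!is_scalar_num(break_point) || break_point <= 0,
           "break_point must be a positive concentration (mM)")
  abort_if(any(concentrations <= 0), "concentrations must be positive")
  abort_if(is.unsorted(concentrations, strictly = TRUE),
           "concentrations must be strictly increasing")
  abort_if(!(axis_mode %in% c("linear", "log")),
           "axis_mode must be 'linear' or 'log'")
  abort_if(!(slope_below < slope_above && slope_above <= 0),
           "surfactant-like curve needs slope_below < slope_above <= 0")
  n_below <- sum(concentrations < break_point)
  n_above <- sum(concentrations > break_point)
  abort_if(n_below < 3 || n_above < 3,
           "need at least 3 concentrations on each side of the break")
  abort_if(!is_scalar_num(noise_sigma) || noise_sigma < 0,
           "noise_sigma must be >= 0")
  structure(list(break_point = break_point, slope_below = slope_below,
                 slope_above = slope_above, intercept = intercept,
                 concentrations = as.numeric(concentrations),
                 noise_sigma = noise_sigma, axis_mode = axis_mode,
                 seed = as.integer(seed)),
            class = "srf_tensiometry_spec")
}

#' Generate a synthetic tensiometry curve
#'
#' @param spec an [tensiometry_spec()].
#' @return list of class `srf_tensiometry_sim` with `curve` (a
#'   [tensiometry_curve()]) and `truth` (the generating parameters).
#' @export
gen_tensiometry_curve <- function(spec) {
  abort_if(!inherits(spec, "srf_tensiometry_spec"),
           "spec must come from tensiometry_spec()")
  x <- if (spec$axis_mode == "log") log10(spec$concentrations) else
    spec$concentrations
  bp <- if (spec$axis_mode == "log") log10(spec$break_point) else
    spec$break_point
  y <- spec$intercept + spec$slope_below * pmin(x, bp) +
    spec$slope_above * pmax(x - bp, 0)
  y <- withr::with_seed(spec$seed, y + rnorm(length(y), 0, spec$noise_sigma))
  structure(list(
    curve = tensiometry_curve(spec$concentrations, y,
                              axis_mode = spec$axis_mode),
    truth = list(break_point = spec$break_point,
                 slope_below = spec$slope_below,
                 slope_above = spec$slope_above,
                 intercept = spec$intercept,
                 noise_sigma = spec$noise_sigma, seed = spec$seed)
  ), class = "srf_tensiometry_sim")
}

#' Specification for a synthetic monolayer adsorption-kinetics trace
#'
#' Surface pressure of a lipid monolayer rising as ligand molecules insert
#' from the subphase, modelled as first-order adsorption
#' `pi(t) = pi0 + delta_pi_inf * (1 - exp(-rate_k * t))` plus noise.
#'
#' @param pi0 initial surface pressure, mN/m.
#' @param delta_pi_inf asymptotic pressure increase, mN/m (>= 0).
#' @param rate_k first-order rate constant, 1/min (>= 0).
#' @param duration recording length, min.
#' @param sampling sampling interval, min.
#' @param noise_sigma Gaussian noise, mN/m.
#' @param seed integer seed.
#' @return An `srf_kinetics_spec`.
#' @export
kinetics_spec <- function(pi0 = 20, delta_pi_inf = 10, rate_k = 0.1,
                          duration = 60, sampling = 0.5, noise_sigma = 0,
                          seed = 1L) {
  abort_if(!is_scalar_num(delta_pi_inf) || delta_pi_inf < 0,
           "delta_pi_inf must be >= 0")
  abort_if(!is_scalar_num(rate_k) || rate_k < 0, "rate_k must be >= 0")
  abort_if(!is_scalar_num(duration) || duration <= 0,
           "duration must be positive (min)")
  abort_if(!is_scalar_num(sampling) || sampling <= 0,
           "sampling must be positive (min)")
  abort_if(!is_scalar_num(noise_sigma) || noise_sigma < 0,
           "noise_sigma must be >= 0")
  structure(list(pi0 = pi0, delta_pi_inf = delta_pi_inf, rate_k = rate_k,
                 duration = duration, sampling = sampling,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "srf_kinetics_spec")
}

#' Generate a synthetic adsorption-kinetics trace
#'
#' @param spec a [kinetics_spec()].
#' @return list of class `srf_kinetics_sim` with `curve` (a
#'   [kinetics_curve()]) and `truth`.
#' @export
gen_kinetics_curve <- function(spec) {
  abort_if(!inherits(spec, "srf_kinetics_spec"),
           "spec must come from kinetics_spec()")
  t <- seq(0, spec$duration, by = spec$sampling)
  y <- spec$pi0 + spec$delta_pi_inf * (1 - exp(-spec$rate_k * t))
  y <- withr::with_seed(spec$seed, y + rnorm(length(y), 0, spec$noise_sigma))
  structure(list(
    curve = kinetics_curve(t, y),
    truth = list(pi0 = spec$pi0, delta_pi_inf = spec$delta_pi_inf,
                 rate_k = spec$rate_k, noise_sigma = spec$noise_sigma,
                 seed = spec$seed)
  ), class = "srf_kinetics_sim")
}
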