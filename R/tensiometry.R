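#' Surface-tension titration curve
#'
#' @param concentration strictly increasing positive concentrations, mM.
#' @param tension surface tension, mN/m.
#' @param axis_mode `"linear"` or `"log"`: whether break-point analysis runs
#'   on concentration or log10 concentration.
#' @return tibble of class `srf_tensiometry_curve` with columns
#'   `concentration_mM`, `tension_mN_per_m`.
#' @export
tensiometry_curve <- function(concentration, tension, axis_mode = "linear") {
  abort_if(length(concentration) != length(tension),
           "concentration and tension lengths differ")
  abort_if(any(concentration <= 0), "concentrations must be positive")
  abort_if(is.unsorted(concentration, strictly = TRUE),
           "concentrations must be strictly increasing")
  abort_if(!(axis_mode %in% c("linear", "log")),
           "axis_mode must be 'linear' or 'log'")
  out <- tibble::tibble(concentration_mM = as.numeric(concentration),
                        tension_mN_per_m = as.numeric(tension))
  attr(out, "axis_mode") <- axis_mode
  class(out) <- c("srf_tensiometry_curve", class(out))
  out
}

#' Read / write a tensiometry curve as CSV
#'
#' Two-column CSV with header `concentration_mM,tension_mN_per_m`.
#'
#' @param path CSV file.
#' @param axis_mode see [tensiometry_curve()].
#' @return An `srf_tensiometry_curve`.
#' @export
read_tensiometry_csv <- function(path, axis_mode = "linear") {
  df <- utils::read.csv(path)
  abort_if(!all(c("concentration_mM", "tension_mN_per_m") %in% names(df)),
           "expected columns concentration_mM, tension_mN_per_m in ", path)
  tensiometry_curve(df$concentration_mM, df$tension_mN_per_m, axis_mode)
}

#' @rdname read_tensiometry_csv
#' @param curve an `srf_tensiometry_curve`.
#' @export
write_tensiometry_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[c("concentration_mM",
                                          "tension_mN_per_m")],
                   path, row.names = FALSE)
  invisible(path)
}

# sum of squared residuals of the continuous two-segment fit with knot c
broken_stick_fit <- function(x, y, c) {
  b <- pmax(x - c, 0)
  fit <- lm(y ~ x + b)
  list(fit = fit, ssr = sum(fit$residuals^2), coef = coef(fit))
}

#' Estimate the critical micelle concentration by break-point regression
#'
#' Fits a continuous two-segment linear model to the tension-concentration
#' curve: below the break the tension falls with one slope, above it with
#' another, and the fit is forced continuous at the knot (matching the usual
#' graphical extrapolation of the concentration at the curve break). The
#' knot is located by an exhaustive sum-of-squared-residual search over the
#' midpoints between interior concentrations followed by golden-section
#' refinement within the bracketing interval; the CMC is the fitted knot
#' abscissa.
#'
#' @param curve an `srf_tensiometry_curve` with at least 3 points on each
#'   side of any candidate break.
#' @param n_boot number of case-resampling bootstrap replicates for the
#'   confidence interval (0 = none).
#' @param seed seed for the bootstrap.
#' @param degenerate_slope_tol slopes differing by less than this
#'   (mN/m per mM) flag the fit as degenerate (no detectable break).
#' @param conf bootstrap interval coverage.
#' @return list of class `srf_cmc_estimate`: `cmc` (mM), `slope_below`,
#'   `slope_above`, `intercept`, `ssr`, `degenerate`, optional `ci`
#'   (2-vector), `axis_mode`, and `fitted(concentration)` accessor.
#' @export
estimate_cmc <- function(curve, n_boot = 0, seed = NULL,
                         degenerate_slope_tol = 0.01, conf = 0.95) {
  abort_if(!inherits(curve, "srf_tensiometry_curve"),
           "curve must be an srf_tensiometry_curve")
  conc <- curve$concentration_mM
  y <- curve$tension_mN_per_m
  n <- length(conc)
  abort_if(n < 6, "need at least 6 points to place a break (got ", n, ")")
  axis_mode <- attr(curve, "axis_mode") %||% "linear"
  x <- if (axis_mode == "log") log10(conc) else conc

  est <- cmc_knot_search(x, y)
  cmc <- if (axis_mode == "log") 10^est$knot else est$knot
  slope_diff <- abs(est$coef[3])
  co <- est$coef

  ci <- NULL
  if (n_boot > 0) {
    boots <- withr::with_seed(seed %||% 1L, vapply(seq_len(n_boot), function(b) {
      idx <- sort(sample.int(n, n, replace = TRUE))
      xb <- x[idx]; yb <- y[idx]
      if (length(unique(xb)) < 6) return(NA_real_)
      kb <- tryCatch(cmc_knot_search(xb, yb)$knot, error = function(e) NA_real_)
      if (axis_mode == "log") 10^kb else kb
    }, numeric(1)))
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(list(
    cmc = unname(cmc),
    slope_below = unname(co[2]),
    slope_above = unname(co[2] + co[3]),
    intercept = unname(co[1]),
    ssr = est$ssr,
    degenerate = slope_diff < degenerate_slope_tol,
    ci = ci, n_boot = n_boot, axis_mode = axis_mode,
    fitted = local({
      knot <- est$knot; cf <- co; mode <- axis_mode
      function(concentration) {
        xx <- if (mode == "log") log10(concentration) else concentration
        unname(cf[1] + cf[2] * xx + cf[3] * pmax(xx - knot, 0))
      }
    })
  ), class = "srf_cmc_estimate")
}

# exhaustive midpoint grid + golden-section refinement for the knot
cmc_knot_search <- function(x, y) {
  n <- length(x)
  # candidate knots keep >= 3 points strictly on each side
  lo <- x[3]; hi <- x[n - 2]
  abort_if(lo >= hi, "concentration range too narrow to place a break")
  mids <- (x[-n] + x[-1]) / 2
  cand <- mids[mids > lo & mids < hi]
  cand <- c(lo + 1e-9, cand, hi - 1e-9)
  ssr <- vapply(cand, function(c) broken_stick_fit(x, y, c)$ssr, numeric(1))
  i <- which.min(ssr)
  bl <- cand[max(1, i - 1)]
  bu <- cand[min(length(cand), i + 1)]
  op <- optimize(function(c) broken_stick_fit(x, y, c)$ssr,
                 interval = c(bl, bu), tol = 1e-9)
  # optimize() can stall a hair off an interior optimum; keep the better of
  # grid and refined knots
  if (op$objective <= ssr[i]) {
    knot <- op$minimum; best <- op$objective
  } else {
    knot <- cand[i]; best <- ssr[i]
  }
  bf <- broken_stick_fit(x, y, knot)
  list(knot = knot, ssr = bf$ssr, coef = bf$coef)
}

#' @export
print.srf_cmc_estimate <- function(x, ...) {
  cat(sprintf(
    "<srf_cmc_estimate> cmc = %.3f mM (slopes %.4f / %.4f mN/m per mM%s)\n",
    x$cmc, x$slope_below, x$slope_above,
    if (x$degenerate) "; DEGENERATE: no clear break" else ""))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap CI [%.3f, %.3f] (%d replicates)\n",
                x$ci[1], x$ci[2], x$n_boot))
  }
  invisible(x)
}

#' Surface-pressure kinetics trace
#'
#' @param time non-negative, strictly increasing times, min.
#' @param pressure surface pressure, mN/m.
#' @return tibble of class `srf_kinetics_curve` with columns `time_min`,
#'   `pressure_mN_per_m`.
#' @export
kinetics_curve <- function(time, pressure) {
  abort_if(length(time) != length(pressure), "time and pressure differ")
  abort_if(any(time < 0), "times must be non-negative")
  abort_if(is.unsorted(time, strictly = TRUE),
           "times must be strictly increasing")
  out <- tibble::tibble(time_min = as.numeric(time),
                        pressure_mN_per_m = as.numeric(pressure))
  class(out) <- c("srf_kinetics_curve", class(out))
  out
}

#' Read / write a kinetics trace as CSV
#'
#' Two-column CSV with header `time_min,pressure_mN_per_m`.
#'
#' @param path CSV file.
#' @return An `srf_kinetics_curve`.
#' @export
read_kinetics_csv <- function(path) {
  df <- utils::read.csv(path)
  abort_if(!all(c("time_min", "pressure_mN_per_m") %in% names(df)),
           "expected columns time_min, pressure_mN_per_m in ", path)
  kinetics_curve(df$time_min, df$pressure_mN_per_m)
}

#' @rdname read_kinetics_csv
#' @param curve an `srf_kinetics_curve`.
#' @export
write_kinetics_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[c("time_min", "pressure_mN_per_m")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Fit first-order monolayer binding kinetics
#'
#' Nonlinear least squares for
#' `pi(t) = pi0 + delta_pi_inf * (1 - exp(-rate_k * t))` via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) with `delta_pi_inf` and
#' `rate_k` bounded below by zero. Starting values are taken from the trace
#' itself (first point, total rise, half-rise time) with a rate-constant
#' grid fallback; non-convergence raises an error carrying the attempted
#' starts rather than returning silent defaults.
#'
#' @param curve an `srf_kinetics_curve` with at least 5 points.
#' @return list of class `srf_kinetics_fit`: `pi0`, `delta_pi_inf`,
#'   `rate_k`, `rss`, and `delta_pi_at(t)` giving the fitted pressure
#'   increase over `pi0` at time `t` (e.g. `delta_pi_at(60)` for the 1 h
#'   endpoint).
#' @export
fit_binding_kinetics <- function(curve) {
  abort_if(!inherits(curve, "srf_kinetics_curve"),
           "curve must be an srf_kinetics_curve")
  t <- curve$time_min
  y <- curve$pressure_mN_per_m
  abort_if(length(t) < 5, "need at least 5 time points (got ", length(t), ")")

  if (sd(y) < 1e-12) {
    # flat trace: no adsorption signal, rate is unidentifiable by convention 0
    return(new_kinetics_fit(mean(y), 0, 0, 0))
  }
  pi0_0 <- y[1]
  dpi_0 <- max(abs(y[length(y)] - y[1]), 1e-6)
  half <- t[which.min(abs((y - pi0_0) - dpi_0 / 2))]
  k_0 <- if (half > 0) log(2) / half else 0.1
  starts <- c(k_0, 10^seq(-3, 1, by = 1))
  last_err <- NULL
  for (k_try in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ pi0 + dpi * (1 - exp(-k * t)),
        start = list(pi0 = pi0_0, dpi = dpi_0, k = k_try),
        lower = c(pi0 = -Inf, dpi = 0, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      cf <- coef(fit)
      return(new_kinetics_fit(cf[["pi0"]], cf[["dpi"]], cf[["k"]],
                              sum(residuals(fit)^2)))
    }
    last_err <- fit
  }
  stop("kinetics fit failed to converge (tried k starts ",
       paste(signif(starts, 3), collapse = ", "), "): ",
       conditionMessage(last_err), call. = FALSE)
}

new_kinetics_fit <- function(pi0, dpi, k, rss) {
  structure(list(
    pi0 = unname(pi0), delta_pi_inf = unname(dpi), rate_k = unname(k),
    rss = rss,
    delta_pi_at = local({
      dpi_ <- unname(dpi); k_ <- unname(k)
      function(t) dpi_ * (1 - exp(-k_ * t))
    })
  ), class = "srf_kinetics_fit")
}

#' @export
print.srf_kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<srf_kinetics_fit> pi0 = %.3f, delta_pi_inf = %.3f mN/m, k = %.4f /min",
    x$pi0, x$delta_pi_inf, x$rate_k),
    sprintf(" (delta_pi at 60 min: %.3f mN/m)\n", x$delta_pi_at(60)))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Compares replicate measurements across groups (e.g. the 60 min surface
#' pressure increase under different lipid monolayers) by one-way analysis
#' of variance followed by Tukey's honest significant difference on all
#' pairwise group differences, with adjusted p values from the studentized
#' range distribution. When every observation is identical the F statistic
#' is reported as 0 with p = 1 by convention.
#'
#' @param groups named list of numeric vectors (one per group, each with at
#'   least 2 replicates), or a data frame with columns `value` and `group`.
#' @return list of class `srf_group_comparison`: `f`, `p`, `df_between`,
#'   `df_within`, `ms_within`, and `tukey`, a tibble with one row per group
#'   pair (`pair`, `diff`, `q`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  if (is.data.frame(groups)) {
    abort_if(!all(c("value", "group") %in% names(groups)),
             "data frame input needs columns value and group")
    groups <- split(groups$value, groups$group)
  }
  abort_if(length(groups) < 2, "need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  sizes <- lengths(groups)
  abort_if(any(sizes < 2), "every group needs n >= 2 (",
           names(groups)[which(sizes < 2)[1]], " has ",
           min(sizes), ")")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))

  if (sd(df$value) < 1e-14) {
    k <- length(groups)
    npairs <- utils::combn(names(groups), 2)
    tk <- tibble::tibble(
      pair = apply(npairs, 2, paste, collapse = "-"),
      diff = 0, q = 0, lwr = 0, upr = 0, p_adj = 1)
    return(structure(list(f = 0, p = 1, df_between = k - 1,
                          df_within = nrow(df) - k, ms_within = 0,
                          tukey = tk),
                     class = "srf_group_comparison"))
  }

  fit <- aov(value ~ group, data = df)
  sm <- summary(fit)[[1]]
  ms_within <- sm["Residuals", "Mean Sq"]
  tk <- TukeyHSD(fit)$group
  pair <- rownames(tk)
  ab <- strsplit(pair, "-", fixed = TRUE)
  n1 <- sizes[vapply(ab, `[[`, "", 1L)]
  n2 <- sizes[vapply(ab, `[[`, "", 2L)]
  q <- abs(tk[, "diff"]) / sqrt(ms_within / 2 * (1 / n1 + 1 / n2))
  structure(list(
    f = sm["group", "F value"],
    p = sm["group", "Pr(>F)"],
    df_between = sm["group", "Df"],
    df_within = sm["Residuals", "Df"],
    ms_within = ms_within,
    tukey = tibble::tibble(pair = pair, diff = unname(tk[, "diff"]),
                           q = unname(q), lwr = unname(tk[, "lwr"]),
                           upr = unname(tk[, "upr"]),
                           p_adj = unname(tk[, "p adj"]))
  ), class = "srf_group_comparison")
}

#' @export
print.srf_group_comparison <- function(x, ...) {
  cat(sprintf("<srf_group_comparison> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p))
  print(x$tukey)
  invisible(x)
}

#' Mole ratio of two monolayer species at equal trough area
#'
#' For two lipids spread at the same surface pressure, the number of
#' molecules filling a given trough area is inversely proportional to the
#' area per molecule, so species *a* is `area_b / area_a`-fold more numerous
#' than species *b*. With ~40 A^2 for cholesterol and ~1000 A^2 for a
#' ganglioside-scale headgroup this gives the familiar 25-fold excess of
#' cholesterol.
#'
#' @param area_a,area_b molecular areas, A^2 per molecule (> 0).
#' @return the count ratio N_a / N_b.
#' @export
monolayer_mole_ratio <- function(area_a, area_b) {
  abort_if(!is_scalar_num(area_a) || area_a <= 0,
           "area_a must be positive (A^2 per molecule)")
  abort_if(!is_scalar_num(area_b) || area_b <= 0,
           "area_b must be positive (A^2 per molecule)")
  area_b / area_a
}
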