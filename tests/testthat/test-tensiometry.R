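two_segment <- function(conc, bp, s1, s2, b0 = 72) {
  b0 + s1 * pmin(conc, bp) + s2 * pmax(conc - bp, 0)
}

test_that("the break-point estimator is exact on noiseless two-segment data", {
  conc <- seq(5, 100, length.out = 30)
  curve <- tensiometry_curve(conc, two_segment(conc, 42, -0.5, 0))
  est <- estimate_cmc(curve)
  expect_equal(est$cmc, 42, tolerance = 1e-6)
  expect_equal(est$slope_below, -0.5, tolerance = 1e-6)
  expect_equal(est$slope_above, 0, tolerance = 1e-6)
  expect_false(est$degenerate)
  expect_lt(est$ssr, 1e-12)
  # break between sample points, off the midpoint grid
  curve2 <- tensiometry_curve(conc, two_segment(conc, 37.3, -0.8, -0.1))
  expect_equal(estimate_cmc(curve2)$cmc, 37.3, tolerance = 1e-6)
})

test_that("a single straight line is flagged degenerate", {
  conc <- seq(5, 100, length.out = 20)
  curve <- tensiometry_curve(conc, 72 - 0.3 * conc)
  expect_true(estimate_cmc(curve)$degenerate)
})

test_that("the CMC estimate is scale-equivariant in concentration", {
  withr::with_seed(5, {
    conc <- seq(5, 100, length.out = 30)
    y <- two_segment(conc, 42, -0.5, 0) + rnorm(30, 0, 0.3)
    for (s in c(0.1, 3)) {
      a <- estimate_cmc(tensiometry_curve(conc, y))
      b <- estimate_cmc(tensiometry_curve(conc * s, y))
      expect_equal(b$cmc, s * a$cmc, tolerance = 1e-6)
    }
  })
})

test_that("CMC error shrinks with the noise level", {
  err <- vapply(c(0, 0.1, 0.3), function(sig) {
    mean(vapply(1:40, function(seed) {
      sim <- gen_tensiometry_curve(tensiometry_spec(break_point = 42,
                                                    noise_sigma = sig,
                                                    seed = seed))
      abs(estimate_cmc(sim$curve)$cmc - 42)
    }, numeric(1)))
  }, numeric(1))
  expect_true(err[1] <= err[2])
  expect_true(err[2] <= err[3])
  expect_lt(err[1], 1e-6)
})

test_that("bootstrap confidence intervals cover the noiseless break", {
  sim <- gen_tensiometry_curve(tensiometry_spec(break_point = 42,
                                                noise_sigma = 0.3, seed = 3))
  est <- estimate_cmc(sim$curve, n_boot = 200, seed = 3)
  expect_length(est$ci, 2)
  expect_lt(est$ci[1], est$ci[2])
  expect_true(est$ci[1] < 42 && 42 < est$ci[2])
  # bootstrap is reproducible under the same seed
  est2 <- estimate_cmc(sim$curve, n_boot = 200, seed = 3)
  expect_identical(est$ci, est2$ci)
})

test_that("log-axis mode returns the CMC in concentration units", {
  conc <- exp(seq(log(5), log(100), length.out = 30))
  x <- log10(conc)
  y <- 72 - 20 * pmin(x, log10(42)) + 0 * pmax(x - log10(42), 0)
  curve <- tensiometry_curve(conc, y, axis_mode = "log")
  expect_equal(estimate_cmc(curve)$cmc, 42, tolerance = 1e-4)
})

test_that("curve validation rejects unusable inputs", {
  expect_error(tensiometry_curve(c(1, 2, 2, 3, 4, 5), 1:6), "increasing")
  expect_error(tensiometry_curve(c(-1, 2, 3, 4, 5, 6), 1:6), "positive")
  expect_error(estimate_cmc(tensiometry_curve(1:5, 5:1)), "at least 6")
})

test_that("kinetics fits are exact on noiseless model data", {
  for (par in list(c(10, 0.1), c(3, 0.02), c(25, 1.5))) {
    sim <- gen_kinetics_curve(kinetics_spec(pi0 = 20, delta_pi_inf = par[1],
                                            rate_k = par[2], noise_sigma = 0))
    fit <- fit_binding_kinetics(sim$curve)
    expect_equal(fit$delta_pi_inf, par[1], tolerance = 1e-6)
    expect_equal(fit$rate_k, par[2], tolerance = 1e-6)
    expect_equal(fit$pi0, 20, tolerance = 1e-6)
  }
})

test_that("flat kinetics traces fit to zero insertion", {
  sim <- gen_kinetics_curve(kinetics_spec(pi0 = 21, delta_pi_inf = 7,
                                          rate_k = 0, noise_sigma = 0))
  fit <- fit_binding_kinetics(sim$curve)
  expect_equal(fit$delta_pi_inf, 0, tolerance = 1e-8)
  expect_equal(fit$delta_pi_at(60), 0, tolerance = 1e-8)
  expect_equal(fit$pi0, 21, tolerance = 1e-8)
})

test_that("noisy kinetics recover the asymptote within five percent", {
  sim <- gen_kinetics_curve(kinetics_spec(pi0 = 20, delta_pi_inf = 10,
                                          rate_k = 0.1, noise_sigma = 0.2,
                                          seed = 17))
  fit <- fit_binding_kinetics(sim$curve)
  expect_lt(abs(fit$delta_pi_inf - 10) / 10, 0.05)
  expect_lt(abs(fit$rate_k - 0.1) / 0.1, 0.05)
  expect_equal(fit$delta_pi_at(60),
               fit$delta_pi_inf * (1 - exp(-fit$rate_k * 60)))
})

test_that("two-group ANOVA reduces to the squared pooled t statistic", {
  withr::with_seed(8, {
    g <- list(a = rnorm(6, 0, 1), b = rnorm(8, 0.5, 1))
    res <- anova_tukey(g)
    tt <- t.test(g$a, g$b, var.equal = TRUE)
    expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  })
})

test_that("identical observations give F = 0 and p = 1 by convention", {
  res <- anova_tukey(list(a = c(2, 2, 2), b = c(2, 2), c = c(2, 2, 2)))
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$tukey$p_adj == 1))
})

test_that("ANOVA and Tukey HSD match the textbook formulas", {
  withr::with_seed(12, {
    k <- 5; n <- 3
    g <- lapply(setNames(seq_len(k), paste0("g", seq_len(k))),
                function(i) rnorm(n, mean = i * 0.3))
    res <- anova_tukey(g)
    # formula oracle: between/within sums of squares
    all_v <- unlist(g)
    grand <- mean(all_v)
    means <- vapply(g, mean, numeric(1))
    ssb <- n * sum((means - grand)^2)
    ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
    dfb <- k - 1; dfw <- k * n - k
    f_oracle <- (ssb / dfb) / (ssw / dfw)
    p_oracle <- pf(f_oracle, dfb, dfw, lower.tail = FALSE)
    expect_equal(res$f, f_oracle, tolerance = 1e-10)
    expect_equal(res$p, p_oracle, tolerance = 1e-10)
    msw <- ssw / dfw
    for (i in seq_len(nrow(res$tukey))) {
      ab <- strsplit(res$tukey$pair[i], "-")[[1]]
      diff <- means[ab[1]] - means[ab[2]]
      q <- abs(diff) / sqrt(msw / n)
      p_adj <- ptukey(q, k, dfw, lower.tail = FALSE)
      expect_equal(res$tukey$diff[i], unname(diff), tolerance = 1e-10)
      expect_equal(res$tukey$q[i], unname(q), tolerance = 1e-10)
      expect_equal(res$tukey$p_adj[i], unname(p_adj), tolerance = 1e-3)
    }
  })
})

test_that("group validation requires replicates", {
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(anova_tukey(list(a = c(1, 2))), "2 groups")
})

test_that("monolayer mole ratios follow the area arithmetic", {
  expect_equal(monolayer_mole_ratio(40, 1000), 25)
  expect_equal(monolayer_mole_ratio(120, 120), 1)
  # count-then-divide oracle at an arbitrary trough area
  a_total <- 5e5
  expect_equal(monolayer_mole_ratio(50, 200), (a_total / 50) / (a_total / 200))
  expect_error(monolayer_mole_ratio(-1, 10), "positive")
})

test_that("curve CSV round trips preserve the data", {
  sim <- gen_tensiometry_curve(tensiometry_spec(noise_sigma = 0.3, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tensiometry_csv(sim$curve, path)
  expect_identical(readLines(path)[1],
                   "\"concentration_mM\",\"tension_mN_per_m\"")
  back <- read_tensiometry_csv(path)
  expect_equal(back$tension_mN_per_m, sim$curve$tension_mN_per_m)

  ksim <- gen_kinetics_curve(kinetics_spec(noise_sigma = 0.1, seed = 2))
  kpath <- withr::local_tempfile(fileext = ".csv")
  write_kinetics_csv(ksim$curve, kpath)
  kback <- read_kinetics_csv(kpath)
  expect_equal(kback$pressure_mN_per_m, ksim$curve$pressure_mN_per_m)
})
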