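test_that("sigmoid curve fitting is exact on clean data and the smoother
          agrees", {
  psi <- seq(-6, -0.5, by = 0.1)
  frac <- 1 / (1 + exp((psi + 4.07) / 0.202))
  fit <- fit_cavitation_curve(psi = psi, frac = frac)
  expect_equal(fit$p50, -4.07, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.202, tolerance = 1e-6)
  sm <- fit_cavitation_curve(psi = psi, frac = frac, method = "smoother")
  expect_equal(sm$p50, fit$p50, tolerance = 0.05)
  expect_error(fit_cavitation_curve(psi = psi[1:4], frac = frac[1:4]),
               "6 distinct")
  expect_error(fit_cavitation_curve(psi = psi, frac = rev(frac)),
               "monotone")
})

test_that("P-level extraction inverts the fitted sigmoid", {
  par <- list(p50 = -4.07, alpha = 0.202)
  expect_equal(round(extract_px(par, 20), 2), -3.79)
  expect_equal(extract_px(par, 50), -4.07)
  expect_equal(round(extract_px(par, 88), 2), -4.47)
  expect_error(extract_px(par, 0), "p")
  # smoother refuses to extrapolate beyond its data range
  psi <- seq(-4.3, -3.8, by = 0.05)
  frac <- 1 / (1 + exp((psi + 4.07) / 0.202))
  sm <- fit_cavitation_curve(psi = psi, frac = frac, method = "smoother")
  expect_error(extract_px(sm, 99), "range")
})

test_that("breakpoint regression is exact on noiseless two-segment data
          and declines a single line", {
  x <- seq(-6, -0.5, by = 0.05)
  y <- ifelse(x > -3.62, 6.1963 * x + 106.22,
              6.1963 * -3.62 + 106.22 + 3 * 6.1963 * (x + 3.62))
  fit <- fit_breakpoint(x, y)
  expect_equal(fit$breakpoint, -3.62, tolerance = 1e-6)
  expect_equal(fit$slope_after, 6.1963, tolerance = 1e-6)
  expect_equal(fit$slope_before, 3 * 6.1963, tolerance = 1e-6)
  expect_false(fit$no_breakpoint)
  expect_equal(unname(coef(fit)["breakpoint"]), fit$breakpoint)
  expect_equal(predict(fit, newdata = x), y, tolerance = 1e-8)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
  line <- fit_breakpoint(x, 2 + 0.5 * x)
  expect_true(line$no_breakpoint)
  expect_true(is.na(line$breakpoint))
})

test_that("breakpoint estimates are robust to the starting value", {
  x <- seq(-6, -0.5, by = 0.05)
  set.seed(7)
  y <- generate_fvfm_series(x, seed = 77)
  fits <- lapply(c(-5, -3, -1.2), function(ini)
    fit_breakpoint(x, y, init = ini))
  bps <- vapply(fits, `[[`, 0, "breakpoint")
  expect_lt(max(bps) - min(bps), 0.051)   # within one x-grid step
})

test_that("noisy fluorescence bundles recover their breakpoint within
          the observed spread", {
  x <- seq(-0.5, -6, by = -0.05)
  bps <- vapply(1:6, function(i) {
    y <- generate_fvfm_series(x, breakpoint = -3.53, noise_sd = 0.02,
                              seed = 300 + i)
    fit_breakpoint(x, y)$breakpoint
  }, 0)
  expect_equal(mean(bps), -3.53, tolerance = 0.07)
})

test_that("bootstrap breakpoint standard errors shrink with sample
          size", {
  mk <- function(n, seed) {
    set.seed(seed)
    x <- seq(-6, -0.5, length.out = n)
    y <- ifelse(x > -3.6, 0.8, 0.8 + 0.3 * (x + 3.6)) + rnorm(n, 0, 0.02)
    fit_breakpoint(x, y, n_boot = 40, seed = seed)
  }
  se_small <- mk(60, 11)$se
  se_large <- mk(240, 12)$se
  expect_lt(se_large, se_small)
})

test_that("ordinary least squares recovers the printed width calibration
          exactly", {
  x <- seq(-4.4, -0.5, length.out = 40)
  fl <- fit_linear(x, 6.1963 * x + 106.22)
  expect_equal(fl$slope, 6.1963)
  expect_equal(fl$intercept, 106.22)
  expect_equal(fl$r2, 1)
  expect_equal(fit_linear(x, rep(3, 40))$slope, 0)
  noisy <- fit_linear(x, 6.1963 * x + 106.22 + rnorm(40, 0, 1))
  expect_lt(noisy$r2, 1)
})

test_that("rehydration conductance instances are standardised and
          flagged when inconsistent", {
  # Fmax/area = 10 mmol m-2 s-1 at psi_init = -2 gives K = 5
  k <- kleaf_instance(fmax = 10 * 1e-3, f2 = 5 * 1e-3,
                      psi_init = -2, psi_fin = -1, area_m2 = 1e-3)
  expect_equal(k$k, 5)
  expect_false(k$flagged)
  expect_equal(k$k1, k$k2)
  expect_equal(water_viscosity_ratio(20), 1)
  expect_lt(water_viscosity_ratio(23), 1)      # warmer water flows easier
  k23 <- kleaf_instance(10e-3, 5e-3, -2, -1, 1e-3, temp_c = 23)
  expect_equal(k23$k, k$k * water_viscosity_ratio(23))
  bad <- kleaf_instance(20e-3, 12e-3, -2, -1, 1e-3)
  expect_true(bad$flagged)
  expect_error(kleaf_instance(1, 1, 0, -1, 1), "negative")
})

test_that("the 4-parameter K_leaf sigmoid and its 3-parameter reduction
          recover generating values", {
  r0 <- generate_rehydration_samples(y0 = 0, seed = 41)
  f0 <- fit_kleaf_curve(r0)
  expect_equal(f0$kmax, 5.77, tolerance = 1e-4 * 5.77)
  expect_equal(f0$y0, 0, tolerance = 1e-4)
  expect_equal(f0$p50, f0$x0, tolerance = 1e-4)  # y0 = 0: P50 is x0
  ry <- generate_rehydration_samples(y0 = 0.4, seed = 42)
  fy <- fit_kleaf_curve(ry)
  expect_equal(fy$kmax, 5.77, tolerance = 1e-3)
  # reduction consistency: predicted K at the reduced P50 is kmax/2
  expect_equal(predict(fy, fy$p50), fy$kmax / 2, tolerance = 1e-6)
  rn <- generate_rehydration_samples(noise_sd = 0.05, n = 40, seed = 43)
  fn <- fit_kleaf_curve(rn)
  expect_equal(fn$p50, -3.73, tolerance = 0.1)
  expect_error(fit_kleaf_curve(psi = c(-1, -2, -3), k = c(5, 4, 3)),
               "6 records")
})

test_that("gmin estimation finds the terminal linear phase", {
  tr <- generate_gmin_trace(gmin = 10.02, seed = 51)
  gf <- gmin_from_trace(tr, 1e-3, vpd_kpa = leaf_environment()$vpd_kpa)
  expect_equal(gf$gmin, 10.02, tolerance = 0.02 * 10.02)
  # hand-computable case: slope 1e-6 g/s over 1e-3 m2 at VPD 1.94 kPa
  trh <- data.frame(time_min = 0:120, mass_g = 1 - 1e-6 * 60 * (0:120))
  gh <- gmin_from_trace(trh, 1e-3, vpd_kpa = 1.94)
  expect_equal(gh$wl, 0.0555, tolerance = 1e-3)
  expect_equal(gh$gmin, 2.90, tolerance = 0.01)
  flat <- data.frame(time_min = 0:60, mass_g = rep(1, 61))
  expect_equal(gmin_from_trace(flat, 1e-3)$gmin, 0)
  expect_error(gmin_from_trace(trh[1:10, ], 1e-3), "30 min")
})

test_that("PV analysis recovers the turgor loss point, survives unit
          changes and flags all-linear input", {
  pv <- generate_pv_series(tlp = -2.01, seed = 61)
  f1 <- tlp_from_pv(pv$psi, pv$mass_g, mass_sat = 1, mass_dry = 0.2)
  expect_equal(f1$tlp, -2.01, tolerance = 0.05)
  f2 <- tlp_from_pv(pv$psi, 2 * pv$mass_g, mass_sat = 2, mass_dry = 0.4)
  expect_equal(f2$tlp, f1$tlp)
  # purely post-turgor data: warn and return the wettest point
  d <- seq(0.01, 0.4, length.out = 15)
  psi <- -1.7 * 0.8 / (0.8 - d)
  mass <- 0.2 + 0.8 * (1 - d)
  expect_warning(f3 <- tlp_from_pv(psi, mass, 1, 0.2), "linear")
  expect_equal(f3$tlp, psi[1])
  expect_true(f3$all_linear)
})
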