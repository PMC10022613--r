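test_that("leaf geometry is deterministic, tiles the lamina and orders
          pixel counts by vein rank", {
  g1 <- small_geom(seed = 3)
  g2 <- small_geom(seed = 3)
  expect_identical(g1$order_mask, g2$order_mask)
  expect_identical(g1$segments$id, g2$segments$id)
  # served-area tiling covers the lamina
  expect_gt(sum(g1$served_px) / g1$lamina$n_px, 0.99)
  expect_lte(sum(g1$served_px), g1$lamina$n_px)
  # pixel counts: hov > major > midrib; enough HOV segments
  cnt <- table(factor(g1$order_mask, levels = 1:3,
                      labels = c("midrib", "major", "hov")))
  expect_gt(cnt[["hov"]], cnt[["major"]])
  expect_gt(cnt[["major"]], cnt[["midrib"]])
  expect_gte(sum(g1$segments$order == "hov"), 50)
  expect_gte(sum(g1$segments$order == "major"), 6)
  # every vein pixel has exactly one segment id
  expect_true(all(g1$segment_map[g1$order_mask %in% 1:3] > 0))
  expect_error(build_leaf_geometry(width_px = 128), "256")
  expect_error(build_leaf_geometry(hov_spacing_px = 4), "denser")
  expect_error(build_leaf_geometry(scale_um = 60), "50 um")
})

test_that("psychrometer series is a seeded linear ramp", {
  s0 <- generate_psychrometer_series(noise_sd = 0)
  expect_equal(s0$psi_stem[1], -0.5)
  expect_equal(s0$psi_stem[nrow(s0)], -6)
  slope <- diff(s0$psi_stem[1:2]) / diff(s0$time_min[1:2])
  expect_equal(slope, (-6 + 0.5) / (5 * 1440))
  expect_identical(generate_psychrometer_series(seed = 9),
                   generate_psychrometer_series(seed = 9))
  # replicate mean at mid-course concentrates on the ramp midpoint
  mid <- vapply(1:40, function(i) {
    s <- generate_psychrometer_series(dt_min = 720, noise_sd = 0.1,
                                      seed = 100 + i)
    s$psi_stem[s$time_min == 3600]
  }, 0)
  expect_equal(mean(mid), -3.25, tolerance = 4 * 0.1 / sqrt(40))
  expect_error(generate_psychrometer_series(psi0 = -6, psi_end = -1),
               "wetter")
})

test_that("cavitation schedules respect per-order counts and the
          single-event HOV rule", {
  g <- small_geom(seed = 5)
  ps <- short_psi(noise_sd = 0.02, seed = 6)
  s1 <- schedule_cavitation_events(g, ps, seed = 7)
  s2 <- schedule_cavitation_events(g, ps, seed = 7)
  expect_identical(s1$psi_trigger, s2$psi_trigger)
  hov <- s1[s1$order == "hov", ]
  expect_equal(nrow(hov), sum(g$segments$order == "hov"))
  expect_false(any(duplicated(hov$segment_id)))
  # pooled trigger medians over several leaves recover the order P50s
  trig <- lapply(1:6, function(k)     # rare tail triggers may be truncated
    suppressWarnings(schedule_cavitation_events(g, ps, seed = 20 + k)))
  pool <- do.call(rbind, trig)
  med <- tapply(pool$psi_trigger, pool$order, median)
  expect_equal(unname(med[["hov"]]), -4.07, tolerance = 0.1)
  expect_equal(unname(med[["midrib"]]), -3.35, tolerance = 0.15)
  cnt <- events_per_segment(pool, g)   # six leaves pooled on one geometry
  expect_equal(cnt$mean_events[cnt$order == "midrib"] / 6, 9.4,
               tolerance = 0.15 * 9.4)
  expect_equal(cnt$mean_events[cnt$order == "major"] / 6, 4.53,
               tolerance = 0.15 * 4.53)
})

test_that("a psi series that never reaches the sigmoid tail truncates
          the schedule with a warning", {
  g <- small_geom(seed = 5)
  ps <- generate_psychrometer_series(psi_end = -3.3, noise_sd = 0, seed = 1)
  expect_warning(schedule_cavitation_events(g, ps, seed = 2), "dropped")
})

test_that("width series inverts the printed calibration", {
  expect_equal(generate_width_series(-1.0038), 100, tolerance = 1e-3)
  expect_equal(generate_width_series(0), 106.22)
  psi <- seq(-4.4, -0.5, length.out = 30)
  fl <- fit_linear(psi, generate_width_series(psi))
  expect_equal(fl$slope, 6.1963)
  expect_equal(fl$intercept, 106.22)
  expect_error(generate_width_series(-1, slope = -2), "slope")
})

test_that("Fv/Fm series holds its plateau, collapses past the breakpoint
          and stays flat for controls", {
  psi <- seq(-0.5, -6, by = -0.05)
  y <- generate_fvfm_series(psi, noise_sd = 0)
  expect_equal(generate_fvfm_series(-3.53, noise_sd = 0), 0.80)
  expect_true(all(y[psi > -3.53] == 0.80))
  expect_lt(y[length(y)], 0.2)
  ctl <- generate_fvfm_series(psi, breakpoint = -10, noise_sd = 0)
  expect_true(all(ctl == 0.80))
  expect_equal(fit_linear(psi, ctl)$slope, 0)
})

test_that("gmin traces are invertible and flat without demand", {
  tr <- generate_gmin_trace(gmin = 10.02, seed = 8)
  gf <- gmin_from_trace(tr, 1e-3, vpd_kpa = leaf_environment()$vpd_kpa)
  expect_equal(gf$gmin, 10.02, tolerance = 0.02 * 10.02)
  expect_gt(gf$phase_start_min, 30)
  flat <- generate_gmin_trace(env = leaf_environment(vpd_kpa = 0))
  expect_equal(diff(range(flat$mass_g)), 0)
})

test_that("PV curves recover their turgor loss point and osmotic slope", {
  pv <- generate_pv_series(seed = 9)
  expect_true(all(diff(pv$mass_g) < 0))
  fit <- tlp_from_pv(pv$psi, pv$mass_g, mass_sat = 1, mass_dry = 0.2)
  expect_equal(fit$tlp, -2.01, tolerance = 0.05)
  # terminal slope of -1/psi vs deficit equals 1 / (pi0 * symplastic)
  expect_equal(fit$slope, 1 / (attr(pv, "pi0") * 0.8), tolerance = 1e-3)
  expect_equal(fit$po, attr(pv, "pi0"), tolerance = 0.02)
})

test_that("rehydration records round-trip the K_leaf plateau and flag
          inconsistent pairs", {
  r <- generate_rehydration_samples(seed = 10)
  expect_true(all(r$psi_init < 0))
  kf <- fit_kleaf_curve(r)
  expect_equal(kf$kmax, 5.77, tolerance = 1e-3)
  expect_equal(kf$p50, -3.73, tolerance = 1e-3)
  bad <- kleaf_instance(r$fmax[5], r$f2[5] * 1.25, r$psi_init[5],
                        r$psi_fin[5], r$area_m2[5], r$temp_c[5])
  expect_true(bad$flagged)
})

test_that("rendering turns scheduled events into difference episodes at
          the configured SNR", {
  g <- small_geom(seed = 1)
  ps <- short_psi(dt_min = 360)            # 21 frames
  ords <- order_defaults()
  sch <- schedule_cavitation_events(g, ps, ords, seed = 2)
  keep <- c(which(sch$order == "hov")[1:2], which(sch$order == "midrib")[1])
  sch3 <- sch[keep, ]
  attr(sch3, "footprints") <- attr(sch, "footprints")[keep]
  class(sch3) <- class(sch)
  sch3$frame <- c(5L, 10L, 15L)
  st <- render_stack(g, sch3, ps, noise_sd = 0, seed = 3)
  d <- difference_stack(st)
  active <- which(apply(d, 3, max) > 0)
  # 3 events x (onset + offset) episodes, flash length 2 frames
  expect_equal(active, c(4, 6, 9, 11, 14, 16))
  expect_equal(max(d), 0.10)
  # flash SNR at defaults
  expect_equal(0.10 / 0.02, 5)
  # shrink disabled: constant margin
  mw <- measure_leaf_width(st, g)
  expect_equal(diff(range(mw$width_px)), 0)
  expect_error(render_stack(g, sch3, ps[1:10, ], seed = 1), "beyond")
})
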