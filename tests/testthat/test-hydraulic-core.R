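test_that("conductance follows the sigmoid with half-max at P50", {
  vc <- study_curve()
  expect_equal(conductance(vc, -3.73), 5.77 / 2)
  expect_equal(conductance(vc, 0), 5.77, tolerance = 1e-10)
  expect_equal(conductance(vc, -3.8205), 1.5457, tolerance = 1e-3)
  psi <- seq(-6, -2, by = 0.05)       # away from double-precision plateaus
  expect_true(all(diff(conductance(vc, psi)) > 0))
  psi_all <- seq(-10, 0, by = 0.05)
  expect_true(all(diff(conductance(vc, psi_all)) >= 0))
  expect_error(conductance(vc, NA), "finite")
  expect_error(vuln_curve(5.77, -3.73, -0.1), "alpha")
  expect_error(vuln_curve(5.77, 3.73, 0.09), "p50")
})

test_that("percent loss of conductance is 50 at P50 and monotone", {
  vc <- study_curve()
  expect_equal(plc_at_psi(vc, -3.73), 50)
  expect_equal(plc_at_psi(vc, -3.8205), 73.2, tolerance = 1e-3)
  expect_lt(plc_at_psi(vc, 50 * .Machine$double.eps), 1e-6)
  psi <- seq(-6, -2, by = 0.05)
  expect_true(all(diff(plc_at_psi(vc, psi)) < 0))
})

test_that("Arden-Buck VPD matches direct evaluation and guards RH", {
  expect_equal(vpd_arden_buck(24.31, 35.86), 1.949, tolerance = 1e-3)
  expect_equal(vpd_arden_buck(21, 100), 0)
  expect_equal(vpd_arden_buck(0, 0), 0.61121)
  expect_error(vpd_arden_buck(20, 120), "rh_pct")
})

test_that("cuticular transpiration reproduces the trait-table value", {
  expect_equal(cuticular_transpiration(10.02, 1.94, 101.3), 0.19,
               tolerance = 0.01)
  expect_equal(cuticular_transpiration(0, 1.94, 101.3), 0)
  expect_equal(cuticular_transpiration(100, 1.013, 101.3), 1)
  expect_error(cuticular_transpiration(10, 1.9, 0), "patm")
})

test_that("supply rate vanishes at equilibrium and peaks at the balance
          point", {
  vc <- study_curve()
  expect_equal(supply_rate(vc, -2, -2), 0)
  expect_equal(supply_rate(vc, -3.8205, -3.6975), 0.1902, tolerance = 1e-3)
  expect_error(supply_rate(vc, -1, -2), "psi_leaf")
  # brute-force argmax equals the root of K'(psi)(psi_s - psi) = K(psi)
  ps <- -3.6975
  grid <- seq(-6, ps, by = 1e-4)
  s <- supply_rate(vc, grid, ps)
  num <- grid[which.max(s)]
  h <- 1e-6
  kp <- function(p) (conductance(vc, p + h) - conductance(vc, p - h)) / (2 * h)
  bal <- uniroot(function(p) kp(p) * (ps - p) - conductance(vc, p),
                 c(-5, ps - 1e-3))$root
  expect_equal(num, bal, tolerance = 1e-3)
})

test_that("closed-form runaway point matches the study mean and is
          self-consistent", {
  vc <- study_curve()
  rw <- runaway_point(vc, 0.19)
  expect_equal(rw$psi_runaway, -3.8205, tolerance = 1e-4)
  expect_equal(rw$plc_runaway, 73.2, tolerance = 1e-3)
  expect_equal(rw$k_at_runaway, 5.77 * (1 - rw$plc_runaway / 100))
  expect_equal(plc_at_psi(vc, rw$psi_runaway), rw$plc_runaway,
               tolerance = 1e-9)
  # vanishing demand: no runaway, PLC -> 100
  rw0 <- runaway_point(vc, 1e-10)
  expect_lt(rw0$psi_runaway, -5)
  expect_gt(rw0$plc_runaway, 99.99)
  expect_error(runaway_point(vc, 0), "ec")
})

test_that("numeric supply-demand oracle agrees with the closed form", {
  vc <- study_curve()
  rn <- runaway_point_numeric(vc, 0.19)
  rw <- runaway_point(vc, 0.19)
  expect_equal(rn$psi_runaway, rw$psi_runaway, tolerance = 1e-6)
  expect_equal(rn$plc_runaway, rw$plc_runaway, tolerance = 1e-4)
  # independent of the starting source potential
  rn2 <- runaway_point_numeric(vc, 0.19, psi_source_start = -1.5)
  expect_equal(rn2$psi_runaway, rn$psi_runaway, tolerance = 1e-8)
  expect_equal(rn$psi_source_critical, -3.6976, tolerance = 1e-3)
  # demand already above peak supply at the start
  expect_error(runaway_point_numeric(vc, 0.19, psi_source_start = -5),
               "already passed")
})

test_that("closed form and oracle agree over a random parameter sweep", {
  set.seed(421)
  n_ok <- 0
  while (n_ok < 100) {
    kmax <- runif(1, 1, 20); p50 <- runif(1, -8, -1)
    alpha <- runif(1, 0.02, 1); ec <- runif(1, 0.01, 1)
    vc <- vuln_curve(kmax, p50, alpha)
    rw <- runaway_point(vc, ec)
    if (rw$psi_runaway > -0.2) next    # outside the physical search window
    rn <- runaway_point_numeric(vc, ec)
    expect_equal(rn$psi_runaway, rw$psi_runaway, tolerance = 1e-6)
    expect_equal(rn$plc_runaway, rw$plc_runaway, tolerance = 1e-4)
    n_ok <- n_ok + 1
  }
})

test_that("drydown simulation tracks the source without demand", {
  vc <- study_curve()
  sim <- simulate_drydown_ode(vc, ec = 0, t_end = 3000)
  expect_true(is.na(sim$onset_time))
  off <- with(sim$series, psi_source - psi_leaf)
  expect_lt(max(abs(off[sim$series$time_min > 100])), 0.005)
})

test_that("drydown simulation flags runaway onset at the closed-form
          point and then accelerates", {
  vc <- study_curve()
  sim <- simulate_drydown_ode(vc, ec = 0.19)
  rw <- runaway_point(vc, 0.19)
  expect_equal(sim$psi_leaf_onset, rw$psi_runaway, tolerance = 0.02)
  # acceleration signature after onset
  s <- sim$series
  post <- which(s$time_min > sim$onset_time)[1:40]
  rate <- abs(diff(s$psi_leaf[post]))
  expect_true(all(diff(rate[1:11]) > 0))
  # before onset the leaf-source offset stays bounded
  pre <- s$time_min < sim$onset_time - 60
  expect_lt(max(abs(s$psi_source[pre] - s$psi_leaf[pre])), 0.2)
})

test_that("a vanishing slope parameter collapses the runaway point to
          P50", {
  vc <- vuln_curve(5.77, -3.73, 1e-4)
  rw <- runaway_point(vc, 0.19)
  expect_equal(rw$psi_runaway, -3.73, tolerance = 0.01)
})
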