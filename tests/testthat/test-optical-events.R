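test_that("difference stack is |I_t+1 - I_t| with preserved geometry", {
  const <- array(0.4, c(8, 8, 5))
  expect_true(all(difference_stack(const) == 0))
  # one-frame flash of amplitude A: equal onset and offset episodes
  st <- array(0.4, c(8, 8, 5))
  st[3:4, 3:4, 3] <- 0.4 + 0.07
  d <- difference_stack(st)
  expect_equal(max(d[, , 2]), 0.07)
  expect_equal(max(d[, , 3]), 0.07)
  expect_equal(max(d[, , c(1, 4)]), 0)
  # difference of a linear ramp is constant
  ramp <- array(rep(0.01 * (1:6), each = 16), c(4, 4, 6))
  expect_true(all(abs(difference_stack(ramp) - 0.01) < 1e-12))
  expect_error(difference_stack(array(0, c(4, 4, 1))), "2 frames")
})

test_that("planted flashes are recovered with full recall and precision
          and a noise-only stack yields nothing", {
  pf <- plant_flashes(n = 25, seed = 31)
  ev <- detect_events(difference_stack(pf$stack))
  m <- match_events(ev, pf$footprints, pf$frames)
  expect_gte(m$recall, 0.98)
  expect_gte(m$precision, 0.98)
  # detection is deterministic
  ev2 <- detect_events(difference_stack(pf$stack))
  expect_identical(ev$start_frame, ev2$start_frame)
  expect_identical(attr(ev, "footprints"), attr(ev2, "footprints"))
  # noise only
  set.seed(32)
  noise <- array(stats::rnorm(128 * 128 * 30, 0.5, 0.02), c(128, 128, 30))
  expect_equal(nrow(detect_events(difference_stack(noise))), 0)
  # appending an all-zero difference frame changes nothing (fixed
  # threshold: the data-driven rules see a different pooled histogram)
  d <- difference_stack(pf$stack)
  d2 <- array(0, dim(d) + c(0, 0, 1)); d2[, , seq_len(dim(d)[3])] <- d
  evf <- detect_events(d, threshold = "fixed", threshold_value = 0.06)
  evf2 <- detect_events(d2, threshold = "fixed", threshold_value = 0.06)
  expect_equal(nrow(evf2), nrow(evf))
  expect_equal(evf2$area_px, evf$area_px)
  expect_identical(attr(evf2, "footprints"), attr(evf, "footprints"))
})

test_that("overlapping flashes within the merge window collapse into one
          event", {
  st <- array(0.5, c(32, 32, 10))
  px <- function(rows, cols) { m <- st[, , 1] * 0; m[rows, cols] <- 1; m }
  st[10:12, 10:12, 4] <- 0.62
  st[11:13, 10:12, 6] <- 0.62     # overlaps, 2 difference-frames apart
  ev1 <- detect_events(difference_stack(st), threshold = "fixed",
                       threshold_value = 0.05, merge_window = 2)
  expect_equal(nrow(ev1), 1)
  # without any merge window even a single flash splits into its onset
  # and offset difference episodes
  ev0 <- detect_events(difference_stack(st), threshold = "fixed",
                       threshold_value = 0.05, merge_window = 0)
  expect_equal(nrow(ev0), 4)
})

test_that("vein order is assigned by majority overlap with ties toward
          the lower order", {
  g <- small_geom(seed = 2)
  segs <- g$segments
  mid_px <- segs$px[[which(segs$order == "midrib")[1]]]
  maj_px <- segs$px[[which(segs$order == "major")[1]]]
  hov_px <- segs$px[[which(segs$order == "hov")[1]]]
  ev <- fake_events(list(hov_px,
                         c(mid_px[1:6], maj_px[1:4]),   # 60/40 majority
                         c(mid_px[1:5], maj_px[1:5]),   # tie
                         c(0L) + which(g$order_mask == 0L)[1:5]))
  expect_warning(out <- assign_vein_order(ev, g), "no vein overlap")
  expect_equal(out$order, c("hov", "midrib", "midrib"))
  expect_equal(out$segment_id[1], segs$id[segs$order == "hov"][1])
  expect_equal(nrow(out), 3)
})

test_that("rendered leaves round-trip through detection with correct
          orders and per-segment counts", {
  leaf <- rendered_leaf()
  sched <- leaf$sched
  ev <- leaf$events
  m <- match_events(ev, attr(sched, "footprints"), sched$frame)
  expect_gte(m$recall, 0.98)
  expect_gte(m$precision, 0.98)
  # order accuracy on matched events
  ok <- !is.na(m$hit)
  expect_equal(mean(ev$order[ok] == sched$order[m$hit[ok]]), 1.0)
  # per-segment counts close to the scheduled truth
  truth <- events_per_segment(sched, leaf$geom)
  det <- events_per_segment(ev, leaf$geom)
  for (ord in c("midrib", "major", "hov"))
    expect_equal(det$mean_events[det$order == ord],
                 truth$mean_events[truth$order == ord],
                 tolerance = 0.06 * truth$mean_events[truth$order == ord])
})

test_that("cumulative curves behave like CDFs and recover their
          generating sigmoid", {
  one <- data.frame(event_id = 1, segment_id = 1, order = "hov",
                    psi_trigger = -3.1, frame = 4, area_px = 10)
  cv <- cumulative_cavitation(one)
  expect_equal(cv$hov$cum_frac, 1)
  expect_equal(psi_at_fraction(cv$hov, 1), -3.1)
  set.seed(44)
  trig <- stats::rlogis(400, -3.73, 0.25)
  ev <- data.frame(event_id = seq_along(trig), segment_id = 1,
                   order = "leaf", psi_trigger = trig, frame = 1,
                   area_px = 5)
  cv <- cumulative_cavitation(ev)$leaf
  expect_true(all(diff(cv$cum_frac) >= 0))
  expect_equal(cv$cum_frac[nrow(cv)], 1)
  expect_equal(psi_at_fraction(cv, 0.5), -3.73, tolerance = 0.1)
  # permuting rows leaves the curve unchanged
  ev2 <- ev[sample(nrow(ev)), ]
  expect_equal(cumulative_cavitation(ev2)$leaf, cv)
})

test_that("events beyond the psi series raise a join error and empty
          tables give zero counts", {
  g <- small_geom(seed = 2)
  ev <- fake_events(list(g$segments$px[[1]]), start_frame = 5L)
  ev$time_min <- 1e6
  ev$order <- "midrib"; ev$segment_id <- 1L
  expect_error(cumulative_cavitation(ev, short_psi()), "beyond")
  cnt <- events_per_segment(ev[0, ], g)
  expect_true(all(cnt$mean_events == 0))
})

test_that("leaf width tracks the rendered shrink within a pixel", {
  g <- small_geom(seed = 21)
  ps <- short_psi(dt_min = 120, seed = 22)   # 61 frames
  pl <- generate_psi_leaf(ps$psi_stem, -3.82, 3)
  ps$width_pct <- generate_width_series(pl)
  sch <- schedule_cavitation_events(g, ps, seed = 23)
  st <- render_stack(g, sch, ps, shrink = TRUE, seed = 24)
  mw <- measure_leaf_width(st, g)
  hw0 <- g$mid_col - g$lamina$cols[1]
  expected <- round(hw0 * pmin(ps$width_pct, 100) / 100) -
    g$midrib_halfwidth
  expect_false(any(mw$missing))
  expect_lte(max(abs(mw$width_px - expected)), 1)
  expect_equal(mw$width_pct[1], 100)
  # sub-pixel noise: recovered width varies well below half a percent
  flat <- ps; flat$width_pct <- rep(100, nrow(ps))
  st2 <- render_stack(g, sch, flat, shrink = TRUE, seed = 25)
  mw2 <- measure_leaf_width(st2, g)
  expect_lt(stats::sd(mw2$width_pct), 0.5)
})

test_that("functional HOV area declines monotonically from 100% to near
          zero as segments cavitate", {
  g <- small_geom(seed = 26)
  ps <- short_psi(seed = 27)
  sch <- schedule_cavitation_events(g, ps, seed = 28)
  none <- functional_area_remaining(sch[0, ], g)
  expect_equal(none$final_remaining_pct, 100)
  fa <- functional_area_remaining(sch, g)
  expect_lte(fa$final_remaining_pct, 5)
  expect_true(all(diff(fa$curve$remaining_pct) <= 1e-12))
  # a single event removes exactly its served share
  hov1 <- sch[sch$order == "hov", ][1, ]
  one <- functional_area_remaining(hov1, g)
  expect_equal(one$final_remaining_pct,
               100 * (1 - g$served_px[hov1$segment_id] / g$lamina$n_px))
  # brush mode also severs (nearly) everything when all HOV cavitate
  fb <- functional_area_remaining(sch, g, mode = "brush")
  expect_lte(fb$final_remaining_pct, 5)
  # unknown segment ids are skipped with a warning
  bad <- hov1; bad$segment_id <- 99999L
  expect_warning(functional_area_remaining(bad, g), "unknown")
})
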