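# Shared fixtures, all generated in code.

study_curve <- function() vuln_curve(kmax = 5.77, p50 = -3.73, alpha = 0.09)

small_geom <- function(seed = 1)
  build_leaf_geometry(width_px = 256, height_px = 256,
                      n_midrib_segments = 4, seed = seed)

# a short drydown for rendering tests
short_psi <- function(dt_min = 30, noise_sd = 0, seed = 1)
  generate_psychrometer_series(dt_min = dt_min, noise_sd = noise_sd,
                               seed = seed)

# hand-built event table (detected-events layout) from footprints
fake_events <- function(footprints, start_frame = seq_along(footprints)) {
  out <- data.frame(event_id = seq_along(footprints),
                    start_frame = start_frame,
                    end_frame = start_frame,
                    area_px = lengths(footprints),
                    centroid_row = NA_real_, centroid_col = NA_real_,
                    time_min = NA_real_)
  attr(out, "footprints") <- footprints
  class(out) <- c("event_table", "data.frame")
  out
}

# plant n isolated square flashes on a flat background; returns the stack
# and the ground truth
plant_flashes <- function(n = 25, side = 128, n_frames = 60, size = 3,
                          amp = 0.10, noise_sd = 0.02,
                          flash_frames = 2, seed = 1) {
  set.seed(seed)
  stack <- array(stats::rnorm(side * side * n_frames, mean = 0.5,
                              sd = noise_sd), c(side, side, n_frames))
  grid <- floor(sqrt(n)) + 1
  step <- side %/% (grid + 1)
  pos <- expand.grid(r = step * seq_len(grid), c = step * seq_len(grid))
  pos <- pos[seq_len(n), ]
  frames <- sort(sample(3:(n_frames - 3), n, replace = FALSE))
  fps <- vector("list", n)
  for (e in seq_len(n)) {
    rows <- pos$r[e] + 0:(size - 1); cols <- pos$c[e] + 0:(size - 1)
    fps[[e]] <- as.integer(outer(rows, (cols - 1) * side, "+"))
    for (f in frames[e]:min(n_frames, frames[e] + flash_frames - 1))
      stack[rows, cols, f] <- stack[rows, cols, f] + amp
  }
  list(stack = stack, frames = frames, footprints = fps)
}

# match detected events to planted truth by pixel overlap and frame
# proximity; returns recall, precision and per-match truth index
match_events <- function(events, truth_fps, truth_frames, max_lag = 3) {
  det_fps <- attr(events, "footprints")
  hit <- rep(NA_integer_, nrow(events))
  for (e in seq_len(nrow(events))) {
    ov <- vapply(seq_along(truth_fps), function(k)
      length(intersect(det_fps[[e]], truth_fps[[k]])), 0L)
    k <- which.max(ov)
    if (length(k) && ov[k] > 0 &&
        abs(events$start_frame[e] - truth_frames[k]) <= max_lag)
      hit[e] <- k
  }
  list(recall = length(unique(stats::na.omit(hit))) / length(truth_fps),
       precision = mean(!is.na(hit)), hit = hit)
}

# one rendered leaf shared by the slower optical tests (built on demand)
.render_cache <- new.env(parent = emptyenv())
rendered_leaf <- function() {
  if (is.null(.render_cache$leaf)) {
    geom <- build_leaf_geometry(width_px = 256, height_px = 256,
                                n_midrib_segments = 4, seed = 11)
    psi <- short_psi(dt_min = 30, noise_sd = 0.02, seed = 12)
    sched <- schedule_cavitation_events(geom, psi, seed = 13)
    stack <- render_stack(geom, sched, psi, seed = 14)
    events <- assign_vein_order(detect_events(difference_stack(stack)),
                                geom)
    .render_cache$leaf <- list(geom = geom, psi = psi, sched = sched,
                               events = events)
  }
  .render_cache$leaf
}
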