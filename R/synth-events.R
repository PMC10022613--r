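# Cavitation event schedules and optical stack rendering.

#' Default per-order cavitation parameters
#'
#' Trigger potentials follow per-order cumulative sigmoids
#' \eqn{1/(1+e^{(\Psi-P50)/\alpha})} (midrib most vulnerable, then major
#' veins, then HOV), i.e. trigger draws are logistic with location `p50`
#' and scale `alpha`.  Midrib and major segments carry multiple events
#' (normal counts, rounded, floored at 1); every HOV segment cavitates
#' exactly once, in a single whole-segment event.
#'
#' @return A named list with one entry per order: `p50`, `alpha`,
#'   `count_mean`, `count_sd`.
#' @export
order_defaults <- function() {
  list(midrib = list(p50 = -3.35, alpha = 0.25, count_mean = 9.4,
                     count_sd = 1.17),
       major = list(p50 = -3.80, alpha = 0.25, count_mean = 4.53,
                    count_sd = 0.51),
       hov = list(p50 = -4.07, alpha = 0.202, count_mean = 1,
                  count_sd = 0))
}

# A cavitation flash spreads slightly beyond the vein lumen: HOV event
# footprints are the 1-px segment dilated one pixel to each side across
# the vein axis, interior pixels only, so dilated footprints of pieces
# meeting at a crossing never share pixels.
dilate_hov_footprint <- function(seg, H) {
  px <- seg$px[[1]]
  if (length(px) < 3L) return(px)
  core <- px[-c(1L, length(px))]
  off <- if (seg$axis == "col") 1L else H      # across-axis neighbours
  sort(unique(c(px, core - off, core + off)))
}

# split a segment of axial length L into n disjoint stripes (2-4 px long,
# 2 px gap so stripes stay separable even under a 1-px detection
# tolerance); returns a list of index vectors into 1:L, possibly fewer
# than n when the segment is too short
axis_stripes <- function(L, n) {
  cap <- (L + 2L) %/% 4L                     # 2-px stripes + 2-px gaps
  n_eff <- min(n, max(1L, cap))
  len <- min(4L, max(2L, (L - 2L * (n_eff - 1L)) %/% n_eff))
  starts <- round(seq(1L, L - len + 1L, length.out = n_eff))
  if (n_eff > 1L)
    starts <- pmin(starts, c(starts[-1L] - len - 2L, L - len + 1L))
  lapply(starts, function(s) s:(s + len - 1L))
}

#' Schedule cavitation events on a leaf geometry
#'
#' Draws, per vein segment, the number of cavitation events and their
#' trigger water potentials, and maps each trigger onto the frame of a
#' stem-water-potential series.  Event footprints are whole segments for
#' HOV (one event deactivates the whole segment) and short axial
#' sub-stripes for midrib and major veins (several vessels per segment).
#'
#' @param geometry A [build_leaf_geometry()] object.
#' @param psi_series Data frame with `time_min` and `psi_stem` (see
#'   [generate_psychrometer_series()]).
#' @param orders Per-order parameter list, see [order_defaults()].
#' @param seed Integer seed.
#' @return An object of class `event_schedule`: a data frame with columns
#'   `event_id`, `segment_id`, `order`, `psi_trigger`, `frame`, `area_px`,
#'   and an attribute `footprints` holding one linear-pixel-index vector
#'   per event.  Events whose trigger lies beyond the end of the series are
#'   dropped with a warning.
#' @export
schedule_cavitation_events <- function(geometry, psi_series,
                                       orders = order_defaults(),
                                       seed = 1) {
  stopifnot(inherits(geometry, "leaf_geometry"),
            all(c("time_min", "psi_stem") %in% names(psi_series)))
  set.seed(seed)
  segs <- geometry$segments
  psi <- psi_series$psi_stem
  rows <- list(); fps <- list()
  for (ord in names(orders)) {
    par <- orders[[ord]]
    idx <- which(segs$order == ord)
    for (i in idx) {
      n <- if (ord == "hov") 1L else
        max(1L, as.integer(round(stats::rnorm(1, par$count_mean, par$count_sd))))
      trig <- sort(stats::rlogis(n, location = par$p50, scale = par$alpha),
                   decreasing = TRUE)
      if (ord == "hov") {
        foot <- list(dilate_hov_footprint(segs[i, ], geometry$height_px))
      } else {
        px <- segs$px[[i]]
        # order pixels along the segment axis, then cut into stripes
        ax <- if (segs$axis[i] == "row") ((px - 1L) %% geometry$height_px) + 1L
              else ((px - 1L) %/% geometry$height_px) + 1L
        o <- order(ax)
        levels_ax <- sort(unique(ax))
        stripes <- axis_stripes(length(levels_ax), n)
        if (length(stripes) < n) {
          warning(sprintf("segment %d: capacity %d < %d events requested",
                          segs$id[i], length(stripes), n))
          n <- length(stripes)
          trig <- trig[seq_len(n)]
        }
        stripes <- stripes[sample.int(n)]    # random stripe-to-event pairing
        foot <- lapply(stripes, function(s)
          px[o][ax[o] %in% levels_ax[s]])
      }
      for (e in seq_len(n)) {
        frame <- which(psi <= trig[e])[1L]
        rows[[length(rows) + 1L]] <-
          data.frame(segment_id = segs$id[i], order = ord,
                     psi_trigger = trig[e], frame = frame,
                     area_px = length(foot[[e]]))
        fps[[length(fps) + 1L]] <- foot[[e]]
      }
    }
  }
  out <- do.call(rbind, rows)
  keep <- !is.na(out$frame)
  if (any(!keep))
    warning(sprintf("%d events beyond the end of the psi series dropped",
                    sum(!keep)))
  out <- out[keep, , drop = FALSE]
  fps <- fps[keep]
  o <- order(out$frame, -out$psi_trigger)
  out <- out[o, , drop = FALSE]
  fps <- fps[o]
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("event_id", "segment_id", "order", "psi_trigger",
                 "frame", "area_px")]
  attr(out, "footprints") <- fps
  class(out) <- c("event_schedule", "data.frame")
  out
}

#' Render a synthetic optical-vulnerability image stack
#'
#' Produces a grayscale time-lapse stack (values in `[0, 1]`) in which each
#' scheduled cavitation event appears as a transient brightening of its
#' pixel footprint, over a leaf whose veins are darker than the lamina and
#' whose margin can shrink with the drydown's leaf-width series.
#'
#' @param geometry A [build_leaf_geometry()] object.
#' @param schedule An [schedule_cavitation_events()] table.
#' @param drydown Data frame with `time_min` and, when `shrink = TRUE`, a
#'   `width_pct` column; its length sets the number of frames.
#' @param flash_amp Intensity added over an event footprint (default 0.10).
#' @param flash_frames Number of consecutive frames an event stays bright
#'   (default 2).
#' @param noise_sd Gaussian pixel noise standard deviation (default 0.02;
#'   the default flash SNR is therefore 5).
#' @param shrink Move the margin so that the measured leaf width follows
#'   `drydown$width_pct` (default `FALSE`).
#' @param levels Base intensities: background, lamina, hov, major, midrib.
#' @param seed Integer seed for the pixel noise.
#' @return A 3-d array `[row, col, frame]` of class `ovt_stack` with
#'   attribute `frame_time` (minutes).
#' @export
render_stack <- function(geometry, schedule, drydown,
                         flash_amp = 0.10, flash_frames = 2L,
                         noise_sd = 0.02, shrink = FALSE,
                         levels = c(bg = 0.95, lamina = 0.60, hov = 0.40,
                                    major = 0.30, midrib = 0.20),
                         seed = 1) {
  stopifnot(inherits(geometry, "leaf_geometry"),
            inherits(schedule, "event_schedule"),
            "time_min" %in% names(drydown))
  H <- geometry$height_px; W <- geometry$width_px
  n_frames <- nrow(drydown)
  if (nrow(schedule) && max(schedule$frame) > n_frames)
    stop("schedule frames extend beyond the stack length", call. = FALSE)
  fps <- attr(schedule, "footprints")
  if (any(vapply(fps, function(p) any(p < 1L | p > H * W), TRUE)))
    stop("event footprint outside the image", call. = FALSE)
  set.seed(seed)

  base <- matrix(levels[["bg"]], H, W)
  lr <- geometry$lamina$rows; lc <- geometry$lamina$cols
  base[lr[1]:lr[2], lc[1]:lc[2]] <- levels[["lamina"]]
  base[geometry$order_mask == 3L] <- levels[["hov"]]
  base[geometry$order_mask == 2L] <- levels[["major"]]
  base[geometry$order_mask == 1L] <- levels[["midrib"]]

  hw0 <- geometry$mid_col - lc[1]
  width_pct <- if (shrink) {
    if (!"width_pct" %in% names(drydown))
      stop("'shrink = TRUE' needs a width_pct column in 'drydown'",
           call. = FALSE)
    drydown$width_pct
  } else rep(100, n_frames)

  # per-frame footprint lists (event flashes persist flash_frames frames)
  flash_px <- vector("list", n_frames)
  if (nrow(schedule)) {
    for (e in seq_len(nrow(schedule))) {
      for (f in schedule$frame[e]:min(n_frames,
                                      schedule$frame[e] + flash_frames - 1L))
        flash_px[[f]] <- c(flash_px[[f]], fps[[e]])
    }
  }

  stack <- array(0, dim = c(H, W, n_frames))
  cols_all <- seq_len(W)
  for (f in seq_len(n_frames)) {
    img <- base
    hw <- as.integer(round(hw0 * width_pct[f] / 100))
    if (hw < hw0) {      # margin moves inward; outside reverts to background
      out_cols <- cols_all[abs(cols_all - geometry$mid_col) > hw]
      img[, out_cols] <- levels[["bg"]]
    }
    if (!is.null(flash_px[[f]])) {
      px <- flash_px[[f]]
      keep <- abs(((px - 1L) %/% H + 1L) - geometry$mid_col) <= hw
      img[px[keep]] <- img[px[keep]] + flash_amp
    }
    if (noise_sd > 0) img <- img + stats::rnorm(H * W, sd = noise_sd)
    stack[, , f] <- pmin(pmax(img, 0), 1)
  }
  attr(stack, "frame_time") <- drydown$time_min
  class(stack) <- "ovt_stack"
  stack
}
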