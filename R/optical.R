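# Optical-vulnerability quantification: difference imaging, event
# detection, vein-order assignment, cumulative curves, per-segment counts,
# leaf-width measurement and functional-area-loss mapping.

#' Frame-to-frame absolute difference stack
#'
#' @param stack 3-d array `[row, col, frame]` with at least two frames of
#'   constant size (an `ovt_stack` or plain array).
#' @return Array of `n - 1` absolute difference frames; frame `t` holds
#'   `|I[t+1] - I[t]|`.  Attributes `frame_time` (time of the later frame)
#'   and `frame_offset = 1` are set so that detected events can be mapped
#'   back to original frame indices.
#' @export
difference_stack <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3L || d[3L] < 2L)
    stop("'stack' must be a 3-d array with at least 2 frames", call. = FALSE)
  ds <- abs(stack[, , -1L, drop = FALSE] - stack[, , -d[3L], drop = FALSE])
  ft <- attr(stack, "frame_time")
  attr(ds, "frame_time") <- if (!is.null(ft)) ft[-1L] else NULL
  attr(ds, "frame_offset") <- 1L
  class(ds) <- "ovt_diff"
  ds
}

# robust noise scale of an absolute-difference stack: for folded Gaussian
# noise the median is 0.6745 sigma.  Strided subsample keeps this cheap.
diff_noise_sigma <- function(dstack, max_n = 1e6) {
  n <- length(dstack)
  v <- if (n > max_n) dstack[seq(1L, n, length.out = max_n)] else
    as.vector(dstack)
  stats::median(v) / 0.6745
}

#' Detect cavitation events in a difference stack
#'
#' Thresholds each difference frame, labels connected components
#' (4-connectivity via \pkg{EBImage}), and merges components that overlap
#' in pixels across at most `merge_window` frames into single events, so
#' that the onset and offset episodes of a transient flash count once.
#'
#' The default threshold rule is Otsu's method on a pooled sample of the
#' difference histogram, floored at three robust noise standard deviations
#' (an unfloored Otsu threshold on a signal-free, unimodal histogram falls
#' inside the noise mode and floods the detector).
#'
#' @param dstack A [difference_stack()] (or any 3-d array of non-negative
#'   differences).
#' @param threshold `"otsu"` (default) or `"fixed"`.
#' @param threshold_value Threshold for `threshold = "fixed"`, required and
#'   positive.
#' @param min_area Minimum event footprint, pixels (applied to the merged
#'   pixel union).
#' @param merge_window Maximum frame gap across which overlapping
#'   components merge.
#' @param min_component_px Single-frame components smaller than this are
#'   discarded as noise speckle before merging (default 3; isolated
#'   supra-threshold noise pixels and pairs would otherwise dominate the
#'   merge bookkeeping).
#' @param noise_floor Lower bound on the threshold, in units of the
#'   robust noise sd of the difference stack (default 2.75).
#' @return An object of class `event_table`: a data frame with columns
#'   `event_id`, `start_frame` (index into the original stack),
#'   `end_frame`, `area_px`, `centroid_row`, `centroid_col` and `time_min`
#'   (`NA` when the stack carries no frame times), plus an attribute
#'   `footprints` (list of linear pixel indices).  An empty stack yields an
#'   empty table.  Detection is deterministic for a fixed configuration.
#' @export
detect_events <- function(dstack, threshold = c("otsu", "fixed"),
                          threshold_value = NULL, min_area = 4L,
                          merge_window = 2L, min_component_px = 3L,
                          noise_floor = 2.75) {
  threshold <- match.arg(threshold)
  d <- dim(dstack)
  if (length(d) != 3L)
    stop("'dstack' must be a 3-d array", call. = FALSE)
  H <- d[1L]; W <- d[2L]; Tn <- d[3L]
  offset <- attr(dstack, "frame_offset"); if (is.null(offset)) offset <- 0L
  ftime <- attr(dstack, "frame_time")

  empty <- function() {
    out <- data.frame(event_id = integer(), start_frame = integer(),
                      end_frame = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      time_min = numeric())
    attr(out, "footprints") <- list()
    class(out) <- c("event_table", "data.frame")
    out
  }
  if (Tn == 0L) return(empty())

  if (threshold == "fixed") {
    if (is.null(threshold_value) || threshold_value <= 0)
      stop("'threshold_value' must be a positive number", call. = FALSE)
    thr <- threshold_value
  } else {
    sig <- diff_noise_sigma(dstack)
    nz <- dstack[dstack > 0]
    if (length(nz) > 5e5) nz <- nz[seq(1L, length(nz), length.out = 5e5)]
    ot <- if (length(nz) > 10)
      EBImage::otsu(EBImage::Image(matrix(nz, 1L)),
                    range = c(0, max(nz)), levels = 256L) else 0
    thr <- max(ot, noise_floor * sig)
  }

  open <- list(); done <- list()
  for (f in seq_len(Tn)) {
    # retire events that can no longer merge
    if (length(open)) {
      stale <- vapply(open, function(e) e$last < f - merge_window, TRUE)
      done <- c(done, open[stale])
      open <- open[!stale]
    }
    bw <- dstack[, , f] > thr
    if (!any(bw)) next
    lab <- EBImage::bwlabel(bw)
    idx <- which(lab > 0)
    comps <- split(idx, as.vector(lab)[idx])
    comps <- comps[lengths(comps) >= min_component_px]
    for (cp in comps) {
      # overlap is tested on the 1-px dilated component so that the onset
      # and offset episodes of one flash merge even when noise dropout
      # makes their supra-threshold pixel subsets disjoint
      cpd <- unique(c(cp, cp - 1L, cp + 1L, cp - H, cp + H))
      hit <- which(vapply(open, function(e) any(cpd %in% e$px), TRUE))
      if (!length(hit)) {
        open[[length(open) + 1L]] <- list(px = cp, start = f, last = f)
      } else {
        k <- hit[1L]
        open[[k]]$px <- unique(c(open[[k]]$px, cp,
                                 unlist(lapply(open[hit[-1L]], `[[`, "px"))))
        open[[k]]$start <- min(c(open[[k]]$start,
                                 vapply(open[hit], `[[`, 0L, "start")))
        open[[k]]$last <- f
        if (length(hit) > 1L) open <- open[-hit[-1L]]
      }
    }
  }
  done <- c(done, open)
  if (!length(done)) return(empty())

  area <- vapply(done, function(e) length(e$px), 0L)
  keep <- area >= min_area
  done <- done[keep]; area <- area[keep]
  if (!length(done)) return(empty())
  start <- vapply(done, `[[`, 0L, "start")
  o <- order(start)
  done <- done[o]; area <- area[o]; start <- start[o]
  out <- data.frame(
    event_id = seq_along(done),
    start_frame = start + offset,
    end_frame = vapply(done, `[[`, 0L, "last") + offset,
    area_px = area,
    centroid_row = vapply(done, function(e) mean((e$px - 1L) %% H + 1L), 0),
    centroid_col = vapply(done, function(e) mean((e$px - 1L) %/% H + 1L), 0),
    time_min = if (is.null(ftime)) NA_real_ else ftime[start])
  attr(out, "footprints") <- lapply(done, function(e) sort(e$px))
  class(out) <- c("event_table", "data.frame")
  out
}

#' Assign vein order and segment to detected events
#'
#' Order is assigned by majority pixel overlap with the geometry's order
#' mask; ties break toward the lower (larger) order, midrib < major < hov,
#' and are reported.  The segment id is the majority overlap with the
#' segment map.  Events with no vein overlap are labelled background and
#' excluded with a warning.
#'
#' @param events An [detect_events()] table.
#' @param geometry A [build_leaf_geometry()] object whose mask matches the
#'   stack size.
#' @return The event table with `order` and `segment_id` columns added.
#' @export
assign_vein_order <- function(events, geometry) {
  stopifnot(inherits(geometry, "leaf_geometry"))
  fps <- attr(events, "footprints")
  if (!nrow(events)) {
    events$order <- character(0); events$segment_id <- integer(0)
    return(events)
  }
  names_ord <- c("midrib", "major", "hov")
  ord <- character(nrow(events)); seg <- integer(nrow(events))
  for (e in seq_len(nrow(events))) {
    lab <- geometry$order_mask[fps[[e]]]
    cnt <- tabulate(lab[lab %in% 1:3], nbins = 3L)
    if (!sum(cnt)) { ord[e] <- "background"; next }
    best <- which(cnt == max(cnt))
    if (length(best) > 1L)
      message(sprintf("event %d: order tie broken toward '%s'",
                      events$event_id[e], names_ord[best[1L]]))
    ord[e] <- names_ord[best[1L]]
    sl <- geometry$segment_map[fps[[e]]]
    sl <- sl[sl > 0L]
    seg[e] <- if (length(sl)) as.integer(names(which.max(table(sl)))) else 0L
  }
  drop <- ord == "background"
  if (any(drop))
    warning(sprintf("%d event(s) with no vein overlap excluded", sum(drop)))
  out <- events[!drop, , drop = FALSE]
  out$order <- ord[!drop]
  out$segment_id <- seg[!drop]
  attr(out, "footprints") <- fps[!drop]
  class(out) <- c("event_table", "data.frame")
  out
}

# water potential for each event: a schedule already carries its trigger;
# detected events are joined to the psi series by nearest time
event_psi <- function(events, psi_series = NULL, max_gap_min = 2.5) {
  if ("psi_trigger" %in% names(events)) return(events$psi_trigger)
  if ("psi_stem" %in% names(events)) return(events$psi_stem)
  if (is.null(psi_series))
    stop("detected events need a 'psi_series' to join on", call. = FALSE)
  tt <- events$time_min
  if (all(is.na(tt)))
    stop("events carry no frame times; re-detect from a stack with them",
         call. = FALSE)
  late <- tt > max(psi_series$time_min) + max_gap_min
  if (any(late))
    stop(sprintf("events at frames %s lie beyond the end of the psi series",
                 paste(events$start_frame[late], collapse = ", ")),
         call. = FALSE)
  idx <- vapply(tt, function(t) which.min(abs(psi_series$time_min - t)), 0L)
  psi_series$psi_stem[idx]
}

#' Cumulative cavitated area against water potential, by vein order
#'
#' Joins each event to the stem water potential at its start time (or uses
#' the scheduled trigger potential) and accumulates cavitated pixel area
#' per vein order, normalised by the order's final cumulative area so each
#' curve ends at 1.
#'
#' @param events An event table (detected and order-assigned, or an
#'   [schedule_cavitation_events()] table).
#' @param psi_series Stem water potential series for the time join (not
#'   needed for schedules).
#' @param max_gap_min Largest tolerated time gap in the nearest-time join.
#' @return A named list (class `cumulative_curves`) of data frames, one per
#'   order present, each with `psi`, `area_px`, `cum_area` and `cum_frac`
#'   sorted from wet to dry; `cum_frac` is non-decreasing as psi declines
#'   and reaches 1 at the driest event.
#' @export
cumulative_cavitation <- function(events, psi_series = NULL,
                                  max_gap_min = 2.5) {
  if (!"order" %in% names(events))
    stop("events need an 'order' column; see assign_vein_order()",
         call. = FALSE)
  psi <- event_psi(events, psi_series, max_gap_min)
  out <- list()
  for (ord in unique(events$order)) {
    i <- which(events$order == ord)
    o <- i[order(psi[i], decreasing = TRUE)]
    df <- data.frame(psi = psi[o], area_px = events$area_px[o])
    df$cum_area <- cumsum(df$area_px)
    df$cum_frac <- df$cum_area / sum(df$area_px)
    out[[ord]] <- df
  }
  class(out) <- "cumulative_curves"
  out
}

#' Water potential at a given cumulative cavitation fraction
#'
#' Linear interpolation across the step of the empirical cumulative curve;
#' e.g. `fraction = 0.5` gives the empirical P50.
#'
#' @param curve One element of [cumulative_cavitation()] (a data frame with
#'   `psi` and `cum_frac`).
#' @param fraction Target cumulative fraction in (0, 1].
#' @return Water potential, MPa.
#' @export
psi_at_fraction <- function(curve, fraction) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
  i <- which(curve$cum_frac >= fraction)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(curve$psi[1L])
  f0 <- curve$cum_frac[i - 1L]; f1 <- curve$cum_frac[i]
  w <- if (f1 > f0) (fraction - f0) / (f1 - f0) else 1
  curve$psi[i - 1L] + w * (curve$psi[i] - curve$psi[i - 1L])
}

#' Events per vein segment, by order
#'
#' Counts distinct events touching each segment (zero-event segments
#' included) and summarises per order.
#'
#' @param events Event table with `segment_id` and `order` columns.
#' @param segments Segment table (`geometry$segments`) or a `leaf_geometry`.
#' @return Data frame with `order`, `n_segments`, `mean_events`,
#'   `sd_events`.
#' @export
events_per_segment <- function(events, segments) {
  if (inherits(segments, "leaf_geometry")) segments <- segments$segments
  stopifnot(all(c("id", "order") %in% names(segments)))
  if (nrow(events) && !"segment_id" %in% names(events))
    stop("events need a 'segment_id' column", call. = FALSE)
  res <- lapply(unique(segments$order), function(ord) {
    ids <- segments$id[segments$order == ord]
    n <- if (nrow(events))
      vapply(ids, function(s) sum(events$segment_id == s), 0L)
    else rep(0L, length(ids))
    data.frame(order = ord, n_segments = length(ids),
               mean_events = mean(n),
               sd_events = if (length(n) > 1L) stats::sd(n) else 0)
  })
  do.call(rbind, res)
}

#' Measure leaf width from an image stack
#'
#' Measures, per frame, the distance from the edge of the midrib to the
#' leaf margin along horizontal transects (median of the configured rows,
#' three by default), in pixels and as a percentage of the first frame.
#' The margin is the last leaf pixel before a sustained run of
#' background-bright pixels.
#'
#' @param stack An `ovt_stack` (3-d array, leaf darker than background).
#' @param geometry The matching [build_leaf_geometry()].
#' @param rows Transect rows; default three rows at 1/4, 1/2 and 3/4 of the
#'   lamina, nudged off major veins is not needed since vein pixels are
#'   darker than the threshold anyway.
#' @param side `"right"` (default) or `"left"` of the midrib.
#' @return Data frame with `frame`, `time_min`, `width_px`, `width_pct` and
#'   a logical `missing` flag for frames where no margin was found (those
#'   get `NA`, not an error).
#' @export
measure_leaf_width <- function(stack, geometry, rows = NULL,
                               side = c("right", "left")) {
  side <- match.arg(side)
  d <- dim(stack); H <- d[1L]; W <- d[2L]; Tn <- d[3L]
  lr <- geometry$lamina$rows
  if (is.null(rows))
    rows <- round(lr[1] + c(0.25, 0.5, 0.75) * (lr[2] - lr[1]))
  f1 <- stack[, , 1L]
  bg <- stats::median(f1[, c(1:4, (W - 3):W)])
  lam <- stats::median(f1[lr[1]:lr[2],
                          geometry$mid_col + c(-20:-10, 10:20)])
  thr <- (bg + lam) / 2
  edge <- geometry$midrib_halfwidth
  out <- data.frame(frame = seq_len(Tn), time_min = NA_real_,
                    width_px = NA_real_, width_pct = NA_real_,
                    missing = FALSE)
  ft <- attr(stack, "frame_time")
  if (!is.null(ft)) out$time_min <- ft
  for (f in seq_len(Tn)) {
    w <- numeric(0)
    for (r in rows) {
      v <- stack[r, , f]
      scan <- if (side == "right")
        (geometry$mid_col + edge + 1L):W else (geometry$mid_col - edge - 1L):1L
      bright <- v[scan] >= thr
      # margin: first position where background stays bright for 3 px
      run <- which(bright & c(bright[-1], TRUE) & c(bright[-(1:2)], TRUE, TRUE))
      if (length(run)) w <- c(w, run[1L] - 1L)
    }
    if (!length(w)) { out$missing[f] <- TRUE; next }
    out$width_px[f] <- stats::median(w)
  }
  if (!is.na(out$width_px[1L]) && out$width_px[1L] > 0)
    out$width_pct <- 100 * out$width_px / out$width_px[1L]
  out
}

#' Leaf area remaining with functional HOV water supply
#'
#' Each HOV cavitation event severs the lamina area its segment uniquely
#' serves.  In `"tile"` mode that area is the nearest-vein tiling computed
#' by [build_leaf_geometry()] (half the distance to the nearest neighbouring
#' vein); `"brush"` mode instead paints a stripe of diameter equal to the
#' mean HOV nearest-neighbour distance along the segment.  The remaining
#' percentage is non-increasing in the number of cavitated segments and is
#' 100 with no events.
#'
#' @param events Event table with `order`, `segment_id` and a water
#'   potential (scheduled trigger or joined `psi_stem`).
#' @param geometry A [build_leaf_geometry()] object.
#' @param mode `"tile"` (default) or `"brush"`.
#' @param psi_series Optional psi series for detected events.
#' @return A list of class `functional_area`: `curve` (data frame `psi`,
#'   `segment_id`, `remaining_pct`, one row per newly cavitated segment,
#'   dry-ordered), `final_remaining_pct`, and `painted` (logical matrix of
#'   severed pixels).
#' @export
functional_area_remaining <- function(events, geometry,
                                      mode = c("tile", "brush"),
                                      psi_series = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "leaf_geometry"))
  hov_ids <- geometry$segments$id[geometry$segments$order == "hov"]
  ev <- events[events$order == "hov", , drop = FALSE]
  painted <- matrix(FALSE, geometry$height_px, geometry$width_px)
  lam_n <- geometry$lamina$n_px
  if (!nrow(ev))
    return(structure(list(curve = data.frame(psi = numeric(),
                                             segment_id = integer(),
                                             remaining_pct = numeric()),
                          final_remaining_pct = 100, painted = painted),
                     class = "functional_area"))
  psi <- event_psi(ev, psi_series)
  o <- order(psi, decreasing = TRUE)
  ev <- ev[o, , drop = FALSE]; psi <- psi[o]
  seen <- integer(0)
  rows <- list()
  brush_half <- max(1L, as.integer(round(geometry$mean_nn_um /
                                           geometry$scale_um / 2)))
  lr <- geometry$lamina$rows; lc <- geometry$lamina$cols
  for (e in seq_len(nrow(ev))) {
    sid <- ev$segment_id[e]
    if (!sid %in% hov_ids) {
      warning(sprintf("event %s: unknown HOV segment id %s skipped",
                      ev$event_id[e], sid))
      next
    }
    if (!sid %in% seen) {
      seen <- c(seen, sid)
      if (mode == "tile") {
        painted[geometry$served_map == sid] <- TRUE
      } else {
        s <- geometry$segments[geometry$segments$id == sid, ]
        r <- max(lr[1], s$row0 - brush_half):min(lr[2], s$row1 + brush_half)
        cl <- max(lc[1], s$col0 - brush_half):min(lc[2], s$col1 + brush_half)
        painted[r, cl] <- TRUE
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(psi = psi[e], segment_id = sid,
                 remaining_pct = 100 * (1 - sum(painted) / lam_n))
  }
  curve <- do.call(rbind, rows)
  structure(list(curve = curve,
                 final_remaining_pct = if (is.null(curve)) 100 else
                   curve$remaining_pct[nrow(curve)],
                 painted = painted),
            class = "functional_area")
}
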