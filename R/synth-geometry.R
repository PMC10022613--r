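# Procedural vein-network generator.
#
# The emulated leaf is a rectangular lamina with a vertical midrib, major
# veins branching horizontally from the midrib to the margin, and a
# reticulum of high-order veins (HOV) laid out as a jittered grid of 1-px
# lines whose physical diameter at the default scale is below 50 um.
# Every HOV line piece between two crossings is a segment; the area it
# uniquely serves is the set of lamina pixels closer to it than to any
# other HOV line (half the distance to the nearest neighboring vein).

# nearest grid value: returns index into 'grid' and distance, vectorised
nearest_grid <- function(x, grid) {
  k <- findInterval(x, grid)
  k0 <- pmax(k, 1L)
  k1 <- pmin(k + 1L, length(grid))
  d0 <- abs(x - grid[k0])
  d1 <- abs(x - grid[k1])
  use1 <- d1 < d0
  list(idx = ifelse(use1, k1, k0), dist = pmin(d0, d1))
}

#' Build a procedural leaf vein network
#'
#' Generates a deterministic (under `seed`) leaf geometry: order mask,
#' segment map, segment list and the served-area tiling used for
#' functional-area-loss mapping.  Vein orders are `midrib` (one axial
#' vein), `major` (veins branching from the midrib to the margin) and
#' `hov` (the high-order reticulum; 1 px wide, i.e. `scale_um` < 50 um in
#' diameter).
#'
#' @param width_px,height_px Image size in pixels (at least 256 each).
#' @param scale_um Pixel scale, micrometres per pixel; must keep the 1-px
#'   HOV diameter below 50 um.
#' @param hov_spacing_px Spacing of the HOV grid, pixels (>= 8).
#' @param n_major Total number of major veins (split between the two sides
#'   of the midrib), at least 6.
#' @param n_midrib_segments Number of segments the midrib is divided into.
#' @param margin_inset_px Distance of the lamina margin from the image
#'   border, pixels.
#' @param seed Integer seed controlling the (small) positional jitter.
#' @return An object of class `leaf_geometry`; see Details.
#' @details The returned list contains `order_mask` (integer matrix with
#'   0 background, 1 midrib, 2 major, 3 hov, 4 margin), `segment_map`
#'   (integer matrix of segment ids on vein pixels), `served_map` (integer
#'   matrix assigning every lamina pixel to the HOV segment that serves
#'   it), `segments` (data frame with id, order, axis, bounding box, pixel
#'   count, and a list column `px` of linear pixel indices),
#'   `served_px` (pixels served per HOV segment id), `lamina` (row/col
#'   ranges and pixel count) and `mean_nn_um`, the mean nearest-neighbour
#'   HOV distance.
#' @export
build_leaf_geometry <- function(width_px = 320, height_px = 320,
                                scale_um = 25, hov_spacing_px = 24,
                                n_major = 8, n_midrib_segments = 5,
                                margin_inset_px = 16, seed = 1) {
  if (width_px < 256 || height_px < 256)
    stop("image must be at least 256 x 256 px", call. = FALSE)
  if (scale_um >= 50)
    stop("'scale_um' must keep the 1-px HOV diameter below 50 um",
         call. = FALSE)
  if (hov_spacing_px < 8)
    stop("infeasible geometry: HOV grid denser than the pixel grid allows",
         call. = FALSE)
  if (n_major < 6) stop("need at least 6 major veins", call. = FALSE)
  set.seed(seed)

  H <- as.integer(height_px); W <- as.integer(width_px)
  inset <- as.integer(margin_inset_px)
  mid_col <- as.integer(ceiling(W / 2))
  rr <- (inset + 1L):(H - inset)              # lamina rows
  hw0 <- mid_col - inset - 1L                 # lamina half width, cols
  cc <- (mid_col - hw0):(mid_col + hw0)       # lamina cols
  mhw <- 2L                                   # midrib half width (5 px wide)
  mid_cols <- (mid_col - mhw):(mid_col + mhw)

  lin <- function(i, j) (rep(j, each = length(i)) - 1L) * H + rep(i, length(j))

  segs <- list()
  add_seg <- function(order, axis, rows, cols, px) {
    segs[[length(segs) + 1L]] <<- list(order = order, axis = axis,
                                       row0 = min(rows), row1 = max(rows),
                                       col0 = min(cols), col1 = max(cols),
                                       px = px)
  }

  # midrib, split lengthwise
  bands <- split(rr, cut(seq_along(rr), n_midrib_segments, labels = FALSE))
  for (b in bands) add_seg("midrib", "row", b, mid_cols, lin(b, mid_cols))

  # major veins: horizontal, jittered row positions, one segment per side
  n_side <- ceiling(n_major / 2)
  base <- round(seq(rr[1] + 0.1 * length(rr), rr[length(rr)] - 0.1 * length(rr),
                    length.out = n_side))
  major_rows <- integer(0)
  for (side in c("left", "right")) {
    rows0 <- base + sample(-4:4, n_side, replace = TRUE)
    ncount <- if (side == "left") n_side else n_major - n_side
    rows0 <- rows0[seq_len(ncount)]
    for (r in rows0) {
      rows <- c(r, r + 1L)
      cols <- if (side == "left") (cc[1] + 1L):(mid_col - mhw - 3L)
              else (mid_col + mhw + 3L):(cc[length(cc)] - 1L)
      add_seg("major", "col", rows, cols, lin(rows, cols))
      major_rows <- c(major_rows, r)
    }
  }
  major_band <- sort(unique(c(major_rows, major_rows + 1L)))

  # HOV grid: jittered offsets, 1-px lines, pieces between crossings
  sp <- as.integer(hov_spacing_px)
  off_h <- sample.int(sp, 1L) - 1L
  off_v <- sample.int(sp, 1L) - 1L
  hr <- seq(rr[1] + 3L + off_h, rr[length(rr)] - 3L, by = sp)
  vc <- seq(cc[1] + 3L + off_v, cc[length(cc)] - 3L, by = sp)
  vc <- vc[abs(vc - mid_col) > mhw + 3L]      # no vertical HOV near the midrib
  # keep HOV lines at least 3 px clear of larger veins so that laterally
  # spread optical flashes of different orders can never touch
  major_buffer <- sort(unique(c(outer(major_rows, -2:3, "+"))))
  hr <- hr[!hr %in% major_buffer]
  mid_buffer <- (mid_col - mhw - 2L):(mid_col + mhw + 2L)
  if (length(hr) < 3L || length(vc) < 3L)
    stop("infeasible geometry: lamina too small for the HOV spacing",
         call. = FALSE)

  colbreaks <- sort(c(vc, mid_col))
  rowbreaks <- sort(unique(c(hr, major_rows)))
  hov_first <- length(segs) + 1L
  h_id <- matrix(0L, length(hr), length(colbreaks) + 1L)
  v_id <- matrix(0L, length(vc), length(rowbreaks) + 1L)
  bounds_c <- c(cc[1], colbreaks, cc[length(cc)])
  bounds_r <- c(rr[1] - 1L, rowbreaks, rr[length(rr)] + 1L)
  for (k in seq_along(hr)) {
    for (iv in seq_len(length(colbreaks) + 1L)) {
      c1 <- bounds_c[iv] + 2L; c2 <- bounds_c[iv + 1L] - 2L
      cols <- setdiff(seq(c1, length.out = max(0L, c2 - c1 + 1L)),
                      mid_buffer)
      if (length(cols) >= 4L) {
        add_seg("hov", "col", hr[k], cols, lin(hr[k], cols))
        h_id[k, iv] <- length(segs)
      }
    }
    # orphan intervals inherit the nearest kept piece on the same line
    have <- which(h_id[k, ] > 0L)
    if (length(have))
      h_id[k, ] <- h_id[k, have[nearest_grid(seq_len(ncol(h_id)), have)$idx]]
  }
  for (k in seq_along(vc)) {
    for (iv in seq_len(length(rowbreaks) + 1L)) {
      r1 <- bounds_r[iv] + 2L; r2 <- bounds_r[iv + 1L] - 2L
      rows <- setdiff(seq(r1, length.out = max(0L, r2 - r1 + 1L)),
                      major_buffer)
      if (length(rows) >= 4L) {
        add_seg("hov", "row", rows, vc[k], lin(rows, vc[k]))
        v_id[k, iv] <- length(segs)
      }
    }
    have <- which(v_id[k, ] > 0L)
    if (length(have))
      v_id[k, ] <- v_id[k, have[nearest_grid(seq_len(ncol(v_id)), have)$idx]]
  }

  segments <- data.frame(id = seq_along(segs),
                         order = vapply(segs, `[[`, "", "order"),
                         axis = vapply(segs, `[[`, "", "axis"),
                         row0 = vapply(segs, `[[`, 0, "row0"),
                         row1 = vapply(segs, `[[`, 0, "row1"),
                         col0 = vapply(segs, `[[`, 0, "col0"),
                         col1 = vapply(segs, `[[`, 0, "col1"))
  segments$n_px <- vapply(segs, function(s) length(s$px), 0L)
  segments$px <- lapply(segs, `[[`, "px")
  if (sum(segments$order == "hov") < 50L)
    stop("infeasible geometry: fewer than 50 HOV segments", call. = FALSE)

  # masks; draw order hov < major < midrib so lower orders take precedence
  order_mask <- matrix(0L, H, W)
  segment_map <- matrix(0L, H, W)
  code <- c(midrib = 1L, major = 2L, hov = 3L)
  for (ord in c("hov", "major", "midrib")) {
    for (i in which(segments$order == ord)) {
      order_mask[segments$px[[i]]] <- code[[ord]]
      segment_map[segments$px[[i]]] <- segments$id[i]
    }
  }
  edge <- c(lin(rr, cc[1]), lin(rr, cc[length(cc)]),
            lin(rr[1], cc), lin(rr[length(rr)], cc))
  order_mask[edge[order_mask[edge] == 0L]] <- 4L

  # served-area tiling: every lamina pixel -> nearest HOV line piece
  i <- rep(rr, times = length(cc))
  j <- rep(cc, each = length(rr))
  nh <- nearest_grid(i, hr)
  nv <- nearest_grid(j, vc)
  use_h <- nh$dist <= nv$dist
  seg_of <- integer(length(i))
  iv_h <- findInterval(j, colbreaks) + 1L
  iv_v <- findInterval(i, rowbreaks) + 1L
  seg_of[use_h] <- h_id[cbind(nh$idx[use_h], iv_h[use_h])]
  seg_of[!use_h] <- v_id[cbind(nv$idx[!use_h], iv_v[!use_h])]
  served_map <- matrix(0L, H, W)
  served_map[lin(rr, cc)] <- seg_of
  served_px <- tabulate(seg_of, nbins = nrow(segments))

  structure(list(width_px = W, height_px = H, scale_um = scale_um,
                 lamina = list(rows = range(rr), cols = range(cc),
                               n_px = length(i)),
                 mid_col = mid_col, midrib_halfwidth = mhw,
                 order_mask = order_mask, segment_map = segment_map,
                 served_map = served_map, served_px = served_px,
                 segments = segments,
                 hov_spacing_px = sp, mean_nn_um = sp * scale_um,
                 seed = seed),
            class = "leaf_geometry")
}

#' @export
print.leaf_geometry <- function(x, ...) {
  tab <- table(x$segments$order)
  cat(sprintf("Leaf geometry %d x %d px (%.0f um/px)\n",
              x$width_px, x$height_px, x$scale_um))
  cat(sprintf("  segments: %d midrib, %d major, %d hov\n",
              tab[["midrib"]], tab[["major"]], tab[["hov"]]))
  cat(sprintf("  lamina %d px; mean HOV spacing %.0f um\n",
              x$lamina$n_px, x$mean_nn_um))
  invisible(x)
}
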