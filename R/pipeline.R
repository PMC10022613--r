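# End-to-end orchestration: synthetic bundle -> optical quantification ->
# fitting -> trait table and threshold-coincidence comparison.

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()].  Defaults reproduce the
#' study conditions: 13 replicate leaves, 6 fluorescence plants, a 5-day
#' drydown from -0.5 to -6 MPa, per-order vulnerability sigmoids at
#' -3.35 / -3.80 / -4.07 MPa, event counts 9.4 and 4.53 per midrib and
#' major segment (HOV exactly once), the printed width calibration, and
#' the Table-1 hydraulic parameters.  With `couple_thresholds = TRUE`
#' (default) the width and Fv/Fm breakpoints are generated at the runaway
#' point of the configured hydraulics, the regime in which the pipeline's
#' three damage thresholds are expected to coincide.
#'
#' @param ... Named overrides, merged recursively (e.g.
#'   `synthesis = list(n_leaves = 3)`).
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1) {
  cfg <- list(
    seed = seed,
    synthesis = list(
      n_leaves = 13, n_fvfm_plants = 6, n_pv = 5, n_gmin = 5,
      n_stem_plants = 6,
      days = 5, dt_min = 20, psi0 = -0.5, psi_end = -6, psi_noise_sd = 0.02,
      geometry = list(width_px = 320, height_px = 320, scale_um = 25,
                      hov_spacing_px = 24, n_major = 8,
                      n_midrib_segments = 5, margin_inset_px = 16),
      orders = order_defaults(),
      stem = list(p50 = -3.97, alpha = 0.743, n_events = 150),
      width = list(slope = 6.1963, intercept = 106.22, noise_sd = 0.5,
                   post_multiplier = 3, breakpoint = -3.62),
      fvfm = list(plateau = 0.80, death_value = 0.05, noise_sd = 0.02,
                  breakpoint = -3.53),
      couple_thresholds = TRUE,
      gmin = list(true = 10.02, area_m2 = 1e-3, noise_sd = 0),
      pv = list(tlp = -2.01, n = 20, noise_sd = 5e-4),
      rehydration = list(kmax = 5.77, x0 = -3.73, b = 0.25, y0 = 0,
                         n = 24, noise_sd = 0.01)),
    hydraulics = list(kmax = 5.77, p50 = -3.73, alpha = 0.09,
                      gmin = 10.02, vpd_kpa = 1.94, temp_c = 20,
                      rh_pct = NULL, patm_kpa = 101.3, capacitance = 50),
    optical = list(render = FALSE, threshold = "otsu", min_area = 4,
                   merge_window = 2, flash_amp = 0.1, flash_frames = 2,
                   noise_sd = 0.02),
    report = list(write = TRUE))
  structure(merge_config(cfg, list(...)), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' The JSON holds any subset of the [pipeline_config()] tree; missing
#' entries keep their defaults.
#'
#' @param path Path to a JSON run configuration.
#' @return A `pipeline_config`.
#' @export
read_run_config <- function(path) {
  override <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  do.call(pipeline_config, override)
}

#' One-way ANOVA with Tukey HSD contrasts
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (at least 2 groups
#'   with at least 2 values each).
#' @return List with `f`, `p`, `df`, and `tukey`, a data frame of pairwise
#'   contrasts (`pair`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_groups <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  wvar <- tapply(values, g, stats::var)
  if (all(wvar < 1e-300))
    stop("degenerate: zero within-group variance in every group",
         call. = FALSE)
  fm <- stats::aov(values ~ g)
  an <- summary(fm)[[1]]
  tk <- stats::TukeyHSD(fm)$g
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}

# empirical cumulative curve from trigger potentials and areas
curve_from_triggers <- function(psi, area = rep(1, length(psi))) {
  o <- order(psi, decreasing = TRUE)
  df <- data.frame(psi = psi[o], area_px = area[o])
  df$cum_area <- cumsum(df$area_px)
  df$cum_frac <- df$cum_area / sum(df$area_px)
  df
}

trait_row <- function(trait, unit, replicate, value, stage) {
  data.frame(trait = trait, unit = unit, replicate = replicate,
             value = value, stage = stage)
}

#' Run the full synthetic drydown analysis pipeline
#'
#' Generates (under the configured seed) the complete synthetic bundle -
#' per-leaf psychrometer series, vein geometries and cavitation schedules
#' (optionally rendered to image stacks and re-detected optically),
#' fluorescence and width series, stem event streams, gmin, PV and
#' rehydration traces - runs every estimator, and assembles a trait table
#' and the threshold-coincidence comparison.  Re-running with an identical
#' configuration reproduces the outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, the trait table
#'   (CSV + JSON), the comparison report (JSON) and per-leaf event tables
#'   (CSV) are written there.
#' @return Object of class `cavistress_run`: list with `trait_table`
#'   (fields `values`, `summary`), `comparison` (class
#'   `threshold_comparison`), `per_leaf` fit details and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  syn <- cfg$synthesis
  hyd <- cfg$hydraulics
  opt <- cfg$optical
  seed0 <- cfg$seed * 1000L

  vpd <- if (!is.null(hyd$vpd_kpa)) hyd$vpd_kpa else
    vpd_arden_buck(hyd$temp_c, hyd$rh_pct)
  env <- leaf_environment(temp_c = hyd$temp_c,
                          rh_pct = if (is.null(hyd$rh_pct)) 50 else
                            hyd$rh_pct,
                          patm_kpa = hyd$patm_kpa, gmin = hyd$gmin,
                          vpd_kpa = vpd)
  hyd_curve <- vuln_curve(hyd$kmax, hyd$p50, hyd$alpha)
  rw_cfg <- runaway_point(hyd_curve, env$ec)
  bp_width_true <- if (isTRUE(syn$couple_thresholds))
    rw_cfg$psi_runaway else syn$width$breakpoint
  bp_fvfm_true <- if (isTRUE(syn$couple_thresholds))
    rw_cfg$psi_runaway else syn$fvfm$breakpoint

  ramp <- (syn$psi_end - syn$psi0) / (syn$days * 1440)
  time_of_psi <- function(psi) (psi - syn$psi0) / ramp

  vals <- list()
  add <- function(...) vals[[length(vals) + 1L]] <<- trait_row(...)
  per_leaf <- list()

  for (i in seq_len(syn$n_leaves)) {
    si <- seed0 + i
    psi_series <- generate_psychrometer_series(syn$psi0, syn$psi_end,
                                               syn$days, syn$dt_min,
                                               syn$psi_noise_sd, seed = si)
    geom <- do.call(build_leaf_geometry,
                    c(syn$geometry, list(seed = si + 500L)))
    sched <- schedule_cavitation_events(geom, psi_series, syn$orders,
                                        seed = si + 700L)
    stage <- sprintf("leaf%02d", i)
    if (isTRUE(opt$render)) {
      stack <- render_stack(geom, sched, psi_series,
                            flash_amp = opt$flash_amp,
                            flash_frames = opt$flash_frames,
                            noise_sd = opt$noise_sd, shrink = FALSE,
                            seed = si + 900L)
      ev <- detect_events(difference_stack(stack),
                          threshold = opt$threshold,
                          min_area = opt$min_area,
                          merge_window = opt$merge_window)
      ev <- assign_vein_order(ev, geom)
      ev$psi_stem <- event_psi(ev, psi_series)
      rm(stack)
    } else {
      ev <- sched
    }
    curves <- cumulative_cavitation(ev, psi_series)
    p50s <- list()
    for (ord in c("midrib", "major", "hov")) {
      fit <- tryCatch(fit_cavitation_curve(curves[[ord]]),
                      error = function(e) NULL)
      p50s[[ord]] <- if (is.null(fit)) NA_real_ else fit$p50
      if (ord == "hov" && !is.null(fit)) {
        add("P20_hov", "MPa", i, extract_px(fit, 20), stage)
        add("P88_hov", "MPa", i, extract_px(fit, 88), stage)
      }
    }
    add("P50_mid", "MPa", i, p50s$midrib, stage)
    add("P50_maj", "MPa", i, p50s$major, stage)
    add("P50_hov", "MPa", i, p50s$hov, stage)
    psi_all <- event_psi(ev, psi_series)
    pooled <- curve_from_triggers(psi_all, ev$area_px)
    add("P50_veins_pooled", "MPa", i, psi_at_fraction(pooled, 0.5), stage)

    cnt <- events_per_segment(ev, geom)
    for (ord in c("midrib", "major", "hov"))
      add(paste0("events_per_segment_", ord), "events", i,
          cnt$mean_events[cnt$order == ord], stage)

    # leaf width against stem water potential: decoupling below the
    # transition makes the apparent slope steepen
    psi_leaf <- generate_psi_leaf(psi_series$psi_stem, bp_width_true,
                                  syn$width$post_multiplier)
    width <- generate_width_series(psi_leaf, syn$width$slope,
                                   syn$width$intercept,
                                   syn$width$noise_sd, seed = si + 1100L)
    bw <- fit_breakpoint(psi_series$psi_stem, width)
    add("BP_width", "MPa", i, bw$breakpoint, stage)
    add("BP_width_time", "min", i,
        if (is.na(bw$breakpoint)) NA_real_ else time_of_psi(bw$breakpoint),
        stage)
    per_leaf[[i]] <- list(p50s = p50s, counts = cnt, bp_width = bw,
                          n_events = nrow(ev))
  }

  for (j in seq_len(syn$n_fvfm_plants)) {
    sj <- seed0 + 400L + j
    psi_series <- generate_psychrometer_series(syn$psi0, syn$psi_end,
                                               syn$days, syn$dt_min,
                                               syn$psi_noise_sd, seed = sj)
    fv <- generate_fvfm_series(psi_series$psi_stem, bp_fvfm_true,
                               syn$fvfm$plateau, syn$fvfm$death_value,
                               syn$psi_end, syn$fvfm$noise_sd,
                               seed = sj + 50L)
    bf <- fit_breakpoint(psi_series$psi_stem, fv)
    add("BP_fvfm", "MPa", j, bf$breakpoint, sprintf("fvfm%02d", j))
    add("BP_fvfm_time", "min", j,
        if (is.na(bf$breakpoint)) NA_real_ else time_of_psi(bf$breakpoint),
        sprintf("fvfm%02d", j))
  }

  for (j in seq_len(syn$n_stem_plants)) {
    set.seed(seed0 + 600L + j)
    trig <- stats::rlogis(syn$stem$n_events, syn$stem$p50, syn$stem$alpha)
    cv <- curve_from_triggers(trig)
    fit <- fit_cavitation_curve(cv)
    add("P50_stem", "MPa", j, fit$p50, sprintf("stem%02d", j))
    add("P88_stem", "MPa", j, extract_px(fit, 88), sprintf("stem%02d", j))
  }

  for (j in seq_len(syn$n_pv)) {
    pv <- generate_pv_series(tlp = syn$pv$tlp, n = syn$pv$n,
                             noise_sd = syn$pv$noise_sd,
                             seed = seed0 + 800L + j)
    tl <- tlp_from_pv(pv$psi, pv$mass_g, mass_sat = 1, mass_dry = 0.2)
    add("TLP", "MPa", j, tl$tlp, sprintf("pv%02d", j))
  }

  gmins <- numeric(0)
  for (j in seq_len(syn$n_gmin)) {
    tr <- generate_gmin_trace(gmin = syn$gmin$true,
                              area_m2 = syn$gmin$area_m2, env = env,
                              noise_sd = syn$gmin$noise_sd,
                              seed = seed0 + 850L + j)
    gf <- gmin_from_trace(tr, syn$gmin$area_m2, temp_c = env$temp_c,
                          patm_kpa = env$patm_kpa, vpd_kpa = env$vpd_kpa)
    gmins <- c(gmins, gf$gmin)
    add("gmin", "mmol m-2 s-1", j, gf$gmin, sprintf("gmin%02d", j))
  }

  reh <- generate_rehydration_samples(kmax = syn$rehydration$kmax,
                                      x0 = syn$rehydration$x0,
                                      b = syn$rehydration$b,
                                      y0 = syn$rehydration$y0,
                                      n = syn$rehydration$n,
                                      noise_sd = syn$rehydration$noise_sd,
                                      seed = seed0 + 950L)
  kl <- fit_kleaf_curve(reh)
  add("Kmax", "mmol s-1 m-2 MPa-1", 1, kl$kmax, "rehydration")
  add("P50_leaf", "MPa", 1, kl$p50, "rehydration")

  ec_fit <- cuticular_transpiration(mean(gmins), env$vpd_kpa, env$patm_kpa)
  add("VPD", "kPa", 1, env$vpd_kpa, "environment")
  add("Ec", "mmol m-2 s-1", 1, ec_fit, "environment")
  rw <- runaway_point(vuln_curve(kl$kmax, kl$p50, hyd$alpha), ec_fit)
  add("runaway_psi", "MPa", 1, rw$psi_runaway, "runaway")
  add("runaway_plc", "%", 1, rw$plc_runaway, "runaway")

  values <- do.call(rbind, vals)
  summ <- do.call(rbind, lapply(split(values, values$trait), function(d)
    data.frame(trait = d$trait[1], unit = d$unit[1], n = sum(!is.na(d$value)),
               mean = mean(d$value, na.rm = TRUE),
               sd = if (sum(!is.na(d$value)) > 1L)
                 stats::sd(d$value, na.rm = TRUE) else NA_real_)))
  rownames(summ) <- NULL
  trait_table <- list(values = values, summary = summ)

  msum <- function(tr) summ$mean[summ$trait == tr]
  th <- c(BP_width = msum("BP_width"), BP_fvfm = msum("BP_fvfm"),
          P20_hov = msum("P20_hov"), TLP = msum("TLP"),
          runaway = msum("runaway_psi"), P88_stem = msum("P88_stem"))
  res_mpa <- outer(th, th, "-")
  res_min <- outer(time_of_psi(th), time_of_psi(th), "-")
  dimnames(res_min) <- dimnames(res_mpa)

  p50_long <- values[values$trait %in% c("P50_mid", "P50_maj", "P50_hov") &
                       !is.na(values$value), ]
  cmp_p50 <- compare_groups(p50_long$value, p50_long$trait)
  cnt_long <- values[grepl("^events_per_segment", values$trait), ]
  cmp_cnt <- tryCatch(compare_groups(cnt_long$value, cnt_long$trait),
                      error = function(e) NULL)

  comparison <- structure(
    list(thresholds_mpa = th, residuals_mpa = res_mpa,
         residuals_min = res_min,
         dt_p20hov_bpwidth_min = res_min["P20_hov", "BP_width"],
         anova_p50 = cmp_p50, anova_counts = cmp_cnt),
    class = "threshold_comparison")

  out <- structure(list(trait_table = trait_table, comparison = comparison,
                        per_leaf = per_leaf, config = cfg),
                   class = "cavistress_run")
  if (!is.null(out_dir) && isTRUE(cfg$report$write)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trait_table(trait_table, file.path(out_dir, "trait_table"))
    write_report(comparison, file.path(out_dir, "report.json"))
  }
  out
}

#' @export
print.cavistress_run <- function(x, ...) {
  cat("cavistress pipeline run\n")
  cat(sprintf("  %d leaves, seed %d\n",
              x$config$synthesis$n_leaves, x$config$seed))
  cat("\nTrait summary:\n")
  print(x$trait_table$summary, digits = 4)
  cat("\nThresholds (MPa):\n")
  print(round(x$comparison$thresholds_mpa, 3))
  invisible(x)
}

#' @export
print.threshold_comparison <- function(x, ...) {
  cat("Damage-threshold comparison\n")
  print(round(x$residuals_mpa, 3))
  cat(sprintf("\nP20_hov - BP_width: %.1f min\n", x$dt_p20hov_bpwidth_min))
  cat(sprintf("vein-order P50 ANOVA: F = %.2f, p = %.3g\n",
              x$anova_p50$f, x$anova_p50$p))
  invisible(x)
}

#' Write / read the trait table
#'
#' `write_trait_table()` writes a CSV summary (fixed column order, units in
#' the header) and a JSON file with the per-replicate values;
#' `read_trait_table()` reads them back into the same structure.
#'
#' @param trait_table The `trait_table` element of a [run_pipeline()] run.
#' @param path Base path; `.csv` and `.json` are appended.
#' @return `write_trait_table()` the paths, invisibly;
#'   `read_trait_table()` a `trait_table` list.
#' @export
write_trait_table <- function(trait_table, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  s <- trait_table$summary[, c("trait", "unit", "n", "mean", "sd")]
  utils::write.csv(s, csv, row.names = FALSE)
  jsonlite::write_json(list(summary = s, values = trait_table$values),
                       js, digits = NA, na = "null")
  invisible(c(csv = csv, json = js))
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  js <- jsonlite::fromJSON(paste0(path, ".json"))
  list(values = js$values, summary = js$summary)
}

#' Write the threshold-comparison report
#'
#' @param comparison A `threshold_comparison`.
#' @param path Output JSON path.
#' @export
write_report <- function(comparison, path) {
  jsonlite::write_json(
    list(thresholds_mpa = as.list(comparison$thresholds_mpa),
         residuals_mpa = comparison$residuals_mpa,
         residuals_min = comparison$residuals_min,
         dt_p20hov_bpwidth_min = comparison$dt_p20hov_bpwidth_min,
         anova_p50 = comparison$anova_p50[c("f", "p")],
         anova_counts = comparison$anova_counts[c("f", "p")]),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
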