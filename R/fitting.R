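# Estimators: cumulative-cavitation sigmoid (and monotone smoother),
# P-level extraction, OLS calibration, rehydration-kinetics conductance,
# 4-parameter K_leaf sigmoid, gmin from mass traces, PV-curve turgor loss.

#' Fit a cumulative cavitation curve
#'
#' Parametric default: least squares on the declining sigmoid
#' \eqn{F(\Psi) = 1/(1 + e^{(\Psi - P50)/\alpha})}.  Alternatively a
#' monotone smoother (isotonic regression on the wet-to-dry ordering,
#' linearly interpolated), useful as a shape-agnostic cross-check.
#'
#' @param curve A data frame with `psi` and `cum_frac` (one element of
#'   [cumulative_cavitation()]), or two vectors via `psi` and `frac`.
#' @param method `"sigmoid"` (default) or `"smoother"`.
#' @param psi,frac Alternative vector interface.
#' @return Object of class `vuln_fit`: `p50`, `alpha` (sigmoid only),
#'   `method`, `sigma` (residual sd), `n`, and `fun`, the fitted
#'   evaluable curve \eqn{F(\Psi)}.
#' @export
fit_cavitation_curve <- function(curve = NULL, method = c("sigmoid",
                                                          "smoother"),
                                 psi = NULL, frac = NULL) {
  method <- match.arg(method)
  if (!is.null(curve)) {
    psi <- curve$psi
    frac <- if (!is.null(curve$cum_frac)) curve$cum_frac else curve$frac
  }
  ok <- is.finite(psi) & is.finite(frac)
  psi <- psi[ok]; frac <- frac[ok]
  if (length(unique(psi)) < 6L)
    stop("need at least 6 distinct psi levels", call. = FALSE)
  # monotonicity check: cumulative fraction must not drop as psi declines
  o <- order(psi, decreasing = TRUE)
  viol <- max(cummax(frac[o]) - frac[o])
  if (viol > 0.1)
    stop(sprintf("input not monotone: cumulative fraction drops by %.2f",
                 viol), call. = FALSE)

  if (method == "sigmoid") {
    p50_0 <- psi[which.min(abs(frac - 0.5))]
    alpha_0 <- max(diff(range(psi)) / 10, 1e-3)
    fm <- minpack.lm::nlsLM(frac ~ 1 / (1 + exp((psi - p50) / alpha)),
                            start = list(p50 = p50_0, alpha = alpha_0),
                            lower = c(p50 = min(psi) - 1, alpha = 1e-6),
                            upper = c(p50 = max(psi) + 1, alpha = Inf),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
    cf <- stats::coef(fm)
    fun <- function(p) 1 / (1 + exp((p - cf[["p50"]]) / cf[["alpha"]]))
    out <- list(p50 = cf[["p50"]], alpha = cf[["alpha"]],
                method = "sigmoid",
                sigma = sqrt(mean(stats::residuals(fm)^2)),
                n = length(psi), fun = fun,
                range = range(psi))
  } else {
    # isotonic fit in the wet-to-dry direction, then linear interpolation
    iso <- stats::isoreg(-psi, frac)
    xs <- iso$x[iso$ord]                     # sorted -psi
    fit_fun <- stats::approxfun(rev(-xs), rev(iso$yf), rule = 2,
                                ties = mean)
    out <- list(p50 = NA_real_, alpha = NA_real_, method = "smoother",
                sigma = sqrt(mean((fit_fun(psi) - frac)^2)),
                n = length(psi), fun = fit_fun, range = range(psi))
    out$p50 <- tryCatch(extract_px_numeric(out, 50), error = function(e)
      NA_real_)
  }
  structure(out, class = "vuln_fit")
}

#' @export
print.vuln_fit <- function(x, ...) {
  cat(sprintf("Cumulative cavitation curve fit (%s, n = %d)\n",
              x$method, x$n))
  if (x$method == "sigmoid")
    cat(sprintf("  P50 = %.4f MPa, alpha = %.4f MPa, resid sd %.3g\n",
                x$p50, x$alpha, x$sigma))
  else
    cat(sprintf("  P50 (numeric) = %.4f MPa, resid sd %.3g\n",
                x$p50, x$sigma))
  invisible(x)
}

#' @export
predict.vuln_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) seq(object$range[1], object$range[2],
                                 length.out = 101)
       else if (is.list(newdata)) newdata$psi else newdata
  object$fun(x)
}

#' @export
coef.vuln_fit <- function(object, ...) {
  c(p50 = object$p50, alpha = object$alpha)
}

extract_px_numeric <- function(fit, p) {
  f <- p / 100
  lo <- fit$range[1]; hi <- fit$range[2]
  flo <- fit$fun(lo); fhi <- fit$fun(hi)
  if (f > max(flo, fhi) || f < min(flo, fhi))
    stop(sprintf("P%g outside the fitted range", p), call. = FALSE)
  stats::uniroot(function(x) fit$fun(x) - f, c(lo, hi), tol = 1e-9)$root
}

#' Water potential at p percent cumulative cavitation
#'
#' Inverts a fitted cumulative cavitation curve.  For the sigmoid this is
#' the closed form \eqn{\Psi_p = P50 + \alpha \ln((100-p)/p)}, so that
#' `extract_px(fit, 50)` returns the P50 exactly; for the smoother the
#' inverse is found numerically and extrapolation beyond the data range is
#' an error.
#'
#' @param fit A [fit_cavitation_curve()] object, or any list with `p50`
#'   and `alpha` components (a sigmoid parameterisation).
#' @param p Percent cavitation, in (0, 100).
#' @return Water potential, MPa.
#' @examples
#' extract_px(list(p50 = -4.07, alpha = 0.202), 20)  # P20 = -3.79
#' @export
extract_px <- function(fit, p) {
  stopifnot(is.numeric(p), all(p > 0), all(p < 100))
  if (inherits(fit, "vuln_fit") && fit$method == "smoother")
    return(vapply(p, function(pp) extract_px_numeric(fit, pp), 0))
  if (is.null(fit$p50) || is.null(fit$alpha))
    stop("'fit' must carry p50 and alpha", call. = FALSE)
  fit$p50 + fit$alpha * log((100 - p) / p)
}

#' Ordinary least squares line with closed-form summary
#'
#' @param x,y Numeric vectors.
#' @return List with `slope`, `intercept`, `r2`, `p_value`, `sigma`, `n`.
#' @export
fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  fm <- stats::lm(y ~ x, subset = ok)
  sm <- suppressWarnings(summary(fm))   # noiseless input is legitimate here
  list(slope = stats::coef(fm)[[2]], intercept = stats::coef(fm)[[1]],
       r2 = sm$r.squared,
       p_value = if (nrow(sm$coefficients) > 1L &&
                     ncol(sm$coefficients) >= 4L)
         sm$coefficients[2, 4] else NA_real_,
       sigma = sm$sigma, n = sum(ok))
}

#' Viscosity ratio of water relative to 20 degrees C
#'
#' Vogel equation for liquid water, \eqn{\ln\eta = A + B/(T - C)} with T in
#' kelvin; only the ratio \eqn{\eta(T)/\eta(20°C)} is used, so A cancels.
#'
#' @param temp_c Temperature, degrees C.
#' @return Dimensionless ratio; exactly 1 at 20 degrees C.
#' @export
water_viscosity_ratio <- function(temp_c) {
  B <- 578.919; C <- 137.546
  exp(B / (temp_c + 273.15 - C) - B / (293.15 - C))
}

#' Instantaneous leaf conductance from a rehydration record
#'
#' Two conductances are implied by one record, `K = F / (area |psi|)` at
#' the initial and at the rehydrated water potential, both standardised to
#' 20 degrees C water viscosity.  Records whose two values disagree by
#' more than `tol` (default 10\%) are flagged; otherwise the mean is the
#' accepted value.
#'
#' @param fmax,f2 Peak and half-time flows, mmol s\eqn{^{-1}}.
#' @param psi_init,psi_fin Initial and final water potentials, MPa
#'   (strictly negative).
#' @param area_m2 Leaf area, m\eqn{^2}.
#' @param temp_c Measurement temperature, degrees C.
#' @param tol Relative disagreement that triggers the flag.
#' @return List with `k1`, `k2` (mmol s\eqn{^{-1}} m\eqn{^{-2}}
#'   MPa\eqn{^{-1}}), `k` (accepted mean), `flagged`.
#' @export
kleaf_instance <- function(fmax, f2, psi_init, psi_fin, area_m2,
                           temp_c = 20, tol = 0.10) {
  if (any(c(psi_init, psi_fin) >= 0))
    stop("water potentials must be strictly negative", call. = FALSE)
  if (area_m2 <= 0) stop("'area_m2' must be positive", call. = FALSE)
  visc <- water_viscosity_ratio(temp_c)
  k1 <- fmax / (area_m2 * abs(psi_init)) * visc
  k2 <- f2 / (area_m2 * abs(psi_fin)) * visc
  rel <- abs(k1 - k2) / mean(c(k1, k2))
  list(k1 = k1, k2 = k2, k = mean(c(k1, k2)), flagged = rel > tol,
       rel_diff = rel)
}

#' Fit the 4-parameter K_leaf vulnerability sigmoid
#'
#' Nonlinear least squares of
#' \eqn{y = y_0 + a/(1 + e^{-(\Psi - x_0)/b})} over a deterministic
#' multistart grid (8 starts), with the reduction to the 3-parameter
#' vulnerability curve used by the runaway formulas: plateau
#' `kmax = y0 + a`, `p50` the water potential where the curve crosses
#' `kmax/2`, and `alpha = |b|`.
#'
#' @param records Data frame of rehydration records
#'   ([generate_rehydration_samples()] layout), or vectors via `psi`/`k`.
#' @param psi,k Optional explicit vectors of water potential and accepted
#'   conductance.
#' @return Object of class `kleaf_fit` with `y0`, `a`, `x0`, `b`, the
#'   reduction `kmax`, `p50`, `alpha`, residual `sigma`, `n`, and the
#'   number of flagged records.
#' @export
fit_kleaf_curve <- function(records = NULL, psi = NULL, k = NULL) {
  n_flagged <- 0L
  if (!is.null(records)) {
    ki <- mapply(function(fm, f2, pi, pf, a, tc)
      kleaf_instance(fm, f2, pi, pf, a, tc),
      records$fmax, records$f2, records$psi_init, records$psi_fin,
      records$area_m2, records$temp_c, SIMPLIFY = FALSE)
    k <- vapply(ki, `[[`, 0, "k")
    n_flagged <- sum(vapply(ki, `[[`, TRUE, "flagged"))
    psi <- records$psi_init
  }
  if (length(psi) < 6L)
    stop("need at least 6 records to fit the 4-parameter sigmoid",
         call. = FALSE)
  starts <- expand.grid(
    x0 = stats::quantile(psi, c(0.35, 0.65), names = FALSE),
    b = c(0.1, 0.3, 0.8, 1.5))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fm <- tryCatch(
      minpack.lm::nlsLM(k ~ y0 + a / (1 + exp(-(psi - x0) / b)),
                        start = list(y0 = max(0, min(k)),
                                     a = max(k) - min(k),
                                     x0 = starts$x0[s], b = starts$b[s]),
                        lower = c(y0 = 0, a = 1e-8, x0 = min(psi) - 2,
                                  b = 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fm)) {
      sse <- sum(stats::residuals(fm)^2)
      if (is.null(best) || sse < best$sse) best <- list(fm = fm, sse = sse)
    }
  }
  if (is.null(best))
    stop(sprintf(paste0("K_leaf sigmoid fit failed from all %d starts ",
                        "(n = %d, k range %.3g-%.3g)"),
                 nrow(starts), length(k), min(k), max(k)), call. = FALSE)
  cf <- stats::coef(best$fm)
  y0 <- cf[["y0"]]; a <- cf[["a"]]; x0 <- cf[["x0"]]; b <- cf[["b"]]
  kmax <- y0 + a
  p50 <- if (a > y0) x0 - b * log((a + y0) / (a - y0)) else NA_real_
  structure(list(y0 = y0, a = a, x0 = x0, b = b,
                 kmax = kmax, p50 = p50, alpha = abs(b),
                 sigma = sqrt(mean(stats::residuals(best$fm)^2)),
                 n = length(k), n_flagged = n_flagged, fit = best$fm),
            class = "kleaf_fit")
}

#' @export
print.kleaf_fit <- function(x, ...) {
  cat(sprintf("K_leaf 4-parameter sigmoid (n = %d, %d flagged)\n",
              x$n, x$n_flagged))
  cat(sprintf("  y0 = %.4g, a = %.4g, x0 = %.4g, b = %.4g\n",
              x$y0, x$a, x$x0, x$b))
  cat(sprintf("  reduction: Kmax = %.4g, P50 = %.4g MPa, alpha = %.4g MPa\n",
              x$kmax, x$p50, x$alpha))
  invisible(x)
}

#' @export
coef.kleaf_fit <- function(object, ...) {
  c(y0 = object$y0, a = object$a, x0 = object$x0, b = object$b)
}

#' @export
predict.kleaf_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) seq(-6, -0.1, length.out = 101)
       else if (is.list(newdata)) newdata$psi else newdata
  object$y0 + object$a / (1 + exp(-(x - object$x0) / object$b))
}

#' @export
as_vuln_curve.kleaf_fit <- function(x, ...) {
  vuln_curve(kmax = x$kmax, p50 = x$p50, alpha = x$alpha)
}

#' Minimum cuticular conductance from a mass-loss trace
#'
#' Finds the terminal steady phase of the trace (the longest window ending
#' at the last sample in which the rolling slope varies by less than 5\%),
#' converts its mass slope to a molar water-loss flux and applies
#' `gmin = WL * Patm / VPD` with VPD from [vpd_arden_buck()].
#'
#' @param trace Data frame with `time_min` and `mass_g` (at least 30 min).
#' @param area_m2 Leaf area, m\eqn{^2}.
#' @param temp_c,rh_pct Conditions during the measurement.
#' @param patm_kpa Atmospheric pressure, kPa.
#' @param vpd_kpa Optional VPD override, kPa; when `NULL` it is derived
#'   from `temp_c` and `rh_pct`.
#' @param window_pts Rolling-slope window length, points (default a tenth
#'   of the trace, at least 5).
#' @return List with `gmin` (mmol m\eqn{^{-2}} s\eqn{^{-1}}), `wl` (molar
#'   flux), `slope_g_per_s`, `phase_start_min`, `vpd_kpa`.
#' @export
gmin_from_trace <- function(trace, area_m2, temp_c = 24.31,
                            rh_pct = 35.86, patm_kpa = 101.3,
                            vpd_kpa = NULL, window_pts = NULL) {
  stopifnot(all(c("time_min", "mass_g") %in% names(trace)))
  if (max(trace$time_min) - min(trace$time_min) < 30)
    stop("need at least 30 min of trace", call. = FALSE)
  if (area_m2 <= 0) stop("'area_m2' must be positive", call. = FALSE)
  n <- nrow(trace)
  w <- if (is.null(window_pts)) max(5L, n %/% 10L) else window_pts
  # flat trace: no measurable loss at all
  if (max(abs(diff(trace$mass_g))) < 1e-12 &&
      abs(trace$mass_g[n] - trace$mass_g[1]) < 1e-12) {
    return(list(gmin = 0, wl = 0, slope_g_per_s = 0,
                phase_start_min = trace$time_min[1],
                vpd_kpa = if (is.null(vpd_kpa))
                  vpd_arden_buck(temp_c, rh_pct) else vpd_kpa))
  }
  slope_win <- function(i)                      # window ending at i
    stats::coef(stats::lm(mass_g ~ time_min,
                          data = trace[(i - w + 1L):i, ]))[[2]]
  ends <- seq(w, n)
  sl <- vapply(ends, slope_win, 0)
  s_end <- sl[length(sl)]
  if (abs(s_end) < 1e-15)
    stop("no stable terminal phase: terminal slope is zero", call. = FALSE)
  ok <- abs(sl - s_end) / abs(s_end) < 0.05
  run_start <- max(which(!ok), 0L) + 1L         # first index of terminal run
  if (run_start > length(ends))
    stop("no stable terminal phase detected", call. = FALSE)
  i0 <- ends[run_start] - w + 1L
  phase <- trace[i0:n, ]
  slope_g_min <- stats::coef(stats::lm(mass_g ~ time_min, data = phase))[[2]]
  slope_g_s <- slope_g_min / 60
  wl <- -slope_g_s / 18.0153 * 1000 / area_m2   # mmol m-2 s-1
  vpd <- if (is.null(vpd_kpa)) vpd_arden_buck(temp_c, rh_pct) else vpd_kpa
  list(gmin = wl * patm_kpa / vpd, wl = wl, slope_g_per_s = slope_g_s,
       phase_start_min = phase$time_min[1], vpd_kpa = vpd)
}

#' Turgor loss point from a pressure-volume curve
#'
#' Plots \eqn{-1/\Psi} against relative water deficit and grows the
#' terminal (post-turgor) linear segment from the dry end while it stays
#' straight (r-squared at least `r2_min`, minimum `min_pts` points).  The
#' turgor loss point is the water potential of the wettest point still on
#' the line; the osmotic potential at full turgor comes from the
#' intercept at zero deficit.
#'
#' @param psi Water potentials, MPa (all negative), wet to dry in any
#'   order.
#' @param mass_g Paired leaf masses, g.
#' @param mass_sat Saturated mass, g.
#' @param mass_dry Dry mass, g (default 0; only water differences matter).
#' @param r2_min Linearity criterion for the terminal segment.
#' @param min_pts Minimum points in the terminal segment.
#' @return List of class `pv_fit`: `tlp` (MPa), `po` (osmotic potential at
#'   full turgor, MPa), `slope`, `intercept` (of \eqn{-1/\Psi} vs deficit),
#'   `n_linear`, `all_linear` (degenerate all-linear input flag).
#' @export
tlp_from_pv <- function(psi, mass_g, mass_sat, mass_dry = 0,
                        r2_min = 0.995, min_pts = 4L) {
  if (any(psi >= 0)) stop("all 'psi' must be negative", call. = FALSE)
  if (length(psi) < 10L) stop("need at least 10 points", call. = FALSE)
  d <- 1 - (mass_g - mass_dry) / (mass_sat - mass_dry)  # water deficit
  o <- order(d)
  d <- d[o]; psi <- psi[o]
  y <- -1 / psi
  n <- length(d)
  r2_of <- function(i0) {
    xx <- d[i0:n]; yy <- y[i0:n]
    fm <- stats::lm(yy ~ xx)
    1 - sum(stats::residuals(fm)^2) / sum((yy - mean(yy))^2)
  }
  i_best <- n - min_pts + 1L
  if (i_best < 1L) stop("too few points for the linear tail", call. = FALSE)
  while (i_best > 1L && r2_of(i_best - 1L) >= r2_min) i_best <- i_best - 1L
  all_linear <- i_best == 1L
  if (all_linear)
    warning("entire curve is linear: no turgor phase; TLP set at the wettest point")
  if (r2_of(i_best) < r2_min)
    stop("no linear post-turgor tail found", call. = FALSE)
  fm <- stats::lm(y[i_best:n] ~ d[i_best:n])
  cf <- stats::coef(fm)
  structure(list(tlp = psi[i_best], po = -1 / cf[[1]],
                 slope = cf[[2]], intercept = cf[[1]],
                 n_linear = n - i_best + 1L, all_linear = all_linear),
            class = "pv_fit")
}

#' @export
print.pv_fit <- function(x, ...) {
  cat("Pressure-volume curve analysis\n")
  cat(sprintf("  TLP = %.3f MPa (terminal line through %d points)\n",
              x$tlp, x$n_linear))
  cat(sprintf("  osmotic potential at full turgor = %.3f MPa\n", x$po))
  invisible(x)
}
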