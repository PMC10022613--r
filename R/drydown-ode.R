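#' Dynamic leaf drydown with cavitation feedback
#'
#' Integrates the capacitance-buffered leaf water balance
#' \deqn{C \frac{d\Psi_l}{dt} = K(\Psi_l)(\Psi_s(t) - \Psi_l) - E_c}
#' while the source water potential declines linearly, and flags the onset
#' of runaway cavitation as the first time the quasi-steady solution ceases
#' to exist, i.e. when the peak of the supply curve drops below the demand
#' `ec`.  Before onset the leaf tracks the stable quasi-steady root with a
#' small lag; after onset no steady state exists and the leaf water
#' potential collapses, the positive-feedback signature of runaway
#' cavitation.
#'
#' Fluxes are in mmol m\eqn{^{-2}} s\eqn{^{-1}} and time in minutes, so the
#' balance is integrated as `60 * (supply - ec) / capacitance` MPa per
#' minute.
#'
#' @param curve A [vuln_curve()].
#' @param ec Cuticular transpiration demand, mmol m\eqn{^{-2}} s\eqn{^{-1}}.
#'   `ec = 0` disables the demand: the leaf then tracks the source with zero
#'   equilibrium offset and never runs away.
#' @param psi0 Initial (equilibrated) water potential of both source and
#'   leaf, MPa.
#' @param ramp Source drydown rate, MPa per minute (negative).  The default
#'   is \eqn{-5.5/7200}, i.e. \eqn{-0.5 \to -6} MPa over 5 days.
#' @param capacitance Leaf hydraulic capacitance, mmol m\eqn{^{-2}}
#'   MPa\eqn{^{-1}}.  The default (50) corresponds to a thin, fast
#'   equilibrating leaf with a relaxation time `capacitance / K` of about
#'   half a minute near the runaway point.
#' @param dt Output time step, minutes (must resolve the collapse;
#'   `dt <= 0.5` recommended).
#' @param t_end End of integration, minutes; defaults to the time at which
#'   the source ramp ends plus a margin.
#' @param psi_floor Leaf water potential at which integration stops, MPa.
#' @return An object of class `drydown_sim`: a list with `series` (a data
#'   frame of `time_min`, `psi_source`, `psi_leaf`, `supply`), `onset_time`
#'   (minutes, `NA` if no onset), `psi_leaf_onset`, `psi_source_onset`, the
#'   closed-form [runaway_point()] for comparison, and the parameters.
#' @export
simulate_drydown_ode <- function(curve, ec, psi0 = -0.5,
                                 ramp = -5.5 / 7200,
                                 capacitance = 50, dt = 0.5,
                                 t_end = NULL, psi_floor = -12) {
  curve <- as_vuln_curve(curve)
  stopifnot(is.numeric(ec), length(ec) == 1L, ec >= 0,
            is.numeric(capacitance), capacitance > 0,
            is.numeric(ramp), ramp < 0, dt > 0)
  if (dt > 0.5)
    warning("'dt' larger than 0.5 min may not resolve the collapse")
  if (is.null(t_end))
    t_end <- (psi_floor / 2 - psi0) / ramp
  psi_source_at <- function(t) psi0 + ramp * t

  deriv <- function(t, y, parms) {
    ps <- psi_source_at(t)
    pl <- min(y[1L], ps)               # guard: leaf never above source
    list(60 * (supply_rate(curve, pl, ps) - ec) / capacitance)
  }
  root <- function(t, y, parms) y[1L] - psi_floor
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(c(psi_leaf = psi0), times, deriv, NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-9,
                      rootfun = root)
  if (any(!is.finite(sol[, 2L])))
    stop(sprintf("integration failed near t = %.1f min; reduce 'dt'",
                 sol[max(which(is.finite(sol[, 2L]))), 1L]), call. = FALSE)
  series <- data.frame(time_min = sol[, 1L],
                       psi_source = psi_source_at(sol[, 1L]),
                       psi_leaf = pmin(sol[, 2L], psi_source_at(sol[, 1L])))
  series$supply <- supply_rate(curve, series$psi_leaf, series$psi_source)

  onset_time <- NA_real_
  psi_leaf_onset <- NA_real_
  closed <- if (ec > 0) runaway_point(curve, ec) else NULL
  if (ec > 0) {
    m <- vapply(series$psi_source,
                function(ps) supply_max(curve, ps)$supply - ec, 0)
    i <- which(m < 0)[1L]
    if (!is.na(i) && i > 1L) {
      f <- function(t) supply_max(curve, psi_source_at(t))$supply - ec
      onset_time <- stats::uniroot(f, series$time_min[c(i - 1L, i)],
                                   tol = 1e-8)$root
      psi_leaf_onset <- stats::approx(series$time_min, series$psi_leaf,
                                      xout = onset_time)$y
    }
  }
  structure(list(series = series,
                 onset_time = onset_time,
                 psi_leaf_onset = psi_leaf_onset,
                 psi_source_onset = if (is.na(onset_time)) NA_real_ else
                   psi_source_at(onset_time),
                 runaway = closed,
                 params = list(curve = curve, ec = ec, psi0 = psi0,
                               ramp = ramp, capacitance = capacitance,
                               dt = dt)),
            class = "drydown_sim")
}

#' @export
print.drydown_sim <- function(x, ...) {
  cat("Leaf drydown simulation\n")
  cat(sprintf("  %d steps of %.3g min; source ramp %.3g MPa/min\n",
              nrow(x$series), x$params$dt, x$params$ramp))
  if (is.na(x$onset_time)) {
    cat("  no runaway onset within the simulated window\n")
  } else {
    cat(sprintf("  runaway onset at t = %.1f min, psi_leaf = %.4f MPa\n",
                x$onset_time, x$psi_leaf_onset))
    cat(sprintf("  closed-form runaway point: %.4f MPa\n",
                x$runaway$psi_runaway))
  }
  invisible(x)
}

#' @export
plot.drydown_sim <- function(x, ...) {
  s <- x$series
  graphics::plot(s$time_min, s$psi_source, type = "l", lty = 2,
                 xlab = "time (min)", ylab = "water potential (MPa)",
                 ylim = range(c(s$psi_source, s$psi_leaf)), ...)
  graphics::lines(s$time_min, s$psi_leaf, col = 2)
  if (!is.na(x$onset_time))
    graphics::abline(v = x$onset_time, col = 4, lty = 3)
  graphics::legend("bottomleft", c("source", "leaf", "runaway onset"),
                   lty = c(2, 1, 3), col = c(1, 2, 4), bty = "n")
  invisible(x)
}
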