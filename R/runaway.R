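#' Steady-state xylem water supply to the leaf
#'
#' The supply rate through a partially cavitated pathway,
#' \eqn{S(\Psi_l) = K(\Psi_l)\,(\Psi_s - \Psi_l)}, evaluated at the current
#' leaf and source water potentials.  For a fixed source potential the
#' supply is zero at \eqn{\Psi_l = \Psi_s}, rises as the leaf depressurises,
#' peaks, and collapses again as cavitation destroys conductance; runaway
#' failure occurs when this peak falls below the transpirational demand.
#'
#' @param curve A [vuln_curve()].
#' @param psi_leaf Leaf water potential, MPa (vectorised).
#' @param psi_source Source (stem/soil) water potential, MPa.
#' @return Supply rate, mmol m\eqn{^{-2}} s\eqn{^{-1}}.
#' @export
supply_rate <- function(curve, psi_leaf, psi_source) {
  curve <- as_vuln_curve(curve)
  if (any(!is.finite(psi_leaf)) || any(!is.finite(psi_source)))
    stop("water potentials must be finite", call. = FALSE)
  if (any(psi_leaf > psi_source + 1e-12))
    stop("'psi_leaf' must not exceed 'psi_source'", call. = FALSE)
  conductance(curve, psi_leaf) * (psi_source - psi_leaf)
}

# Maximum of the supply function over psi_leaf for a fixed source potential.
# Returns the maximising leaf water potential and the peak supply.
supply_max <- function(curve, psi_source, tol = 1e-10) {
  lower <- min(curve$p50 - 40 * curve$alpha, psi_source - 1)
  opt <- stats::optimize(function(p) supply_rate(curve, p, psi_source),
                         interval = c(lower, psi_source),
                         maximum = TRUE, tol = tol)
  list(psi_leaf = opt$maximum, supply = opt$objective)
}

#' Closed-form runaway cavitation point
#'
#' The water potential at which the peak steady-state supply through the
#' vulnerability curve equals the cuticular demand `ec`, beyond which no
#' steady state exists and cavitation becomes self-amplifying:
#' \deqn{\Psi_{run} = P50 - \alpha \ln(\alpha K_{max} / E_c),}
#' with associated percent loss of conductance
#' \deqn{PLC_{run} = 100\,x/(1+x), \qquad x = \alpha K_{max}/E_c.}
#' These two expressions are exactly self-consistent:
#' `plc_at_psi(curve, psi_runaway)` equals `plc_runaway` for any parameter
#' set.
#'
#' @param curve A [vuln_curve()].
#' @param ec Cuticular transpiration, mmol m\eqn{^{-2}} s\eqn{^{-1}};
#'   must be positive (see [cuticular_transpiration()]).
#' @return An object of class `runaway_point` with elements `psi_runaway`
#'   (MPa), `plc_runaway` (percent), `k_at_runaway` (conductance at the
#'   runaway point), `psi_source_critical` (source potential at which the
#'   steady state vanishes; filled in by the numeric oracle, `NA` for the
#'   closed form) and `method`.
#' @examples
#' vc <- vuln_curve(5.77, -3.73, 0.09)
#' runaway_point(vc, ec = 0.19)
#' @export
runaway_point <- function(curve, ec) {
  curve <- as_vuln_curve(curve)
  if (!is.numeric(ec) || length(ec) != 1L || !is.finite(ec) || ec <= 0)
    stop("'ec' must be a single positive number", call. = FALSE)
  x <- curve$alpha * curve$kmax / ec
  structure(list(psi_runaway = curve$p50 - curve$alpha * log(x),
                 plc_runaway = 100 * x / (1 + x),
                 k_at_runaway = curve$kmax / (1 + x),
                 psi_source_critical = NA_real_,
                 method = "closed-form",
                 curve = curve, ec = ec),
            class = "runaway_point")
}

#' Numerical runaway point by supply-demand bracketing
#'
#' Independent oracle for [runaway_point()]: for a trial source water
#' potential the supply curve is maximised over the leaf water potential
#' (scalar optimisation), and the source potential at which that maximum
#' equals the demand `ec` is found by root bracketing.  The maximising leaf
#' water potential at the critical source potential is the runaway point;
#' it does not depend on the starting source potential.
#'
#' @inheritParams runaway_point
#' @param psi_source_start Source water potential from which the downward
#'   search starts, MPa (default 0, i.e. full hydration).
#' @param step Bracketing step, MPa.
#' @return A `runaway_point` object with `method = "numeric"` and
#'   `psi_source_critical` filled in.  If the demand already exceeds the
#'   peak supply at `psi_source_start` the search stops with an error
#'   stating that runaway has already passed.
#' @export
runaway_point_numeric <- function(curve, ec, psi_source_start = 0,
                                  step = 0.5) {
  curve <- as_vuln_curve(curve)
  if (!is.numeric(ec) || length(ec) != 1L || !is.finite(ec) || ec <= 0)
    stop("'ec' must be a single positive number", call. = FALSE)
  margin <- function(ps) supply_max(curve, ps)$supply - ec
  if (margin(psi_source_start) <= 0)
    stop(sprintf(paste0("runaway already passed: peak supply at source ",
                        "potential %.3f MPa is below demand %.4g"),
                 psi_source_start, ec), call. = FALSE)
  hi <- psi_source_start
  lo <- hi - step
  n <- 0L
  while (margin(lo) > 0) {
    hi <- lo
    lo <- lo - step
    n <- n + 1L
    if (n > 200L)
      stop(sprintf(paste0("no runaway bracket found in [%.2f, %.2f] MPa; ",
                          "demand may never exceed supply"),
                   lo, psi_source_start), call. = FALSE)
  }
  ps_crit <- stats::uniroot(margin, c(lo, hi), tol = 1e-11)$root
  at <- supply_max(curve, ps_crit)
  structure(list(psi_runaway = at$psi_leaf,
                 plc_runaway = plc_at_psi(curve, at$psi_leaf),
                 k_at_runaway = conductance(curve, at$psi_leaf),
                 psi_source_critical = ps_crit,
                 method = "numeric",
                 curve = curve, ec = ec),
            class = "runaway_point")
}

#' @export
print.runaway_point <- function(x, ...) {
  cat(sprintf("Runaway cavitation point (%s)\n", x$method))
  cat(sprintf("  psi_runaway: %.4f MPa\n", x$psi_runaway))
  cat(sprintf("  PLC at runaway: %.2f %%\n", x$plc_runaway))
  cat(sprintf("  K at runaway: %.4f mmol s-1 m-2 MPa-1\n", x$k_at_runaway))
  if (is.finite(x$psi_source_critical))
    cat(sprintf("  critical source potential: %.4f MPa\n",
                x$psi_source_critical))
  invisible(x)
}
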