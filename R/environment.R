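#' Vapor-pressure deficit from the Arden-Buck saturation formula
#'
#' \deqn{VPD = (1 - RH/100)\; 0.61121\, e^{17.502\,T/(240.97 + T)}}
#' assuming the leaf internal airspaces are saturated, so the deficit is the
#' dry-down of ambient air relative to saturation at air temperature.
#'
#' @param temp_c Air temperature, degrees C (must exceed -240.97).
#' @param rh_pct Relative humidity, percent, in `[0, 100]`.
#' @return VPD in kPa; zero at saturation (`rh_pct = 100`).
#' @examples
#' vpd_arden_buck(24.31, 35.86)  # ~1.95 kPa
#' @export
vpd_arden_buck <- function(temp_c, rh_pct) {
  stopifnot(is.numeric(temp_c), is.numeric(rh_pct))
  if (any(!is.finite(temp_c)) || any(temp_c <= -240.97))
    stop("'temp_c' must be finite and > -240.97", call. = FALSE)
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0) || any(rh_pct > 100))
    stop("'rh_pct' must lie in [0, 100]", call. = FALSE)
  (1 - rh_pct / 100) * 0.61121 * exp(17.502 * temp_c / (240.97 + temp_c))
}

#' Cuticular transpiration from minimum conductance
#'
#' \eqn{E_c = g_{min} \cdot VPD / P_{atm}}: the residual water loss through
#' the cuticle after stomatal closure, i.e. the demand term of the
#' supply-demand balance at the runaway-cavitation point.
#'
#' @param gmin Minimum (cuticular) conductance, mmol m\eqn{^{-2}} s\eqn{^{-1}}.
#' @param vpd_kpa Vapor-pressure deficit, kPa.
#' @param patm_kpa Atmospheric pressure, kPa (default 101.3).
#' @return Transpiration rate, mmol m\eqn{^{-2}} s\eqn{^{-1}}.
#' @examples
#' cuticular_transpiration(10.02, 1.94, 101.3)  # ~0.19
#' @export
cuticular_transpiration <- function(gmin, vpd_kpa, patm_kpa = 101.3) {
  stopifnot(is.numeric(gmin), is.numeric(vpd_kpa), is.numeric(patm_kpa))
  if (any(gmin < 0) || any(vpd_kpa < 0))
    stop("'gmin' and 'vpd_kpa' must be non-negative", call. = FALSE)
  if (any(patm_kpa <= 0))
    stop("'patm_kpa' must be positive", call. = FALSE)
  gmin * vpd_kpa / patm_kpa
}

#' Bundle the evaporative environment of a drydown experiment
#'
#' Collects the micrometeorological drivers and derives VPD (if not supplied)
#' via [vpd_arden_buck()] and cuticular transpiration via
#' [cuticular_transpiration()].
#'
#' @param temp_c Air temperature, degrees C.
#' @param rh_pct Relative humidity, percent.
#' @param patm_kpa Atmospheric pressure, kPa.
#' @param gmin Minimum cuticular conductance, mmol m\eqn{^{-2}} s\eqn{^{-1}}.
#' @param vpd_kpa Optional VPD override, kPa; when `NULL` it is derived from
#'   temperature and humidity.
#' @return A list of class `leaf_environment` with fields `temp_c`, `rh_pct`,
#'   `patm_kpa`, `gmin`, `vpd_kpa` and the derived `ec`.
#' @export
leaf_environment <- function(temp_c = 24.31, rh_pct = 35.86,
                             patm_kpa = 101.3, gmin = 10.02,
                             vpd_kpa = NULL) {
  if (is.null(vpd_kpa)) vpd_kpa <- vpd_arden_buck(temp_c, rh_pct)
  if (vpd_kpa < 0) stop("'vpd_kpa' must be non-negative", call. = FALSE)
  structure(list(temp_c = temp_c, rh_pct = rh_pct, patm_kpa = patm_kpa,
                 gmin = gmin, vpd_kpa = vpd_kpa,
                 ec = cuticular_transpiration(gmin, vpd_kpa, patm_kpa)),
            class = "leaf_environment")
}

#' @export
print.leaf_environment <- function(x, ...) {
  cat("Leaf evaporative environment\n")
  cat(sprintf("  T = %.2f C, RH = %.1f %%, Patm = %.1f kPa\n",
              x$temp_c, x$rh_pct, x$patm_kpa))
  cat(sprintf("  VPD = %.3f kPa, gmin = %.2f mmol m-2 s-1\n",
              x$vpd_kpa, x$gmin))
  cat(sprintf("  Ec  = %.4f mmol m-2 s-1\n", x$ec))
  invisible(x)
}
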