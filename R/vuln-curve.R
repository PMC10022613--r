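#' Sigmoidal xylem vulnerability curve
#'
#' Constructs a vulnerability curve describing the decline of hydraulic
#' conductance with water potential,
#' \deqn{K(\Psi) = K_{max} / (1 + e^{(P50 - \Psi)/\alpha}),}
#' so that conductance falls sigmoidally as the water potential \eqn{\Psi}
#' becomes more negative, with \eqn{K(P50) = K_{max}/2} exactly.  The slope
#' parameter \eqn{\alpha} is strictly positive by this package's convention;
#' smaller values give a steeper (more threshold-like) curve.
#'
#' @param kmax Maximum hydraulic conductance at full hydration,
#'   mmol s\eqn{^{-1}} m\eqn{^{-2}} MPa\eqn{^{-1}}.  Must be positive.
#' @param p50 Water potential at 50\% loss of conductance, MPa.  Must be
#'   negative.
#' @param alpha Slope of the vulnerability curve, MPa.  Must be positive.
#' @return An object of class `vuln_curve`: a list with elements `kmax`,
#'   `p50` and `alpha`.
#' @examples
#' vc <- vuln_curve(kmax = 5.77, p50 = -3.73, alpha = 0.09)
#' conductance(vc, -3.73)   # == kmax / 2
#' plc_at_psi(vc, -3.73)    # == 50
#' @seealso [conductance()], [plc_at_psi()], [runaway_point()]
#' @export
vuln_curve <- function(kmax, p50, alpha) {
  stopifnot(is.numeric(kmax), length(kmax) == 1L, is.finite(kmax),
            is.numeric(p50), length(p50) == 1L, is.finite(p50),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (kmax <= 0) stop("'kmax' must be positive", call. = FALSE)
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  if (p50 >= 0) stop("'p50' must be negative (a water potential)", call. = FALSE)
  structure(list(kmax = kmax, p50 = p50, alpha = alpha),
            class = "vuln_curve")
}

as_vuln_curve <- function(x, ...) UseMethod("as_vuln_curve")

#' @export
as_vuln_curve.vuln_curve <- function(x, ...) x

#' @export
as_vuln_curve.list <- function(x, ...) {
  vuln_curve(kmax = if (is.null(x$kmax)) 1 else x$kmax,
             p50 = x$p50, alpha = x$alpha)
}

#' @export
print.vuln_curve <- function(x, ...) {
  cat("Sigmoidal vulnerability curve\n")
  cat(sprintf("  Kmax: %.4g mmol s-1 m-2 MPa-1\n", x$kmax))
  cat(sprintf("  P50:  %.4g MPa\n", x$p50))
  cat(sprintf("  alpha: %.4g MPa\n", x$alpha))
  invisible(x)
}

#' Hydraulic conductance at a given water potential
#'
#' Evaluates the sigmoidal vulnerability curve.  Monotone increasing in
#' `psi`; approaches `kmax` as `psi` approaches zero from below and zero as
#' the leaf dries.
#'
#' @param curve A [vuln_curve()] object.
#' @param psi Water potential, MPa.  May be a vector; all values must be
#'   finite.
#' @return Conductance, mmol s\eqn{^{-1}} m\eqn{^{-2}} MPa\eqn{^{-1}}.
#' @export
conductance <- function(curve, psi) {
  curve <- as_vuln_curve(curve)
  if (!is.numeric(psi) || any(!is.finite(psi)))
    stop("'psi' must be finite numeric", call. = FALSE)
  curve$kmax / (1 + exp((curve$p50 - psi) / curve$alpha))
}

#' Percent loss of conductance at a given water potential
#'
#' @inheritParams conductance
#' @return PLC in percent, in `[0, 100)`; 50 exactly at `psi = p50`.
#' @export
plc_at_psi <- function(curve, psi) {
  curve <- as_vuln_curve(curve)
  if (!is.numeric(psi) || any(!is.finite(psi)))
    stop("'psi' must be finite numeric", call. = FALSE)
  # 100 * (1 - K/Kmax), written to avoid cancellation at extreme psi
  100 / (1 + exp((psi - curve$p50) / curve$alpha))
}
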