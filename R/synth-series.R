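# Synthetic drydown series: psychrometer, leaf width, Fv/Fm, gmin mass
# traces, pressure-volume curves and rehydration-kinetics records.
# Every generator is deterministic under its seed.

#' Synthetic stem water potential series
#'
#' A linear drydown ramp with iid Gaussian noise, emulating a psychrometer
#' record over a multi-day bench dehydration (default: -0.5 to -6 MPa over
#' 5 days, sampled every 5 min).
#'
#' @param psi0,psi_end Start and end stem water potential, MPa
#'   (`psi0 > psi_end`).
#' @param days Duration, days.
#' @param dt_min Sampling cadence, minutes.
#' @param noise_sd Gaussian noise sd, MPa.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return Data frame with `time_min` and `psi_stem`.
#' @export
generate_psychrometer_series <- function(psi0 = -0.5, psi_end = -6,
                                         days = 5, dt_min = 5,
                                         noise_sd = 0.02, seed = NULL) {
  if (psi0 <= psi_end)
    stop("'psi0' must be wetter (less negative) than 'psi_end'",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_end <- days * 1440
  time_min <- seq(0, t_end, by = dt_min)
  psi <- psi0 + (psi_end - psi0) * time_min / t_end
  if (noise_sd > 0) psi <- psi + stats::rnorm(length(psi), sd = noise_sd)
  data.frame(time_min = time_min, psi_stem = psi)
}

#' Piecewise leaf water potential model
#'
#' Below a transition point the leaf decouples from the stem and dries
#' faster; this is the simple piecewise stand-in for the post-runaway
#' acceleration: `psi_leaf = psi_stem` above the breakpoint, and
#' `bp + multiplier * (psi_stem - bp)` below it.
#'
#' @param psi_stem Stem water potential vector, MPa.
#' @param breakpoint Transition stem water potential, MPa.
#' @param multiplier Post-breakpoint slope multiplier (default 3).
#' @return Leaf water potential vector, MPa.
#' @export
generate_psi_leaf <- function(psi_stem, breakpoint, multiplier = 3) {
  ifelse(psi_stem > breakpoint, psi_stem,
         breakpoint + multiplier * (psi_stem - breakpoint))
}

#' Synthetic leaf width series from the width-potential calibration
#'
#' Leaf width (% of full hydration) tracks leaf water potential linearly:
#' `width = slope * psi + intercept + noise`.
#'
#' @param psi_leaf Leaf water potential vector, MPa.
#' @param slope Calibration slope, percent per MPa (positive; default
#'   6.1963).
#' @param intercept Calibration intercept, percent (default 106.22).
#' @param noise_sd Gaussian noise sd, percent.
#' @param seed Integer seed.
#' @return Numeric vector of width percentages.
#' @export
generate_width_series <- function(psi_leaf, slope = 6.1963,
                                  intercept = 106.22, noise_sd = 0,
                                  seed = NULL) {
  if (slope <= 0) stop("'slope' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- slope * psi_leaf + intercept
  if (noise_sd > 0) w <- w + stats::rnorm(length(w), sd = noise_sd)
  w
}

#' Synthetic Fv/Fm series: plateau then linear collapse
#'
#' Dark-adapted quantum yield holds a healthy plateau while the stem water
#' potential stays above the breakpoint, then declines linearly to the
#' death value at `death_psi`.  With a breakpoint below the range of
#' `psi_stem` the series is flat (the well-watered control pattern).
#'
#' @param psi_stem Stem water potential vector, MPa.
#' @param breakpoint Breakpoint, MPa (default -3.53).
#' @param plateau Healthy plateau value (default 0.80).
#' @param death_value Value reached at `death_psi` (default 0.05, below the
#'   0.2 leaf-death threshold).
#' @param death_psi Water potential at which the death value is reached,
#'   MPa.
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @return Numeric vector of Fv/Fm values, clamped to `[0, 0.85]`.
#' @export
generate_fvfm_series <- function(psi_stem, breakpoint = -3.53,
                                 plateau = 0.80, death_value = 0.05,
                                 death_psi = -6, noise_sd = 0.02,
                                 seed = NULL) {
  stopifnot(plateau <= 0.85, death_value >= 0)
  # a breakpoint below the sampled range gives the flat control pattern
  if (!is.null(seed)) set.seed(seed)
  slope <- (death_value - plateau) / (death_psi - breakpoint)
  y <- ifelse(psi_stem > breakpoint, plateau,
              plateau + slope * (psi_stem - breakpoint))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
  pmin(pmax(y, 0), 0.85)
}

#' Synthetic leaf mass trace for minimum-conductance estimation
#'
#' Mass loss of a detached leaf: an initial faster (stomatal) phase whose
#' conductance decays exponentially toward `gmin`, followed by the linear
#' cuticular phase whose slope encodes the configured `gmin` through the
#' conductance formula `gmin = WL * Patm / VPD`.
#'
#' @param gmin True minimum conductance, mmol m\eqn{^{-2}} s\eqn{^{-1}}.
#' @param area_m2 Leaf area, m\eqn{^2}.
#' @param env A [leaf_environment()] (supplies VPD and pressure).
#' @param duration_min Trace length, minutes.
#' @param dt_min Weighing cadence, minutes.
#' @param stomatal_phase_min Duration scale of the stomatal phase.
#' @param stomatal_multiplier Initial conductance as a multiple of `gmin`.
#' @param mass0 Initial leaf mass, g.
#' @param noise_sd Balance noise sd, g.
#' @param seed Integer seed.
#' @return Data frame with `time_min` and `mass_g`.
#' @export
generate_gmin_trace <- function(gmin = 10.02, area_m2 = 1e-3,
                                env = leaf_environment(),
                                duration_min = 180, dt_min = 1,
                                stomatal_phase_min = 60,
                                stomatal_multiplier = 3,
                                mass0 = 1, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration_min, by = dt_min)
  tau <- stomatal_phase_min / 3
  g_t <- gmin * (1 + (stomatal_multiplier - 1) * exp(-tt / tau))
  wl <- g_t * env$vpd_kpa / env$patm_kpa           # mmol m-2 s-1
  dmdt <- -wl * area_m2 * 18.0153 / 1000 * 60      # g per minute
  mass <- mass0 + c(0, cumsum((dmdt[-1] + dmdt[-length(dmdt)]) / 2 * dt_min))
  if (noise_sd > 0) mass <- mass + stats::rnorm(length(mass), sd = noise_sd)
  data.frame(time_min = tt, mass_g = mass)
}

#' Synthetic pressure-volume curve
#'
#' Standard PV shape: osmotic potential scales inversely with symplastic
#' water content, turgor declines linearly to zero at the configured water
#' deficit, so that 1/psi against water deficit is curvilinear above the
#' turgor loss point and linear below it.  The osmotic potential at full
#' turgor is set so that the water potential at `d_tlp` equals `tlp`.
#'
#' @param tlp True turgor loss point, MPa (default -2.01).
#' @param mass_sat Saturated mass, g.
#' @param mass_dry Dry mass, g.
#' @param apoplastic_fraction Fraction of water held in the apoplast.
#' @param d_tlp Water deficit (fraction of saturated water) at turgor loss.
#' @param n Number of points.
#' @param psi_min Driest sampled water potential, MPa.
#' @param noise_sd Gaussian noise on mass, g.
#' @param seed Integer seed.
#' @return Data frame with `psi` (MPa) and `mass_g`, plus attributes
#'   `pi0` (osmotic potential at full turgor) and `d_tlp`.
#' @export
generate_pv_series <- function(tlp = -2.01, mass_sat = 1, mass_dry = 0.2,
                               apoplastic_fraction = 0.2, d_tlp = 0.12,
                               n = 20, psi_min = -4.5, noise_sd = 0,
                               seed = NULL) {
  stopifnot(tlp < 0, psi_min < tlp, d_tlp > 0, d_tlp < 1)
  if (!is.null(seed)) set.seed(seed)
  s <- 1 - apoplastic_fraction                 # symplastic fraction
  pi0 <- tlp * (s - d_tlp) / s                 # osmotic potential, full turgor
  d_max <- s * (1 - pi0 / psi_min)
  d <- seq(0.005, d_max, length.out = n)
  pi_d <- pi0 * s / (s - d)
  p0 <- -pi0 * 0.95                            # slight initial tissue tension
  turgor <- pmax(0, p0 * (1 - d / d_tlp))
  psi <- pi_d + turgor
  water <- (mass_sat - mass_dry) * (1 - d)
  mass <- mass_dry + water
  if (noise_sd > 0) mass <- mass + stats::rnorm(n, sd = noise_sd)
  out <- data.frame(psi = psi, mass_g = mass)
  attr(out, "pi0") <- pi0
  attr(out, "d_tlp") <- d_tlp
  out
}

#' Synthetic rehydration-kinetics records
#'
#' Emulates kinetic rehydration measurements of leaf hydraulic conductance:
#' leaves dehydrated to a range of initial water potentials are connected
#' to a flow meter; the peak inflow `Fmax` at `psi_init` and the flow `F2
#' = Fmax/2` at the rehydrated potential `psi_fin = psi_init/2` both imply
#' the conductance of the same vulnerability curve, so the two implied
#' values agree for clean records.
#'
#' @param kmax Plateau conductance of the generating curve (default 5.77).
#' @param x0 Inflection point of the 4-parameter sigmoid, MPa.
#' @param b Slope parameter, MPa.
#' @param y0 Offset of the 4-parameter sigmoid.
#' @param n Number of records.
#' @param psi_range Range of initial water potentials, MPa.
#' @param area_m2 Leaf area, m\eqn{^2}.
#' @param temp_c Water temperature during the measurement, degrees C.
#' @param noise_sd Relative Gaussian noise on flows.
#' @param seed Integer seed.
#' @return Data frame with `psi_init`, `psi_fin`, `fmax`, `f2` (flows,
#'   mmol s\eqn{^{-1}}), `area_m2` and `temp_c`.
#' @export
generate_rehydration_samples <- function(kmax = 5.77, x0 = -3.73, b = 0.25,
                                         y0 = 0, n = 24,
                                         psi_range = c(-5.7, -0.5),
                                         area_m2 = 1e-3, temp_c = 20,
                                         noise_sd = 0, seed = NULL) {
  stopifnot(all(psi_range < 0), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  psi_init <- seq(min(psi_range), max(psi_range), length.out = n)
  k <- y0 + (kmax - y0) / (1 + exp(-(psi_init - x0) / b))
  psi_fin <- psi_init / 2
  fmax <- k * area_m2 * abs(psi_init)
  f2 <- k * area_m2 * abs(psi_fin)
  if (noise_sd > 0) {
    fmax <- fmax * (1 + stats::rnorm(n, sd = noise_sd))
    f2 <- f2 * (1 + stats::rnorm(n, sd = noise_sd))
  }
  data.frame(psi_init = psi_init, psi_fin = psi_fin, fmax = fmax, f2 = f2,
             area_m2 = area_m2, temp_c = temp_c)
}
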