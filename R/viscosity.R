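# Molecular-rotor (FLIM) viscometry.
#
# A molecular rotor's fluorescence lifetime tau grows with solvent
# viscosity; over the 1-10 mPa*s range relevant to phloem sap the
# relationship is well described by the Foerster-Hoffmann power law
#   tau = tau_ref * eta^z,
# fit here in log-log space. Inverting a measured lifetime gives sap
# viscosity, which an aqueous-sucrose viscosity correlation converts to an
# equivalent sucrose concentration.

#' Fit a rotor calibration from (viscosity, lifetime) points
#'
#' Least-squares fit of `log(tau) = log(tau_ref) + z * log(eta)`
#' (Foerster-Hoffmann power law) to calibration measurements of lifetime at
#' known viscosities.
#'
#' @param points Data frame with columns `eta_mPas` and `tau_ns` (optional
#'   `sd_ns`, `n` are carried along but the fit is unweighted).
#' @return Object of class `rotor_calibration`: `tau_ref` (ns, lifetime at
#'   1 mPa*s), `exponent` (`z`), `exponent_se`, `residual_sd` (log scale)
#'   and `valid_range` (the data's eta range, used to flag extrapolation).
#' @examples
#' pts <- data.frame(eta_mPas = c(1, 2, 5, 10), tau_ns = 1.0 * c(1, 2, 5, 10)^0.5)
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points) {
  req <- c("eta_mPas", "tau_ns")
  if (!is.data.frame(points) || !all(req %in% names(points))) {
    schema_error("'points' must be a data frame with columns eta_mPas, tau_ns")
  }
  ok <- stats::complete.cases(points[, req])
  points <- points[ok, , drop = FALSE]
  if (length(unique(points$eta_mPas)) < 2) {
    insufficient_data("calibration needs >= 2 points with distinct viscosities")
  }
  check_positive(points$eta_mPas, "eta_mPas")
  check_positive(points$tau_ns, "tau_ns")
  fit <- stats::lm(log(tau_ns) ~ log(eta_mPas), data = points)
  cf <- stats::coef(fit)
  df_res <- fit$df.residual
  # two points (or a noiseless fit) interpolate exactly: zero residual,
  # no estimable SE; summary.lm would warn about the perfect fit
  se2 <- if (df_res > 0) {
    unname(suppressWarnings(sqrt(diag(stats::vcov(fit))))[2])
  } else NA_real_
  rsd <- if (df_res > 0) sqrt(sum(stats::residuals(fit)^2) / df_res) else 0
  structure(list(
    tau_ref = unname(exp(cf[1])),
    exponent = unname(cf[2]),
    exponent_se = se2,
    residual_sd = rsd,
    valid_range = range(points$eta_mPas),
    n_points = nrow(points)
  ), class = "rotor_calibration")
}

#' @export
print.rotor_calibration <- function(x, ...) {
  cat("Molecular-rotor calibration (Foerster-Hoffmann power law)\n")
  cat(sprintf("  tau = %.4g ns * eta^%.4g   (exponent SE %.3g)\n",
              x$tau_ref, x$exponent, x$exponent_se))
  cat(sprintf("  fitted on %d points over eta in [%.3g, %.3g] mPa*s\n",
              x$n_points, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Invert a measured lifetime to viscosity
#'
#' `eta = (tau / tau_ref)^(1/z)` from a fitted [fit_calibration()].
#' Lifetimes mapping outside the calibration's viscosity range are still
#' returned but flagged with a warning and an `"extrapolated"` attribute.
#'
#' @param tau Fluorescence lifetime(s), ns.
#' @param cal A `rotor_calibration`.
#' @return Viscosity in mPa*s (vectorised over `tau`).
#' @export
lifetime_to_viscosity <- function(tau, cal) {
  check_positive(tau, "tau")
  if (!inherits(cal, "rotor_calibration")) invalid_parameter("'cal' must be a rotor_calibration")
  eta <- (tau / cal$tau_ref)^(1 / cal$exponent)
  outside <- eta < cal$valid_range[1] | eta > cal$valid_range[2]
  if (any(outside)) {
    warning(sprintf("%d lifetime(s) invert outside the calibrated range [%.3g, %.3g] mPa*s",
                    sum(outside), cal$valid_range[1], cal$valid_range[2]))
  }
  attr(eta, "extrapolated") <- outside
  eta
}

# Pure-water dynamic viscosity, Vogel-type correlation
# eta[Pa*s] = 2.414e-5 * 10^(247.8 / (T - 140)), T in K; good to <1% over
# 273-373 K. Returned in mPa*s.
water_viscosity <- function(T_K) {
  2.414e-5 * 10^(247.8 / (T_K - 140)) * 1e3
}

SUCROSE_MOLAR_MASS <- 342.30  # g/mol
WATER_MOLAR_MASS   <- 18.015  # g/mol

#' Dynamic viscosity of aqueous sucrose
#'
#' Empirical correlation for the dynamic viscosity of an aqueous sucrose
#' solution as a function of mass fraction and temperature. The relative
#' viscosity follows the Genotelle (1978) mole-fraction correlation,
#' `log10(eta/eta_w) = 22.46*N + 43.1*phi*N^1.25` with
#' `phi = (30 - t)/(91 + t)` (t in degrees C, N the sucrose mole fraction),
#' anchored to a Vogel-type pure-water viscosity. Strictly increasing in
#' mass fraction and decreasing in temperature.
#'
#' @param mass_fraction Sucrose mass fraction w/w in `[0, 0.75]`.
#' @param T_K Temperature in K, in (273, 373).
#' @return Dynamic viscosity, mPa*s.
#' @examples
#' sucrose_viscosity(0.18, 298)  # ~1.7 mPa*s, typical phloem sap
#' @export
sucrose_viscosity <- function(mass_fraction, T_K) {
  if (!is.numeric(mass_fraction) || anyNA(mass_fraction) ||
      any(mass_fraction < 0) || any(mass_fraction > 0.75)) {
    invalid_parameter("'mass_fraction' must lie in [0, 0.75]")
  }
  if (!is.numeric(T_K) || anyNA(T_K) || any(T_K <= 273) || any(T_K >= 373)) {
    invalid_parameter("'T_K' must lie in (273, 373)")
  }
  w <- mass_fraction
  N <- (w / SUCROSE_MOLAR_MASS) /
    (w / SUCROSE_MOLAR_MASS + (1 - w) / WATER_MOLAR_MASS)
  t <- T_K - 273.15
  phi <- (30 - t) / (91 + t)
  water_viscosity(T_K) * 10^(22.46 * N + 43.1 * phi * N^1.25)
}

#' Equivalent sucrose concentration of a measured viscosity
#'
#' Numerically inverts [sucrose_viscosity()] (bracketed root find on the
#' monotone correlation) to find the sucrose mass fraction whose solution
#' has the given dynamic viscosity at temperature `T_K`.
#'
#' @param eta Dynamic viscosity, mPa*s; must be at least the pure-water
#'   viscosity at `T_K`.
#' @param T_K Temperature, K.
#' @param tol Absolute tolerance in mass fraction.
#' @return Sucrose mass fraction (w/w).
#' @examples
#' viscosity_to_sucrose(1.7, 298)  # ~0.18-0.19 w/w
#' @export
viscosity_to_sucrose <- function(eta, T_K, tol = 1e-6) {
  check_positive(eta, "eta")
  eta_w <- sucrose_viscosity(0, T_K)
  if (eta < eta_w * (1 - 1e-12)) {
    invalid_parameter(sprintf(
      "eta = %.4g mPa*s is below pure-water viscosity %.4g mPa*s at %g K",
      eta, eta_w, T_K))
  }
  if (abs(eta - eta_w) <= tol * eta_w) return(0)
  f <- function(w) sucrose_viscosity(w, T_K) - eta
  if (f(0.75) < 0) {
    invalid_parameter("eta exceeds the correlation's range (mass fraction > 0.75)")
  }
  stats::uniroot(f, c(0, 0.75), tol = tol)$root
}
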