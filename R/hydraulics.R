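# Steady-state Hagen-Poiseuille tube-flow arithmetic:
#
#   U = k * dp / (eta * L)
#
# with U the mean lumen flow velocity, dp the source-sink pressure
# differential, L the tube (transport) length, eta the sap dynamic viscosity
# and k the tube-specific conductivity (area units). k is defined against
# lumen cross-section velocity; the sieve-plate contribution is absorbed
# into k by the conductivity module.

#' Pressure differential required to drive a given flow
#'
#' Computes the source-to-sink pressure differential needed to sustain a
#' steady laminar flow of velocity `U` through a sieve tube of length `L`,
#' sap viscosity `eta` and specific conductivity `k`, from the
#' Hagen-Poiseuille relation `U = k * dp / (eta * L)`.
#'
#' @param U Flow velocity in um/s (non-negative).
#' @param eta Dynamic viscosity in mPa*s (positive).
#' @param L Tube length in m (positive).
#' @param k Tube specific conductivity in um^2 (positive).
#' @return Pressure differential in MPa. Zero velocity gives exactly zero.
#' @examples
#' required_pressure(U = 123, eta = 1.7, L = 1, k = 1) # ~0.21 MPa
#' @seealso [flow_velocity()], [max_transport_distance()]
#' @export
required_pressure <- function(U, eta, L, k) {
  check_nonnegative(U, "U")
  check_positive(eta, "eta")
  check_positive(L, "L")
  check_positive(k, "k")
  U_si   <- U * UM_PER_S_TO_M_PER_S
  eta_si <- eta * MPAS_TO_PAS
  k_si   <- k * UM2_TO_M2
  dp_si  <- U_si * eta_si * L / k_si
  dp_si / MPA_TO_PA
}

#' Maximum transport distance for an available pressure differential
#'
#' Rearranges `U = k * dp / (eta * L)` for the tube length: the longest tube
#' through which the available pressure differential `dp` can still drive
#' flow at velocity `U`.
#'
#' @param dp Available pressure differential in MPa (non-negative).
#' @param U Flow velocity in um/s (strictly positive: the distance is
#'   undefined at zero velocity).
#' @param eta Dynamic viscosity in mPa*s (positive).
#' @param k Tube specific conductivity in um^2 (positive).
#' @return Maximum tube length in m; exactly 0 when `dp` is 0.
#' @examples
#' max_transport_distance(dp = 1.61, U = 256, eta = 1.7, k = 1)   # ~3.70 m
#' max_transport_distance(dp = 1.61, U = 256, eta = 1.7, k = 5.5) # ~20.35 m
#' @export
max_transport_distance <- function(dp, U, eta, k) {
  check_nonnegative(dp, "dp")
  check_positive(U, "U")
  check_positive(eta, "eta")
  check_positive(k, "k")
  dp_si  <- dp * MPA_TO_PA
  U_si   <- U * UM_PER_S_TO_M_PER_S
  eta_si <- eta * MPAS_TO_PAS
  k_si   <- k * UM2_TO_M2
  k_si * dp_si / (U_si * eta_si)
}

#' Flow velocity from a pressure differential
#'
#' Evaluates `U = k * dp / (eta * L)`; the exact inverse of
#' [required_pressure()].
#'
#' @param dp Pressure differential in MPa (non-negative).
#' @param eta Dynamic viscosity in mPa*s (positive).
#' @param L Tube length in m (positive).
#' @param k Tube specific conductivity in um^2 (positive).
#' @return Flow velocity in um/s; exactly 0 when `dp` is 0.
#' @examples
#' flow_velocity(dp = 0.2091, eta = 1.7, L = 1, k = 1) # 123 um/s
#' @export
flow_velocity <- function(dp, eta, L, k) {
  check_nonnegative(dp, "dp")
  check_positive(eta, "eta")
  check_positive(L, "L")
  check_positive(k, "k")
  dp_si  <- dp * MPA_TO_PA
  eta_si <- eta * MPAS_TO_PAS
  k_si   <- k * UM2_TO_M2
  U_si   <- k_si * dp_si / (eta_si * L)
  U_si * M_PER_S_TO_UM_PER_S
}

#' A consistent pressure-flow scenario
#'
#' Bundles the five Hagen-Poiseuille quantities and checks that they satisfy
#' `U = k * dp / (eta * L)` to within a relative tolerance. Useful as a
#' validated record of one plant's flow state.
#'
#' @param U Flow velocity, um/s.
#' @param dp Pressure differential, MPa.
#' @param L Tube length, m.
#' @param eta Dynamic viscosity, mPa*s.
#' @param k Conductivity, um^2.
#' @param tol Relative tolerance for the consistency check.
#' @return An object of class `flow_scenario` (a named list).
#' @export
flow_scenario <- function(U, dp, L, eta, k, tol = 1e-9) {
  check_nonnegative(U, "U")
  check_nonnegative(dp, "dp")
  check_positive(L, "L")
  check_positive(eta, "eta")
  check_positive(k, "k")
  U_implied <- flow_velocity(dp, eta, L, k)
  scale <- max(abs(U), abs(U_implied), 1e-300)
  if (abs(U - U_implied) / scale > tol) {
    invalid_parameter(sprintf(
      "inconsistent flow scenario: U = %.6g um/s but k*dp/(eta*L) = %.6g um/s",
      U, U_implied
    ))
  }
  structure(list(U = U, dp = dp, L = L, eta = eta, k = k),
            class = "flow_scenario")
}

#' @export
print.flow_scenario <- function(x, ...) {
  cat("Pressure-flow scenario (Hagen-Poiseuille consistent)\n")
  cat(sprintf("  U   = %g um/s\n  dp  = %g MPa\n  L   = %g m\n", x$U, x$dp, x$L))
  cat(sprintf("  eta = %g mPa*s\n  k   = %g um^2\n", x$eta, x$k))
  invisible(x)
}
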