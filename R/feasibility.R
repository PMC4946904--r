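# Source-sink pressure feasibility: the headline test of the Muench
# pressure-flow hypothesis. Given measured source and sink turgor, sap
# viscosity, flow velocity and tube conductivity, is the available pressure
# differential sufficient to drive the observed flow over the plant's
# transport distance?
#
# Sink sieve-tube pressure cannot be measured directly; root cortical
# turgor stands in as an upper bound, valid because unloading in root tips
# is symplastic (cortical pressure cannot significantly exceed sieve-tube
# pressure). Reports label it "upper-bound sink pressure".

#' Available pressure differential from turgor samples
#'
#' Mean source turgor minus mean sink turgor. A negative differential is
#' returned (with a warning), not an error: it is a physiologically
#' meaningful finding.
#'
#' @param source,sink Numeric vectors of turgor pressures in MPa, or turgor
#'   data frames with a `pressure_MPa` column (see [gen_turgor()]).
#' @return Pressure differential, MPa.
#' @examples
#' pressure_differential(c(1.08), c(0.59))  # 0.49 MPa
#' @export
pressure_differential <- function(source, sink) {
  src <- turgor_values(source, "source")
  snk <- turgor_values(sink, "sink")
  dp <- mean(src) - mean(snk)
  if (dp < 0) warning(sprintf("negative pressure differential (%.3g MPa): sink turgor exceeds source", dp))
  dp
}

turgor_values <- function(x, what) {
  v <- if (is.data.frame(x)) {
    if (!"pressure_MPa" %in% names(x)) {
      schema_error(sprintf("%s turgor table lacks a 'pressure_MPa' column", what))
    }
    x$pressure_MPa
  } else {
    x
  }
  v <- v[!is.na(v)]
  if (length(v) == 0) insufficient_data(sprintf("no %s turgor samples", what))
  check_positive(v, sprintf("%s turgor", what))
  v
}

#' Summarise turgor samples by measurement site
#'
#' Sample mean, sample SD (n - 1) and n per site for a turgor table.
#'
#' @param samples Data frame with columns `site` and `pressure_MPa`.
#' @param group_by Grouping column, default `"site"`.
#' @param min_n Groups smaller than this are flagged.
#' @return Data frame `<group>`, `mean_MPa`, `sd_MPa`, `n`, `flag_low_n`.
#' @export
summarize_turgor <- function(samples, group_by = "site", min_n = 2) {
  if (!is.data.frame(samples) ||
      !all(c(group_by, "pressure_MPa") %in% names(samples))) {
    schema_error(sprintf("'samples' must have columns %s and pressure_MPa", group_by))
  }
  if (nrow(samples) == 0) {
    warning("empty turgor table; returning empty summary")
    out <- samples[, group_by, drop = FALSE]
    out$mean_MPa <- numeric(0); out$sd_MPa <- numeric(0)
    out$n <- integer(0); out$flag_low_n <- logical(0)
    return(out)
  }
  groups <- samples[, group_by, drop = FALSE]
  m <- stats::aggregate(samples$pressure_MPa, by = groups, FUN = mean)
  s <- stats::aggregate(samples$pressure_MPa, by = groups,
                        FUN = function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  n <- stats::aggregate(samples$pressure_MPa, by = groups, FUN = length)
  out <- m
  names(out)[names(out) == "x"] <- "mean_MPa"
  out$sd_MPa <- s$x
  out$n <- as.integer(n$x)
  out$flag_low_n <- out$n < min_n
  out[do.call(order, out[, group_by, drop = FALSE]), , drop = FALSE]
}

#' A plant's pressure-flow scenario
#'
#' Bundles the measurements feeding a feasibility assessment.
#'
#' @param source_turgors,sink_turgors Turgor pressures, MPa (numeric vectors
#'   or turgor data frames; non-empty).
#' @param transport_length Source-to-sink path length, m (helically
#'   corrected where applicable).
#' @param velocity Measured flow velocity, um/s.
#' @param viscosity Sap dynamic viscosity, mPa*s.
#' @param conductivity Tube specific conductivity, um^2.
#' @return Object of class `plant_scenario`.
#' @export
plant_scenario <- function(source_turgors, sink_turgors, transport_length,
                           velocity, viscosity, conductivity) {
  turgor_values(source_turgors, "source")
  turgor_values(sink_turgors, "sink")
  check_positive(transport_length, "transport_length")
  check_positive(velocity, "velocity")
  check_positive(viscosity, "viscosity")
  check_positive(conductivity, "conductivity")
  structure(list(source_turgors = source_turgors, sink_turgors = sink_turgors,
                 transport_length = transport_length, velocity = velocity,
                 viscosity = viscosity, conductivity = conductivity),
            class = "plant_scenario")
}

#' Muench-feasibility report for a plant scenario
#'
#' Compares the turgor-derived available pressure differential against the
#' differential required to drive the observed flow over the transport
#' distance. The two equivalent verdicts — `dp_available >= dp_required`
#' and `max_distance >= transport_length` — are both computed and must
#' agree.
#'
#' @param scenario A [plant_scenario()].
#' @return Object of class `feasibility_report`: `dp_available` and
#'   `dp_required` (MPa), `required_gradient` (MPa/m), `max_distance` (m),
#'   `feasible` (logical), `margin` (m, `max_distance - transport_length`).
#' @examples
#' sc <- plant_scenario(1.08, 0.59, transport_length = 2,
#'                      velocity = 123, viscosity = 1.7, conductivity = 1)
#' feasibility_report(sc)
#' @export
feasibility_report <- function(scenario) {
  if (!inherits(scenario, "plant_scenario")) invalid_parameter("'scenario' must be a plant_scenario")
  dp_av <- pressure_differential(scenario$source_turgors, scenario$sink_turgors)
  dp_req <- required_pressure(scenario$velocity, scenario$viscosity,
                              scenario$transport_length, scenario$conductivity)
  if (dp_av < 0) {
    # no positive driving force: flow over any distance is infeasible
    max_dist <- 0
  } else {
    max_dist <- max_transport_distance(dp_av, scenario$velocity,
                                       scenario$viscosity, scenario$conductivity)
  }
  feas_pressure <- dp_av >= dp_req
  feas_distance <- max_dist >= scenario$transport_length
  stopifnot(feas_pressure == feas_distance)  # algebraically equivalent
  structure(list(
    dp_available = dp_av,
    dp_required = dp_req,
    required_gradient = dp_req / scenario$transport_length,
    max_distance = max_dist,
    transport_length = scenario$transport_length,
    feasible = feas_pressure,
    margin = max_dist - scenario$transport_length
  ), class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(format_feasibility_report(x), sep = "\n")
  invisible(x)
}

# shared by print method and CLI text output
format_feasibility_report <- function(x) {
  c("Muench pressure-flow feasibility report",
    sprintf("  available pressure differential : %8.3f MPa (sink = upper-bound sink pressure)",
            x$dp_available),
    sprintf("  required pressure differential  : %8.3f MPa over %.3g m", x$dp_required,
            x$transport_length),
    sprintf("  required pressure gradient      : %8.3f MPa/m", x$required_gradient),
    sprintf("  maximum transport distance      : %8.2f m", x$max_distance),
    sprintf("  verdict: %s (margin %+.2f m)",
            if (x$feasible) "FEASIBLE - pressure flow can account for the observed transport"
            else "INFEASIBLE - available pressure cannot drive the observed flow",
            x$margin))
}
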