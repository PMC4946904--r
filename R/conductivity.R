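# Sieve-tube specific conductivity from measured geometry.
#
# Model: one sieve element = lumen (Hagen-Poiseuille cylinder) in series
# with one sieve plate (its pores in parallel); neighbouring elements share
# a plate, so the repeating unit chains without double counting. Each pore
# contributes Poiseuille resistance through the plate thickness plus the
# Sampson orifice (entrance/exit) resistance 3*eta/r^3. The tube-specific
# conductivity k (um^2) is defined so that the lumen cross-section velocity
# obeys U = k * dp / (eta * L); eta cancels analytically.
#
# The per-pore / per-plate calculation is a reconstruction of the standard
# serial-resistance framework for sieve-tube hydraulics; see the package
# vignette for the derivation and its assumptions.
#
# Resistances below are per unit volumetric flow in reduced units (lengths
# in um, eta in mPa*s); only ratios and the eta*L/(pi r^2 R) combination
# ever reach the user, so the reduced units cancel.

#' Set of sieve-plate pores
#'
#' Describes the pores of one sieve plate either as the full radius
#' distribution (`radii`) or as a summary (`mean_radius` + `count`), the two
#' forms in which anatomical pore data are reported.
#'
#' @param radii Numeric vector of per-pore radii in um (distribution mode).
#' @param mean_radius Mean pore radius in um (summary mode).
#' @param count Number of pores per plate (summary mode; >= 1).
#' @return An object of class `pore_set` with a `mode` field,
#'   `"distribution"` or `"summary"`.
#' @export
pore_set <- function(radii = NULL, mean_radius = NULL, count = NULL) {
  if (!is.null(radii)) {
    if (length(radii) < 1) invalid_parameter("'radii' must contain at least one pore")
    check_positive(radii, "radii")
    out <- list(mode = "distribution", radii = as.numeric(radii),
                count = length(radii))
  } else {
    if (is.null(mean_radius) || is.null(count)) {
      invalid_parameter("supply either 'radii' or both 'mean_radius' and 'count'")
    }
    check_positive(mean_radius, "mean_radius")
    if (length(count) != 1 || is.na(count) || count < 1 || count != round(count)) {
      invalid_parameter("'count' must be an integer >= 1")
    }
    out <- list(mode = "summary", mean_radius = as.numeric(mean_radius),
                count = as.integer(count))
  }
  structure(out, class = "pore_set")
}

#' Sieve plate
#'
#' @param thickness Plate thickness in um (>= 0; 0 models an infinitely thin
#'   plate whose pores still carry the Sampson orifice resistance).
#' @param pores A [pore_set()].
#' @return Object of class `sieve_plate`.
#' @export
sieve_plate <- function(thickness, pores) {
  check_nonnegative(thickness, "thickness")
  if (!inherits(pores, "pore_set")) invalid_parameter("'pores' must be a pore_set")
  structure(list(thickness = thickness, pores = pores), class = "sieve_plate")
}

#' One measured sieve element
#'
#' The atom of the conductivity calculation: lumen radius and length plus
#' the sieve plate at one end (plates are shared between neighbours, so one
#' plate per element chains correctly).
#'
#' @param lumen_radius Lumen radius, um.
#' @param length Element length, um.
#' @param plate A [sieve_plate()], or `NULL` for an open tube (no plate
#'   resistance; the Poiseuille limit).
#' @param position Distance from the stem base, m (optional metadata).
#' @param phloem_type `"internal"` or `"external"` (optional metadata).
#' @param plant_id Plant label (optional metadata).
#' @return Object of class `sieve_element`. A warning (not an error) is
#'   issued when the summed pore area exceeds the plate area
#'   `pi * lumen_radius^2`, which flags implausible measurements.
#' @export
sieve_element <- function(lumen_radius, length, plate,
                          position = NA_real_, phloem_type = NA_character_,
                          plant_id = NA_character_) {
  check_positive(lumen_radius, "lumen_radius")
  check_positive(length, "length")
  if (!is.null(plate)) {
    if (!inherits(plate, "sieve_plate")) invalid_parameter("'plate' must be a sieve_plate or NULL")
    pore_area <- if (plate$pores$mode == "distribution") {
      sum(pi * plate$pores$radii^2)
    } else {
      plate$pores$count * pi * plate$pores$mean_radius^2
    }
    if (pore_area > pi * lumen_radius^2) {
      warning(sprintf(
        "total pore area (%.3g um^2) exceeds plate area (%.3g um^2)",
        pore_area, pi * lumen_radius^2
      ))
    }
  }
  structure(list(lumen_radius = lumen_radius, length = length, plate = plate,
                 position = position, phloem_type = phloem_type,
                 plant_id = plant_id),
            class = "sieve_element")
}

#' Hydraulic resistance of a sieve-element lumen
#'
#' Hagen-Poiseuille resistance `8 * eta * length / (pi * radius^4)` of a
#' cylindrical lumen, in reduced units (lengths um, eta mPa*s).
#'
#' @param radius Lumen radius, um.
#' @param length Lumen length, um.
#' @param eta Viscosity, mPa*s (cancels in [tube_conductivity()]).
#' @return Resistance per unit volumetric flow, reduced units.
#' @export
lumen_resistance <- function(radius, length, eta = 1) {
  check_positive(radius, "radius")
  check_positive(length, "length")
  check_positive(eta, "eta")
  8 * eta * length / (pi * radius^4)
}

#' Hydraulic resistance of a single sieve-plate pore
#'
#' Poiseuille flow through the plate thickness plus the Sampson (orifice)
#' entrance/exit correction:
#' `8 * eta * thickness / (pi * r^4) + 3 * eta / r^3`.
#' At zero thickness only the Sampson term remains.
#'
#' @param pore_radius Pore radius, um.
#' @param plate_thickness Plate thickness, um (>= 0).
#' @param eta Viscosity, mPa*s.
#' @return Resistance per unit volumetric flow, reduced units.
#' @export
pore_resistance <- function(pore_radius, plate_thickness, eta = 1) {
  check_positive(pore_radius, "pore_radius")
  check_nonnegative(plate_thickness, "plate_thickness")
  check_positive(eta, "eta")
  8 * eta * plate_thickness / (pi * pore_radius^4) + 3 * eta / pore_radius^3
}

#' Hydraulic resistance of a whole sieve plate
#'
#' Pores act in parallel: `1/R_plate = sum_i 1/R_pore(r_i)` in distribution
#' mode; in summary mode all `count` pores take the mean radius, so
#' `R_plate = R_pore(mean_radius) / count`.
#'
#' @param plate A [sieve_plate()].
#' @param eta Viscosity, mPa*s.
#' @return Resistance per unit volumetric flow, reduced units.
#' @export
plate_resistance <- function(plate, eta = 1) {
  if (!inherits(plate, "sieve_plate")) invalid_parameter("'plate' must be a sieve_plate")
  p <- plate$pores
  if (p$mode == "distribution") {
    1 / sum(1 / pore_resistance(p$radii, plate$thickness, eta))
  } else {
    pore_resistance(p$mean_radius, plate$thickness, eta) / p$count
  }
}

#' Tube-specific conductivity of one sieve element
#'
#' Chains the lumen and plate resistances in series and converts to the
#' conductivity `k` of the Hagen-Poiseuille relation `U = k*dp/(eta*L)`:
#' `k = eta * length / (pi * lumen_radius^2 * (R_lumen + R_plate))`.
#' The viscosity cancels analytically, so `k` depends on geometry only.
#'
#' @param se A [sieve_element()]. An element without a plate (`plate =
#'   NULL`) gives the open-tube Poiseuille limit `k = lumen_radius^2 / 8`.
#' @param eta Viscosity used internally, mPa*s. It cancels analytically, so
#'   the result is independent of it; the argument exists to make that
#'   cancellation assertable.
#' @return Object of class `tube_conductivity` with fields `k` (um^2),
#'   `k_lumen_only` (`lumen_radius^2 / 8`, the open-tube ceiling) and
#'   `plate_resistance_fraction` (`1 - k / k_lumen_only`, the share of total
#'   resistance contributed by the plate).
#' @examples
#' ps <- pore_set(mean_radius = 0.5, count = 50)
#' se <- sieve_element(10, 300, sieve_plate(0.5, ps))
#' tube_conductivity(se)
#' @export
tube_conductivity <- function(se, eta = 1) {
  if (!inherits(se, "sieve_element")) invalid_parameter("'se' must be a sieve_element")
  check_positive(eta, "eta")
  R_lumen <- lumen_resistance(se$lumen_radius, se$length, eta)
  R_plate <- if (is.null(se$plate)) 0 else plate_resistance(se$plate, eta)
  k <- eta * se$length / (pi * se$lumen_radius^2 * (R_lumen + R_plate))
  k_open <- se$lumen_radius^2 / 8
  structure(list(
    k = k,
    k_lumen_only = k_open,
    plate_resistance_fraction = 1 - k / k_open
  ), class = "tube_conductivity")
}

#' @export
print.tube_conductivity <- function(x, ...) {
  cat(sprintf("Sieve-tube conductivity: k = %.4g um^2\n", x$k))
  cat(sprintf("  open-lumen ceiling r^2/8 = %.4g um^2; plate holds %.1f%% of resistance\n",
              x$k_lumen_only, 100 * x$plate_resistance_fraction))
  invisible(x)
}

# ---- table interface -------------------------------------------------------

DEFAULT_PLATE_THICKNESS_UM <- 0.5

#' Per-element conductivity for a geometry table
#'
#' Computes `k` for every row of an element table (schema of
#' [read_geometry()]): columns `element_id`, `plant_id`, `position_m`,
#' `phloem_type`, `se_radius_um`, `se_length_um`, `plate_thickness_um`,
#' `pore_count` and (for summary mode) `mean_pore_radius_um`. When a
#' companion per-pore table (`element_id`, `pore_radius_um`) is supplied the
#' full radius distribution is used; the two modes are never mixed within
#' one call.
#'
#' @param elements Element-level data frame.
#' @param pores Optional per-pore data frame.
#' @param mode `"auto"` (distribution when `pores` is given), or force
#'   `"distribution"` / `"summary"`.
#' @param plate_thickness_default Fallback plate thickness in um used, with
#'   a warning, for rows whose `plate_thickness_um` is missing.
#' @return The element table with columns `k_um2`, `k_lumen_only_um2` and
#'   `plate_resistance_fraction` appended.
#' @export
conductivity_table <- function(elements, pores = NULL,
                               mode = c("auto", "distribution", "summary"),
                               plate_thickness_default = DEFAULT_PLATE_THICKNESS_UM) {
  mode <- match.arg(mode)
  elements <- validate_elements(elements)
  if (mode == "auto") mode <- if (is.null(pores)) "summary" else "distribution"
  if (mode == "distribution") {
    if (is.null(pores)) schema_error("distribution mode requires a per-pore table")
    pores <- validate_pores(pores)
    missing_ids <- setdiff(elements$element_id, pores$element_id)
    if (length(missing_ids) > 0) {
      schema_error(sprintf("no pore radii for element(s): %s",
                           paste(utils::head(missing_ids, 5), collapse = ", ")))
    }
    radii_by_el <- split(pores$pore_radius_um, pores$element_id)
  } else if (!"mean_pore_radius_um" %in% names(elements)) {
    schema_error("summary mode requires a 'mean_pore_radius_um' column")
  }

  thick <- elements$plate_thickness_um
  if (anyNA(thick)) {
    warning(sprintf("plate_thickness_um missing for %d element(s); using default %.2f um",
                    sum(is.na(thick)), plate_thickness_default))
    thick[is.na(thick)] <- plate_thickness_default
  }

  res <- lapply(seq_len(nrow(elements)), function(i) {
    ps <- if (mode == "distribution") {
      pore_set(radii = radii_by_el[[as.character(elements$element_id[i])]])
    } else {
      pore_set(mean_radius = elements$mean_pore_radius_um[i],
               count = elements$pore_count[i])
    }
    se <- sieve_element(elements$se_radius_um[i], elements$se_length_um[i],
                        sieve_plate(thick[i], ps),
                        position = elements$position_m[i],
                        phloem_type = elements$phloem_type[i],
                        plant_id = elements$plant_id[i])
    tube_conductivity(se)
  })
  elements$k_um2 <- vapply(res, `[[`, numeric(1), "k")
  elements$k_lumen_only_um2 <- vapply(res, `[[`, numeric(1), "k_lumen_only")
  elements$plate_resistance_fraction <-
    vapply(res, `[[`, numeric(1), "plate_resistance_fraction")
  attr(elements, "conductivity_mode") <- mode
  elements
}

#' Aggregate per-tube conductivities into group means
#'
#' Groups per-element conductivities (from [conductivity_table()]) by stem
#' position and/or phloem type and reports the sample mean, sample SD
#' (n - 1 denominator) and n per group, the form in which anatomical
#' conductivity profiles are presented.
#'
#' @param ktab Output of [conductivity_table()] (or any data frame with a
#'   `k_um2` column and the grouping columns).
#' @param group_by Character vector of grouping columns, any of
#'   `"position_m"`, `"phloem_type"`, `"plant_id"`.
#' @param min_n Groups with fewer elements than this are flagged
#'   (`flag_low_n`), not dropped.
#' @return Data frame with columns `<groups>`, `mean_k_um2`, `sd_k_um2`,
#'   `n`, `flag_low_n`. Empty input yields an empty table with a warning.
#' @export
aggregate_conductivity <- function(ktab,
                                   group_by = c("position_m", "phloem_type"),
                                   min_n = 2) {
  if (!"k_um2" %in% names(ktab)) {
    schema_error("'ktab' lacks a k_um2 column; run conductivity_table() first")
  }
  bad <- setdiff(group_by, names(ktab))
  if (length(bad) > 0) schema_error(sprintf("unknown grouping column(s): %s",
                                            paste(bad, collapse = ", ")))
  if (nrow(ktab) == 0) {
    warning("empty conductivity table; returning empty aggregate")
    out <- ktab[, group_by, drop = FALSE]
    out$mean_k_um2 <- numeric(0); out$sd_k_um2 <- numeric(0)
    out$n <- integer(0); out$flag_low_n <- logical(0)
    return(out)
  }
  groups <- ktab[, group_by, drop = FALSE]
  agg_mean <- stats::aggregate(ktab$k_um2, by = groups, FUN = mean)
  agg_sd   <- stats::aggregate(ktab$k_um2, by = groups,
                               FUN = function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  agg_n    <- stats::aggregate(ktab$k_um2, by = groups, FUN = length)
  out <- agg_mean
  names(out)[names(out) == "x"] <- "mean_k_um2"
  out$sd_k_um2 <- agg_sd$x
  out$n <- as.integer(agg_n$x)
  out$flag_low_n <- out$n < min_n
  out[do.call(order, out[group_by]), , drop = FALSE]
}
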