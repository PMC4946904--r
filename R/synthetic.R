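# Seeded synthetic-data generation for every input the pipeline consumes:
# geometry tables, turgor samples, rotor calibration points and tracer
# detector traces. Each generator takes an explicit seed and restores the
# caller's RNG state, so the streams are independent: adding one generator
# call never perturbs another's output.
#
# Distribution families: truncated normal (at zero) for sieve-element
# radius/length/plate thickness and pore count (rounded, >= 1); lognormal
# for pore radius, which is strictly positive and right-skewed in measured
# plates. Fields are drawn independently; real covariances among radius,
# length and pore geometry are not emulated (see the vignette).

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    config_error("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# truncated normal on (0, Inf) by rejection; exact for sd = 0
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

# lognormal parameterised by arithmetic mean and sd
rlnorm_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

GEOMETRY_FIELDS <- c("se_radius", "se_length", "plate_thickness",
                     "pore_count", "pore_radius")

#' Configuration for the synthetic geometry generator
#'
#' One row of `cells` per (position, phloem type) combination, holding the
#' distribution parameters for that sampling point. Required columns:
#' `position_m`, `phloem_type`, `n_se`, and `<field>_mean` / `<field>_sd`
#' for each of `se_radius`, `se_length`, `plate_thickness` (um),
#' `pore_count` and `pore_radius` (um).
#'
#' @param cells Data frame of per-cell distribution parameters.
#' @param plant_id Plant label stamped on the generated tables.
#' @param families Named list mapping fields to `"tnorm"` (zero-truncated
#'   normal) or `"lnorm"`; defaults follow the shapes typical of anatomical
#'   data (lognormal pore radii, truncated normal otherwise).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(cells, plant_id = "synthetic",
                             families = list(pore_radius = "lnorm")) {
  need <- c("position_m", "phloem_type", "n_se",
            paste0(rep(GEOMETRY_FIELDS, each = 2), c("_mean", "_sd")))
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0) {
    config_error(sprintf("config 'cells' lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  for (f in GEOMETRY_FIELDS) {
    m <- cells[[paste0(f, "_mean")]]
    s <- cells[[paste0(f, "_sd")]]
    if (any(!is.finite(m)) || any(m <= 0)) {
      config_error(sprintf("'%s_mean' must be strictly positive", f))
    }
    if (any(!is.finite(s)) || any(s < 0)) {
      config_error(sprintf("'%s_sd' must be non-negative", f))
    }
  }
  if (any(cells$n_se < 1)) config_error("'n_se' must be >= 1")
  fam <- list(se_radius = "tnorm", se_length = "tnorm",
              plate_thickness = "tnorm", pore_count = "tnorm",
              pore_radius = "lnorm")
  fam[names(families)] <- families
  bad_fam <- setdiff(unlist(fam), c("tnorm", "lnorm"))
  if (length(bad_fam) > 0) config_error("distribution families must be 'tnorm' or 'lnorm'")
  structure(list(cells = cells, plant_id = plant_id, families = fam),
            class = "synthetic_config")
}

draw_field <- function(n, mean, sd, family) {
  switch(family, tnorm = rtnorm_pos(n, mean, sd), lnorm = rlnorm_ms(n, mean, sd))
}

#' Generate a synthetic sieve-tube geometry table
#'
#' Draws, per configured (position, phloem type) cell, `n_se` sieve
#' elements: radius, length and plate thickness from their configured
#' distributions; a pore count per plate (rounded, minimum 1); then that
#' many per-pore radii. Output conforms exactly to the schema consumed by
#' [conductivity_table()] / [read_geometry()].
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; identical (config, seed) pairs give identical
#'   tables.
#' @return List with data frames `elements` and `pores`.
#' @export
gen_geometry <- function(config, seed) {
  if (!inherits(config, "synthetic_config")) config_error("'config' must be a synthetic_config")
  with_seed(seed, {
    el_list <- list()
    pore_list <- list()
    eid <- 0L
    for (i in seq_len(nrow(config$cells))) {
      cell <- config$cells[i, ]
      n <- cell$n_se
      draw <- function(f) {
        draw_field(n, cell[[paste0(f, "_mean")]], cell[[paste0(f, "_sd")]],
                   config$families[[f]])
      }
      radius <- draw("se_radius")
      len <- draw("se_length")
      thick <- draw("plate_thickness")
      count <- pmax(1L, as.integer(round(draw("pore_count"))))
      ids <- eid + seq_len(n)
      eid <- eid + n
      pr_mean <- numeric(n)
      for (j in seq_len(n)) {
        radii <- draw_field(count[j], cell$pore_radius_mean, cell$pore_radius_sd,
                            config$families$pore_radius)
        pr_mean[j] <- mean(radii)
        pore_list[[length(pore_list) + 1L]] <- data.frame(
          element_id = ids[j], pore_radius_um = radii)
      }
      el_list[[i]] <- data.frame(
        element_id = ids,
        plant_id = config$plant_id,
        position_m = cell$position_m,
        phloem_type = cell$phloem_type,
        se_radius_um = radius,
        se_length_um = len,
        plate_thickness_um = thick,
        pore_count = count,
        mean_pore_radius_um = pr_mean
      )
    }
    list(elements = do.call(rbind, el_list),
         pores = do.call(rbind, pore_list))
  })
}

#' Generate synthetic turgor-pressure samples
#'
#' Zero-truncated normal draws of in-situ turgor measurements.
#'
#' @param mean,sd Mean and SD of turgor, MPa.
#' @param n Number of samples (>= 1).
#' @param site Measurement site label, e.g. `"source_leaf"` or
#'   `"root_cortex"`.
#' @param seed Integer seed.
#' @param plant_id Plant label.
#' @param position_m Measurement position metadata (recycled).
#' @param match_moments If `TRUE`, affinely rescale the draws so the sample
#'   mean and SD equal `mean` and `sd` exactly — the convention for
#'   reconstructing raw values behind a reported "mean (+/- SD, n)".
#' @return Data frame `site`, `pressure_MPa`, `plant_id`, `position_m`.
#' @export
gen_turgor <- function(mean, sd, n, site, seed, plant_id = "synthetic",
                       position_m = NA_real_, match_moments = FALSE) {
  check_positive(mean, "mean")
  check_nonnegative(sd, "sd")
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    config_error("'n' must be >= 1")
  }
  p <- with_seed(seed, rtnorm_pos(n, mean, sd))
  if (match_moments) {
    p <- if (n == 1 || sd == 0) rep(mean, n)
         else mean + (p - base::mean(p)) * sd / stats::sd(p)
    if (any(p <= 0)) estimation_error("moment matching produced non-positive turgor; lower sd")
  }
  data.frame(site = site, pressure_MPa = p, plant_id = plant_id,
             position_m = position_m)
}

#' Generate synthetic rotor calibration points
#'
#' Simulates replicate lifetime measurements at each viscosity standard
#' under the Foerster-Hoffmann law `tau = tau_ref * eta^exponent` with
#' lognormal measurement noise of SD `sigma_logtau` on the log-lifetime,
#' then reports per-standard mean, SD and n — the format of a published
#' calibration curve.
#'
#' @param tau_ref Lifetime at 1 mPa*s, ns.
#' @param exponent Power-law exponent (> 0).
#' @param sigma_logtau Noise SD on log(tau); 0 gives exact power-law points.
#' @param etas Viscosity standards, mPa*s.
#' @param seed Integer seed.
#' @param n_rep Replicates per standard.
#' @return Data frame `eta_mPas`, `tau_ns`, `sd_ns`, `n`.
#' @export
gen_calibration <- function(tau_ref, exponent, sigma_logtau, etas, seed,
                            n_rep = 21) {
  check_positive(tau_ref, "tau_ref")
  check_positive(exponent, "exponent")
  check_nonnegative(sigma_logtau, "sigma_logtau")
  check_positive(etas, "etas")
  if (n_rep < 1) config_error("'n_rep' must be >= 1")
  with_seed(seed, {
    rows <- lapply(etas, function(e) {
      tau <- tau_ref * e^exponent * exp(stats::rnorm(n_rep, 0, sigma_logtau))
      data.frame(eta_mPas = e, tau_ns = mean(tau),
                 sd_ns = if (n_rep > 1) stats::sd(tau) else 0, n = n_rep)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic tracer detector-trace pair
#'
#' A Gaussian tracer pulse advected at constant velocity past two
#' collimated stem detectors; counts are Poisson with a flat background.
#' The peak signal amplitude is `snr^2` counts, so the counting noise at
#' the peak is about `snr` and the peak signal-to-noise ratio is `snr`.
#' `snr = Inf` disables noise (exact Gaussian pulses).
#'
#' @param velocity True flow velocity, um/s.
#' @param detector_positions Two detector locations along the stem, m
#'   (increasing; tracer released at `release_position`).
#' @param pulse_sigma Temporal width (SD) of the pulse at the detectors, s.
#' @param snr Peak signal-to-noise ratio (>= 1, or `Inf`).
#' @param seed Integer seed.
#' @param dt Sampling interval, s.
#' @param release_position Tracer application point, m.
#' @param baseline Background count rate per sample.
#' @return List of two [detector_trace()] objects, `upstream` and
#'   `downstream`.
#' @export
gen_traces <- function(velocity, detector_positions, pulse_sigma, snr, seed,
                       dt = 10, release_position = 0, baseline = 5) {
  check_positive(velocity, "velocity")
  if (length(detector_positions) != 2 || diff(detector_positions) <= 0) {
    config_error("'detector_positions' must be two increasing positions (m)")
  }
  if (any(detector_positions <= release_position)) {
    config_error("detectors must lie downstream of 'release_position'")
  }
  check_positive(pulse_sigma, "pulse_sigma")
  if (!(is.infinite(snr) || snr >= 1)) config_error("'snr' must be >= 1 (or Inf)")
  v_mps <- velocity * UM_PER_S_TO_M_PER_S
  centers <- (detector_positions - release_position) / v_mps
  times <- seq(0, max(centers) + 6 * pulse_sigma, by = dt)
  amplitude <- if (is.infinite(snr)) 100 else snr^2
  with_seed(seed, {
    traces <- lapply(seq_along(centers), function(i) {
      lambda <- baseline + amplitude * exp(-(times - centers[i])^2 / (2 * pulse_sigma^2))
      counts <- if (is.infinite(snr)) lambda else stats::rpois(length(lambda), lambda)
      detector_trace(detector_positions[i], times, counts)
    })
    names(traces) <- c("upstream", "downstream")
    traces
  })
}

#' Preset geometry configurations for the two study regimes
#'
#' Named [synthetic_config()] objects whose aggregate conductivities land
#' on the two headline regimes of morning-glory sieve-tube anatomy:
#' `"foliated_external"` (fully foliated plant, external phloem,
#' mean k near 1 um^2) and `"defoliated_external"` (long partially
#' defoliated plant, larger pores, mean k near 5.5 um^2 — a 5-to-6 fold
#' increase). Each config carries its nominal conductivity as attribute
#' `target_k_um2`.
#'
#' @param n_se Sieve elements per (position, phloem type) cell; the default
#'   matches the anatomical sampling depth of >= 10 per data point.
#' @return Named list of `synthetic_config` objects.
#' @export
geometry_presets <- function(n_se = 10) {
  make_cells <- function(positions, radius, len, thick, count, pore_r) {
    data.frame(
      position_m = positions, phloem_type = "external", n_se = n_se,
      se_radius_mean = radius, se_radius_sd = 0.1 * radius,
      se_length_mean = len, se_length_sd = 0.1 * len,
      plate_thickness_mean = thick, plate_thickness_sd = 0.1 * thick,
      pore_count_mean = count, pore_count_sd = 0.1 * count,
      pore_radius_mean = pore_r, pore_radius_sd = 0.15 * pore_r
    )
  }
  foliated <- synthetic_config(
    make_cells(c(1, 4, 7), radius = 10, len = 300, thick = 0.5,
               count = 50, pore_r = 0.489),
    plant_id = "foliated_7.5m"
  )
  attr(foliated, "target_k_um2") <- 1.0
  defoliated <- synthetic_config(
    make_cells(c(1, 5, 9, 13), radius = 12, len = 350, thick = 0.5,
               count = 45, pore_r = 0.975),
    plant_id = "defoliated_17.5m"
  )
  attr(defoliated, "target_k_um2") <- 5.5
  list(foliated_external = foliated, defoliated_external = defoliated)
}
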