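small_cells <- function(n_se = 5) {
  data.frame(
    position_m = c(1, 4), phloem_type = "external", n_se = n_se,
    se_radius_mean = 10, se_radius_sd = 1,
    se_length_mean = 300, se_length_sd = 30,
    plate_thickness_mean = 0.5, plate_thickness_sd = 0.05,
    pore_count_mean = 30, pore_count_sd = 3,
    pore_radius_mean = 0.5, pore_radius_sd = 0.075
  )
}

test_that("the geometry generator is deterministic in (config, seed)", {
  cfg <- synthetic_config(small_cells())
  g1 <- gen_geometry(cfg, seed = 10)
  g2 <- gen_geometry(cfg, seed = 10)
  expect_identical(g1, g2)
  g3 <- gen_geometry(cfg, seed = 11)
  expect_false(identical(g1$elements$se_radius_um, g3$elements$se_radius_um))
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_geometry(synthetic_config(small_cells()), seed = 4))
  invisible(gen_turgor(1, 0.1, 5, "source_leaf", seed = 5))
  expect_identical(.Random.seed, before)
  # so interleaving a generator call does not perturb the caller's draws
  set.seed(123)
  a <- runif(3)
  set.seed(123)
  invisible(gen_traces(123, c(0.5, 1), 120, 10, seed = 6))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("large samples recover the configured means for every field", {
  cells <- small_cells(n_se = 5000)[1, , drop = FALSE]
  g <- gen_geometry(synthetic_config(cells), seed = 42)
  el <- g$elements
  checks <- list(
    c(mean = 10, sd = 1, field = "se_radius_um"),
    c(mean = 300, sd = 30, field = "se_length_um"),
    c(mean = 0.5, sd = 0.05, field = "plate_thickness_um")
  )
  for (ch in checks) {
    m <- as.numeric(ch["mean"]); s <- as.numeric(ch["sd"])
    expect_lt(abs(mean(el[[ch["field"]]]) - m), 3 * s / sqrt(nrow(el)))
  }
  expect_lt(abs(mean(el$pore_count) - 30), 3 * 3 / sqrt(nrow(el)))
  expect_lt(abs(mean(g$pores$pore_radius_um) - 0.5),
            3 * 0.075 / sqrt(nrow(g$pores)))
})

test_that("zero spread collapses the generator to identical records", {
  cells <- small_cells()
  for (f in phloemflow:::GEOMETRY_FIELDS) cells[[paste0(f, "_sd")]] <- 0
  g <- gen_geometry(synthetic_config(cells), seed = 1)
  expect_equal(length(unique(g$elements$se_radius_um)), 1)
  expect_equal(length(unique(g$pores$pore_radius_um)), 1)
  kt <- conductivity_table(g$elements, g$pores)
  agg <- aggregate_conductivity(kt)
  expect_equal(agg$sd_k_um2, rep(0, nrow(agg)), tolerance = 1e-12)
})

test_that("invalid configurations are rejected with a config error", {
  cells <- small_cells(); cells$se_radius_mean <- -1
  expect_error(synthetic_config(cells), class = "phloemflow_config_error")
  cells <- small_cells(); cells$pore_radius_sd <- -0.1
  expect_error(synthetic_config(cells), class = "phloemflow_config_error")
  cells <- small_cells(); cells$n_se <- 0
  expect_error(synthetic_config(cells), class = "phloemflow_config_error")
  expect_error(synthetic_config(small_cells()[, -1]),
               class = "phloemflow_config_error")
})

test_that("turgor generation is seeded, truncated and moment-matchable", {
  t1 <- gen_turgor(1.08, 0.13, 5, "source_leaf", seed = 9)
  expect_identical(t1, gen_turgor(1.08, 0.13, 5, "source_leaf", seed = 9))
  expect_true(all(t1$pressure_MPa > 0))
  expect_equal(nrow(gen_turgor(0.59, 0.11, 1, "root_cortex", seed = 2)), 1)
  big <- gen_turgor(1.08, 0.13, 1e5, "source_leaf", seed = 3)
  expect_equal(mean(big$pressure_MPa), 1.08, tolerance = 0.005)
  expect_equal(sd(big$pressure_MPa), 0.13, tolerance = 0.01)
  mm <- gen_turgor(1.08, 0.13, 5, "source_leaf", seed = 4, match_moments = TRUE)
  expect_equal(mean(mm$pressure_MPa), 1.08, tolerance = 1e-12)
  expect_equal(sd(mm$pressure_MPa), 0.13, tolerance = 1e-12)
  expect_error(gen_turgor(1, 0.1, 0, "source_leaf", seed = 1),
               class = "phloemflow_config_error")
})

test_that("calibration generation reduces to the exact law at zero noise", {
  pts <- gen_calibration(1.05, 0.45, sigma_logtau = 0, etas = c(1, 2, 5, 10),
                         seed = 1)
  expect_equal(pts$tau_ns, 1.05 * c(1, 2, 5, 10)^0.45, tolerance = 1e-12)
  expect_equal(pts$sd_ns, rep(0, 4), tolerance = 1e-12)
  expect_identical(pts, gen_calibration(1.05, 0.45, 0, c(1, 2, 5, 10), seed = 2))
  n1 <- gen_calibration(1.05, 0.45, 0.02, c(1, 5), seed = 7)
  expect_identical(n1, gen_calibration(1.05, 0.45, 0.02, c(1, 5), seed = 7))
})

test_that("noise-free traces give the exact transit; noisy ones are seeded", {
  tr <- gen_traces(200, c(0.4, 1.2), pulse_sigma = 60, snr = Inf, seed = 1)
  tt <- transit_time(tr$upstream, tr$downstream, method = "peak")
  expect_equal(tt, 0.8 / 200e-6, tolerance = 1e-3)
  n1 <- gen_traces(200, c(0.4, 1.2), 60, 10, seed = 5)
  n2 <- gen_traces(200, c(0.4, 1.2), 60, 10, seed = 5)
  expect_identical(n1, n2)
  expect_error(gen_traces(200, c(1.2, 0.4), 60, 10, seed = 1),
               class = "phloemflow_config_error")
})

test_that("presets load, are seekable and approach their nominal k with n", {
  presets <- geometry_presets()
  expect_setequal(names(presets), c("foliated_external", "defoliated_external"))
  for (p in presets) expect_s3_class(p, "synthetic_config")
  target <- attr(presets$foliated_external, "target_k_um2")
  expect_equal(target, 1.0)
  expect_equal(attr(presets$defoliated_external, "target_k_um2"), 5.5)
  # estimate of mean k tightens toward the nominal value as n grows
  err <- sapply(c(10, 100, 1000), function(n) {
    cfg <- geometry_presets(n_se = ceiling(n / 3))[["foliated_external"]]
    g <- gen_geometry(cfg, seed = 7)
    abs(mean(conductivity_table(g$elements, g$pores)$k_um2) - target)
  })
  expect_lt(err[3], 0.1 * target)
})
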