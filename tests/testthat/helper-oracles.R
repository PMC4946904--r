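# Independent oracles and small utilities shared across the suite.

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Explicit resistor-network oracle for tube conductivity, kept deliberately
# naive and independent of the package's closed-form path: chain m sieve
# elements, each a lumen resistor in series with a plate whose pore
# resistors are accumulated one by one as parallel conductances, then read
# k off the whole chain (total length / total resistance). The per-length
# normalisation must make the result independent of m.
oracle_tube_k <- function(lumen_radius, length, thickness, pore_radii,
                          m = 3, eta = 1.3) {
  R_total <- 0
  for (el in seq_len(m)) {
    R_lumen <- 8 * eta * length / (pi * lumen_radius^4)
    G_plate <- 0
    for (r in pore_radii) {
      R_pore <- 8 * eta * thickness / (pi * r^4) + 3 * eta / r^3
      G_plate <- G_plate + 1 / R_pore
    }
    R_total <- R_total + R_lumen + 1 / G_plate
  }
  L_total <- m * length
  # U = Q / (pi r^2) = dp / (pi r^2 R_total); U = k dp / (eta L_total)
  eta * L_total / (pi * lumen_radius^2 * R_total)
}

# Random valid sieve-element geometry for property tests (caller seeds).
random_geometry <- function() {
  list(
    lumen_radius = stats::runif(1, 4, 15),
    length = stats::runif(1, 100, 500),
    thickness = stats::runif(1, 0.1, 2),
    pore_radii = stats::runif(sample(3:60, 1), 0.2, 1.5)
  )
}

se_from_geometry <- function(g) {
  # random draws may exceed the plate-area plausibility bound; that warning
  # is under test elsewhere and irrelevant to these properties
  suppressWarnings(
    sieve_element(g$lumen_radius, g$length,
                  sieve_plate(g$thickness, pore_set(radii = g$pore_radii)))
  )
}
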