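---
title: "Sieve-tube hydraulics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sieve-tube hydraulics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phloemflow)
```

## The question the package answers

The Münch (pressure-flow) hypothesis holds that phloem transport is bulk
laminar flow driven by an osmotically generated pressure difference between
source tissue (mature leaves) and sink tissue (roots, growing tips), with no
energy input along the path. Whether that is quantitatively tenable in a
real plant comes down to five numbers linked by steady-state
Hagen–Poiseuille flow:

$$ U = \frac{k\,\Delta p}{\eta\, L} $$

with $U$ the flow velocity (µm/s), $\Delta p$ the source–sink pressure
differential (MPa), $L$ the tube length (m), $\eta$ the sap dynamic
viscosity (mPa·s) and $k$ the tube-specific conductivity (µm²). Each module
of this package measures, models or combines one of these quantities; the
feasibility report compares the pressure a plant has against the pressure
its observed flow needs.

All user-facing units are the field's customary ones, listed above.
Internally every computation runs in SI; the conversion constants are
defined once (`R/units.R`), and the test suite asserts that the two routes
agree to 1e-12 relative. Zero velocity and zero pressure are physically
meaningful limits and return exact zeros; zero denominators (viscosity,
length, conductivity, velocity in the distance rearrangement) raise classed
errors naming the offending argument.

## Conductivity from anatomy: a reconstructed resistance model

Sieve tubes are chains of cylindrical sieve elements separated by
perforated end walls (sieve plates). The package computes the tube-specific
conductivity of one element as a serial hydraulic circuit:

* lumen: Hagen–Poiseuille, $R_\text{lumen} = 8\eta\ell / (\pi r^4)$;
* plate: its pores in parallel, each pore contributing Poiseuille flow
  through the plate thickness plus the Sampson orifice (entrance/exit)
  term, $R_\text{pore} = 8\eta t/(\pi r_p^4) + 3\eta/r_p^3$.

One plate is assigned per element end and shared between neighbours, so the
repeating series unit (lumen + one plate) chains over any number of
elements without double counting — the test suite checks the closed form
against an explicit resistor-network oracle built element by element, and
checks that the per-length normalisation is independent of the chain
length. Compound plates are handled by pooling all pores of one junction
into a single pore set; plate inclination is not modelled geometrically,
since its physiological effect (more plate area, larger pores) is already
present in measured pore data.

The conductivity referenced to lumen cross-section velocity is

$$ k = \frac{\eta\,\ell}{\pi r^2 (R_\text{lumen} + R_\text{plate})}, $$

in which $\eta$ cancels analytically; `tube_conductivity()` exposes an
`eta` argument purely so that cancellation can be asserted. Two bounds
follow directly: $k \le r^2/8$ (the open-tube Poiseuille ceiling, attained
exactly when the plate is absent), and $k$ grows with pore radius and pore
count and shrinks with plate thickness. Note that $k$ is *not* monotone in
the lumen radius itself: writing
$k = \ell / (8\ell/r^2 + \pi R_\text{plate} r^2)$ shows it rises with $r$
while the lumen dominates the resistance and falls with $r$ once the plate
dominates, because widening the lumen dilutes the velocity at plate-limited
volumetric flow. The property tests therefore assert lumen-radius
monotonicity only on the lumen-dominated branch.

This serial-resistance formulation is a reconstruction of the standard
framework for sieve-tube hydraulic resistance; the anatomical inputs it
consumes (element radius and length, plate thickness, pore count, pore
radii) are exactly the quantities measured from SEM and confocal images.

**Distribution vs summary pore data.** When per-pore radii are available
the plate conductance sums each pore individually (distribution mode);
figure-level data often report only a mean radius and count (summary mode).
Because pore conductance scales like $r_p^3$–$r_p^4$, Jensen's inequality
makes the distribution-mode conductivity at least the summary-mode value
for any non-degenerate radius spread; both modes are implemented, never
silently mixed within one call, and reported side by side where useful.
Plate thickness is rarely printed in anatomical tables; when missing it
falls back to a configurable default of 0.5 µm with a warning.

Group summaries (`aggregate_conductivity()`) report the sample mean and the
$n-1$ sample SD; the estimator behind published "error bars show standard
deviation" captions is not stated, and $n-1$ is the conventional choice.

## Viscometry: molecular rotor plus a sucrose correlation

A molecular rotor is a fluorophore whose nonradiative decay accelerates in
low-viscosity solvents, so its fluorescence lifetime reports local
viscosity. Over the 1–10 mPa·s range relevant to phloem sap the
lifetime–viscosity relationship is well described by the Förster–Hoffmann
power law $\tau = \tau_\text{ref}\,\eta^z$, which `fit_calibration()` fits
by least squares in log–log space. The published calibration curves for
such rotors are figures, not tables, so the functional form here is a
design choice; the fitting interface accepts arbitrary user-supplied
calibration points, so a digitized curve can be substituted directly.
Lifetimes that invert outside the calibrated viscosity range are returned
but flagged, never refused. A fit through exactly two points interpolates
with zero residual and no estimable slope SE (reported as `NA`).

To express a sap viscosity as an equivalent sucrose concentration,
`sucrose_viscosity()` implements the Génotelle (1978) empirical correlation
in sucrose mole fraction $N$,

$$ \log_{10}\frac{\eta}{\eta_w(T)} = 22.46\,N + 43.1\,\phi\,N^{1.25},
\qquad \phi = \frac{30 - t}{91 + t}, $$

($t$ in °C) anchored to a Vogel-type pure-water viscosity
$\eta_w = 2.414\times10^{-5}\cdot10^{247.8/(T-140)}$ Pa·s. At 298 K this
reproduces pure water within 0.5% and is strictly increasing in mass
fraction and decreasing in temperature over its stated domain (mass
fraction 0–0.75, 273–373 K). `viscosity_to_sucrose()` inverts it by
bracketed root finding to 1e-6 in mass fraction:

```{r sucrose}
sucrose_viscosity(0.18, 298)        # ~1.7 mPa*s
100 * viscosity_to_sucrose(1.7, 298)  # % w/w
```

A measured sap viscosity of 1.7 mPa·s at 298 K thus corresponds to roughly
18–19% w/w sucrose. The mapping from a specific mean lifetime to 1.7 mPa·s
depends on the rotor calibration actually used and is reproduced here only
conditionally on a calibration passing through that point.

## Tracer velocimetry

A short ¹¹CO₂ pulse fixed in a source leaf travels with the sap past two
collimated stem detectors; velocity is detector separation divided by the
transit time of the count-rate pulse. Which arrival feature defines
"transit" is a free choice; the package implements three and defaults to
the peak:

* **peak** — Gaussian-smoothed argmax with three-point parabolic
  refinement (robust to counting noise, unbiased for symmetric pulses);
* **half_rise** — first crossing of half the smoothed maximum (earlier,
  robust to tail asymmetry);
* **centroid** — baseline-subtracted temporal first moment.

All features operate on baseline-subtracted counts (20th-percentile
baseline), making them invariant to uniform count scaling and constant
background offsets. Decay correction with the ¹¹C half-life is unnecessary
for shift-based lag estimation and is not applied. Detector separation is
always an explicit input. The synthetic-trace recovery tests show median
velocity error under 5% at a peak signal-to-noise ratio of 10 over 100
seeded replicates.

## The feasibility report

`feasibility_report()` combines everything: the available differential is
the mean source turgor minus the mean sink turgor; the required
differential is `required_pressure(U, eta, L, k)`; and the same algebra
rearranged gives the maximum distance the available pressure could drive
the observed flow. The two verdict criteria — pressure sufficiency and
distance sufficiency — are algebraically equivalent, and the report
computes both and asserts their agreement. Sink sieve-tube pressure cannot
be probed directly; root cortical turgor stands in as an upper bound (valid
because unloading in root tips is symplastic), and the report labels it as
such. Where a source pressure is reported only as "more than" a value, the
point value is used, which is conservative for feasibility.

```{r feasibility}
feasibility_report(plant_scenario(
  source_turgors = 1.08, sink_turgors = 0.59,
  transport_length = 2, velocity = 123, viscosity = 1.7, conductivity = 1))
```

## What the synthetic generator emulates — and what it does not

`gen_geometry()`, `gen_turgor()`, `gen_calibration()` and `gen_traces()`
produce every input table the pipeline reads, with the statistical
structure the analysis assumes: per-(position, phloem-type) distributions
for the five geometry fields, zero-truncated normal turgor samples,
power-law calibration points with lognormal lifetime noise, and
Poisson-noised Gaussian tracer pulses. Defaults mirror realistic sampling
depth for this kind of anatomy (≥ 10 sieve elements and plates per data
point, hundreds of pores per point, n = 3–5 for velocity and turgor).
Pore radii default to a lognormal family (strictly positive, right-skewed,
as measured pore data are); element radius, length, plate thickness and
pore count default to zero-truncated normals. Every generator takes an
explicit integer seed, restores the caller's RNG state, and is
byte-reproducible from (config, seed).

`gen_turgor(match_moments = TRUE)` affinely rescales a draw so its sample
mean and SD equal the requested values exactly — the right construction
when reconstructing raw values behind a published "mean (± SD, n)".

Two presets (`geometry_presets()`) pin the generator to the two regimes the
anatomy of a climbing morning glory spans: a fully foliated plant whose
external phloem has mean k near 1 µm², and a long partially defoliated
plant whose larger pores raise mean k about 5.5-fold. The preset pore
radii (0.489 and 0.975 µm) were chosen analytically so that the *expected*
mean conductivity under the lognormal pore-radius spread (which inflates
mean pore conductance by roughly $e^{a(a-1)\sigma_{\log}^2/2}$ with
$a \approx 3.5$) lands on the nominal values; Monte-Carlo means at
n ≈ 1000 elements fall within 1–2% of the targets.

Limitations worth keeping in mind when extrapolating from passing tests to
real data: fields are drawn independently, whereas real element radius,
length and pore geometry covary; pore radii are pooled rather than
hierarchically clustered by plate (an optional structure real plates do
show); tracer pulses are symmetric Gaussians, whereas real loading and
dispersion skew them (the half-rise and centroid methods respond to such
asymmetry differently than the peak); and no imaging noise, segmentation
error or detector dead time is simulated.

## Numerical choices and problem sizes

* Root finding for the sucrose inversion: bracketed `uniroot` on
  [0, 0.75] mass fraction, tolerance 1e-6.
* Oracle equivalence and property suites run on hundreds of randomized
  small instances under fixed seeds; the resistor-network oracle tolerance
  is 1e-9 relative.
* The parameter-recovery checks use ~1000 synthetic sieve elements,
  100 tracer replicates at SNR 10, and 20 replicate calibrations (for the
  ±3 SE coverage of the fitted exponent) — sizes at which sampling error is
  far smaller than the effects being checked while the whole suite runs in
  seconds.
* Statistical checks on single seeded draws use 3-SE bands; the exponent
  coverage check instead counts successes across replicates, because a
  single draw cannot distinguish a 1%-probability excursion from bias.

## Interfaces

CSV schemas (column names carry the units) are read and written by
`read_geometry()`/`write_geometry()`, `read_turgor()`,
`read_calibration()`, `read_trace()`/`write_trace()`; scenarios and
reports travel as JSON. The `phloemflow` executable (`exec/phloemflow`)
exposes `simulate`, `conductivity`, `viscosity`, `velocity`, `feasibility`
and `report` subcommands over the same functions, logging the package
version and seed, and exits 0 on success, 2 on schema/configuration
errors, 3 on estimation failures.
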