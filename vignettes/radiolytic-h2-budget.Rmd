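---
title: "Modelling the radiolytic H2 budget of marine sediment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the radiolytic H2 budget of marine sediment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radH2)
```

# The model

Wet sediment is a slow radiolysis reactor. The decay of ²³⁸U, ²³⁵U, ²³²Th
(with their chains) and ⁴⁰K deposits α, β and γ energy in the
grain–porewater mixture, and a fraction of that energy splits water into H₂
and oxidants, net 2H₂O → H₂ + H₂O₂. The volumetric H₂ production rate is

$$P_{\mathrm{H_2}} = \sum_i \sum_s A_{m,s}\,\rho\,(1-\varphi)\,E_{s,i}\,G(\mathrm{H_2})_i$$

over radiation types $i$ and parent series $s$: $A_m$ is the activity per
mass of solid (decays yr⁻¹ g⁻¹), $\rho(1-\varphi)$ the solid mass per cm³
of bulk sediment, $E$ the chain-summed decay energy per parent decay, and
$G$ the radiolytic yield in molecules per 100 eV absorbed. Secular
equilibrium is assumed for all three chains, so each chain's energy release
scales with the parent activity; this is the standard assumption for bulk
marine sediment, where the parent inventories change on half-life
timescales vastly longer than burial.

Because H₂ and oxidant production are stoichiometrically balanced, the
package reports oxidant production as identically equal to H₂ production in
electron equivalents (2 e⁻ per H₂; 4 e⁻ per O₂; 4 e⁻ per organic C). This
is a definition, not an approximation, and several tests assert it exactly.

## Packaged constants and their provenance

The per-isotope abundances, half-lives and chain energy partitions ship as
`inst/extdata/nuclide_constants.csv` with a provenance note per row; every
function that consumes them accepts a replacement table. Two conventions
matter:

* **β energies are deposited energies** — mean emitted kinetic energies
  summed over the chain. Antineutrinos carry away roughly two-thirds of
  each β decay's energy and deposit none of it in the sediment, so they are
  excluded. Compilations that tabulate total decay energy instead would
  roughly triple the β entries; see the β-share discussion below.
* **The eV → "per 100 eV" conversion happens at exactly one code site**
  (inside `production_rate()`), eliminating double-scaling bugs between the
  MeV energy table and the G values.

The yield table (`inst/extdata/radiolytic_yields.csv`) stores
lithology-mean G values for five sediment categories plus pure water and
seawater, for α and γ radiation. Only lithology means are recoverable from
the experimental amplification factors the table encodes (clay-bearing
siliceous ooze 15× and calcareous marl 12× pure water for α; 8× and 4× for
siliceous ooze and abyssal clay under γ; and so on), so per-sample rows are
absent and flagged as such. Abyssal clay's α mean is set at 13× pure water
— consistent with "more than an order of magnitude" and with a per-sample
maximum of 27× stored in `G_max`. Lithogenous sediment has no measured
amplification; it is assigned modest ooze-like factors (α 5×, γ 2×),
documented as approximate in the provenance column and overridable.
Seawater yields are indistinguishable from pure water, and slurry-derived G
values are applied to in situ porewater as-is — the slurries were prepared
at in situ porosity precisely so that this transfer is reasonable.

β yields have never been measured for water-saturated sediment; the model
sets G(β) = G(γ) for the same medium, and `yield_lookup()` hard-codes that
substitution so no separate β row can drift out of sync.

## The β-yield question

`beta_assumption_sensitivity()` decomposes the production sum by radiation
type and recomputes it under two alternatives: G(β) = G(γ, pure water) and
G(β) = G(α, same medium). With the packaged constants and
lithology-average parameters, β contributes about 2% of total H₂
production (its energy share is larger, ~13%, but α's amplified yields
dominate the production sum). Totals therefore move by ~1% when β is given
the pure-water yield and by ~9–14% when β is given the α yield of the same
sediment. These three numbers cannot be made simultaneously small: any
yield table in which α amplification greatly exceeds γ amplification makes
the β=α swap expensive in proportion to β's share. The package reports all
three quantities (the acceptance script writes them out) rather than
tuning constants to soften the trade-off.

# Sediment columns

Compaction follows the Athy form φ(z) = φ₀e^(−c₀z) with c₀ per metre —
"compaction length scale" is read as the e-folding constant of an
exponential, the standard usage. c₀ is assigned by water-depth class:
0.5×10⁻³ (0–200 m), 1.7×10⁻³ (200–2500 m), 0.85×10⁻³ (abyssal). The
2500–3500 m band is not covered by those class definitions; the package
assigns it the abyssal value (the gentler of the two candidates) and lets
callers pass their own c₀ to `porosity_at()` if they disagree.

Depth integration runs in 1-m steps with porosity evaluated at interval
midpoints (top-of-interval evaluation would bias production low in the
top metre, where φ is highest); refining to 0.1 m moves the areal rate by
well under 0.5%, which a test enforces. Integration halts at the column
base or where φ reaches 0.1%, whichever comes first; the halt is flagged
because with the packaged c₀ values it triggers only for extremely thick
columns (~8–13 km depending on depth class). Lithology, composition, grain
density and G are held constant with depth; layered sites are handled by
the two-layer transport variant rather than by layered production columns.

Ages use the mean-accumulation model: age(z) = z·(basement age)/Z, a
bijection of [0, Z] onto [0, basement age]. Site-specific age models can be
substituted wherever an age is consumed, but no compaction correction is
applied to the accumulation rate — consistent with reporting *mean* rates.

# Expected dissolved H₂ and the transport solvers

With constant production and no consumption, the steady-state porewater
balance D/(φF)·C″ + P = 0 with zero-concentration boundaries at seafloor
and basement gives the parabola C(x) = ½(PφF/D)(xZ − x²). Three solvers
coexist:

* the closed form above (`steady_state_profile()`);
* a two-layer closed form (`two_layer_profile()`) imposing continuity of
  concentration and of the diffusive flux −(D/(φF))·dC/dx at the
  interface;
* a conservative finite-difference solver (`numeric_profile()`), which
  samples the diffusivity k = D/(φF) at cell-face midpoints and the source
  as the mean of adjacent face values. This choice makes the scheme exact
  (to round-off) for piecewise-parabolic solutions whenever an interface
  falls on a grid node, and second-order convergent for smooth sources — a
  test measures the error ratio 4.0 under grid halving.

P in these equations is per porewater volume; the production of
`production_rate()` is per bulk-sediment volume, and the conversion
(division by φ) is made at exactly one site in each caller. Solver
internals run in cm; interfaces accept metres. The formation factor
defaults to the Archie-type F = φ⁻² when unmeasured, and the H₂
diffusivity uses a linear seawater fit D ≈ (25.9 + 0.81·T°C)×10⁻⁶ cm² s⁻¹;
both are explicit parameters, so measured values should be supplied where
they exist.

`compare_profiles()` interpolates the expected profile onto measured
depths; measurements below detection are replaced by the detection limit,
making those ratios lower bounds (flagged `censored`), and a median ratio
above 10 raises the consumption flag. For realistic abyssal-clay columns,
expected concentrations are 10⁴–10⁶ nM against nM-scale detection limits —
the gap that implies consumption keeps pace with production.

# Net-rate inversion

Net rates of O₂ reduction or DIC production come from the curvature of
measured concentration profiles: an Akima spline is fit through the data,
the diffusive flux J(z) = −(D/F)·dC/dz is evaluated from its first
derivative, and the net volumetric rate over each interval is
(J(bottom) − J(top))/thickness, per bulk-sediment volume, with negative
rates meaning net consumption. (The φ in flux and the φF in diffusivity
cancel to D/F.) Rates telescope exactly: interval rates times thicknesses
sum to the boundary-flux difference, which a test asserts at 10⁻¹²
relative.

Design choices, in the order they bit:

* **Akima, interpolating, standard weights.** Akima's slope construction
  suppresses the overshoot of global cubic splines near kinks in noisy
  geochemical profiles. The fit interpolates (no penalization); data
  pre-averaging is left to the caller. The in-package implementation is
  cross-checked against `pracma::akimaInterp` in the tests.
* **Akima is not linear in the data** — its weights are slope-difference
  ratios. The honest invariants, which tests enforce exactly, are positive
  homogeneity (scaling data scales rates) and invariance of rates to
  adding any linear profile (slope differences, hence weights, are
  unchanged). Full additivity does not hold and is not claimed.
* **Bins** default to the intervals between successive data midpoints;
  edges are user-configurable but must stay inside the fitted domain.
* **Boundary fluxes** use the one-sided derivative of the fit at the
  profile ends.

`monte_carlo_sigma()` perturbs the concentrations with independent
Gaussian noise at the stated measurement sd, refits and re-inverts (seeded,
bit-reproducible). On forward-modelled profiles with known rate fields the
noise-free depth-integrated rate is recovered within 5% (measured: ~0.3%
for a smooth exponential field sampled at 40 depths), and the ±2 sd
interval covers the true per-interval rate ≥ 93% of the time at sd = 1 µM
(measured: ~95–96% over 200 replicates of a 25-depth profile with 100
inner draws — the problem sizes used throughout the tests and the
acceptance script).

# Bioenergetics and the crossover age

The Knallgas reaction H₂ + ½O₂ → H₂O is evaluated as
ΔG_r = ΔG°_r(T,P) + 2.3·R·T·log₁₀Q with Q = a_H₂O/(a_H₂·a_O₂^½). The
default ΔG°_r(T) is a linear model on the aqueous-species basis
(−275.8 + 0.0432·T[K] kJ per mol H₂, ≈ −263 kJ mol⁻¹ at 25 °C), chosen to
be consistent with dissolved-activity quotients; pressure dependence over
seafloor pressures is small and not modelled, and site-specific ΔG°_r
values are accepted everywhere. Activity coefficients default to 1.
Because ΔG°_r sources vary, Gibbs results are property-tested (Q = 1
identity, log-additivity, monotonicity), not value-matched. Where H₂ is
below detection, evaluating ΔG at the detection limit gives a bound, and
callers should treat it as such.

`ratio_series()` compares radiolytic e⁻eq production to the magnitude of
the net organic-fuelled rate per interval, against the age of the interval
midpoint; the H₂-based and oxidant-based ratios are one number in electron
equivalents, by construction. Rate sd propagates multiplicatively.
`crossover_age()` finds the first age at which the ratio reaches 1 by
linear interpolation; with an exponentially decaying organic field R₀e^(−k·age)
against constant radiolytic supply P, the analytic crossover ln(R₀/P)/k is
recovered within one age bin (measured: ~0.04 Ma error on 1-Ma bins).

# The global rollup

`assign_parameters()` implements the regional rules: a Southern Ocean opal
belt (57–66°S → siliceous ooze); lithogenous fills at 50–57°S, south of
66°S, and the Arctic (≥ 70°N); and the Atlantic rule, under which cells
whose seafloor is abyssal clay take calcareous-marl parameters because
Atlantic columns are carbonate-bearing at depth even under clay seafloors —
a choice that biases Atlantic production low, since clay catalyzes more
strongly than marl. The basin tag driving the Atlantic rule is a coarse
longitude mask in the synthetic generator and a caller-supplied column for
real grids. Latitude-band rules are applied unconditionally within their
bands; drill-site-level adjustments are out of scope.

Cell areas use the closed spherical form R²·Δλ·(sinφ₂ − sinφ₁) with
R = 6371 km; summed over the globe this closes 4πR² to well within 0.1%.
Unclassified cells are excluded from the sum and reported in the coverage
fraction; zero-thickness (land or bare-rock) cells contribute zero but
count as classified. Because the stated global figure could be read as
either the H₂ rate or the H₂ + oxidant sum, the result object carries
`total_H2_eeq_mol_yr`, `total_oxidant_eeq_mol_yr` (identical by
stoichiometry) and `total_combined_eeq_mol_yr` (their sum), so either
reading can be checked.

Grid I/O is CSV/data-frame based; no raster formats are read or written.
Reproducing a published-grid global total therefore requires exporting
those grids to the `seafloor_grid()` column layout first.

# What the synthetic data does and does not show

The generators emulate the statistical structure the analysis assumes:
lithology-typical radionuclide content and porosity (abyssal clay φ₀ in
0.80–0.85), porewater profiles produced by a known rate field plus
Gaussian noise, and global mosaics whose margins are shallow, lithogenous
and thickly sedimented while open-ocean cells are deep and thin, with
thickness spanning more than four orders of magnitude. On such a mosaic
(36×72 cells at 5°) the rollup lands at ~3×10¹³ mol e⁻eq yr⁻¹ with areal
rates spanning ~5 orders of magnitude — emergent from the lithology
parameters and geometry, not calibrated.

Passing the recovery tests on these inputs demonstrates that the numerics
are faithful to their own model: diffusion-only transport, steady state, no
advection or bioturbation, Gaussian independent noise, lithology constant
with depth. Real profiles violate these in known ways (burial advection in
fast-accumulating margins, non-steady boundary conditions, correlated
analytical error), so recovery percentages quoted here bound numerical
error, not field accuracy. The irradiation experiments behind the yield
table, and site-specific stratigraphy, are outside the package's scope.

# Known limitations

* Energy-partition and abundance constants are standard literature values;
  analyses that used different compilations will differ at the few-percent
  level, and exact reproduction of any particular published site rate
  depends on the constants that study used.
* The β share / β-yield sensitivity trade-off described above is inherent
  to strongly α-amplified yield tables.
* No disequilibrium corrections (radon loss, U-series fractionation), no
  dose-rate dependence of G, no H₂O₂ speciation kinetics.
* The global estimate is only as good as the grid fed to it; the packaged
  synthetic mosaic is a structural stand-in, clearly named as such.
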