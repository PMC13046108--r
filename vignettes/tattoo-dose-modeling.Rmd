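---
title: "Modeling dose perturbation by tattoo pigments: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dose perturbation by tattoo pigments: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: what is modeled,
which parameters matter, where the design was genuinely open and what was
decided, and what the simplifications do and do not let you conclude.

## The physical problem

Tattoo pigment is deposited in the reticular dermis, roughly 1.25–1.55 mm
below the skin surface. Brown inks are dominated by iron oxide (Fe₂O₃,
5.3 g/cm³), orange inks carry aluminium hydroxide (Al(OH)₃, 2.4 g/cm³), and
black inks are carbon black (1.8 g/cm³). Under megavoltage photon beams a
dense, higher-Z inclusion produces more secondary electrons per millimetre
(Compton scattering scales with electron density; pair production with
Z(Z+1)) than the surrounding dermis, so dose in and just beyond the pigment
layer rises. Under electron beams the pigment mostly just scatters the
already-charged primaries, so perturbations are small and can even turn into
a deficit beneath the layer at high energy. The package quantifies these
effects as the dose enhancement factor `DEF(z) = D_tattoo(z)/D_control(z)`
between two otherwise identical phantoms.

## From ink survey data to transport materials

Packaged elemental concentrations are wet-basis (per kg of liquid ink). The
pigment retained in healed skin is the solid fraction, so concentrations are
rescaled by the dry-matter fraction: `c_dry = c_wet / f_dry`, with
`f_dry = 0.47` (surveyed commercial range 0.31–0.62 — the synthetic ink
generator draws uniformly from this range). REACH screening intentionally
compares *wet*-basis values against the limits, matching how such surveys
are tabulated; the one below-quantification entry (orange-ink Cu) is stored
as 0 ppm with an explicit flag, which is conservative for dose and lossless
for provenance.

**Dry-mass closure.** The survey reports only the trace metals, never the
full pigment formulation, so the remaining dry mass must be assigned. Two
closures are implemented:

* `"compound"` (default): residual mass goes to the dominant compound, so
  the brown pigment is essentially pure Fe₂O₃ plus traces. This is the only
  reading consistent with assigning the compound's bulk density
  (5.3 g/cm³ = crystalline Fe₂O₃) to the whole dry pigment, and it
  preserves the pair-production character of the metal oxide that drives
  the high-energy photon enhancement. It treats the reported dry-basis Fe
  concentration as a lower bound rather than an exact total.
* `"binder"`: residual mass becomes a generic organic binder modeled as
  carbon, keeping every measured concentration exact. The brown pigment is
  then ~73% carbon at an (inconsistent) 5.3 g/cm³; in testing this closure
  suppresses the 18 MV pair-production channel enough to invert the
  expected 18 MV ≥ 6 MV peak-DEF ordering, which is why it is not the
  default.

The closure used is recorded in material metadata and in scenario
provenance.

**Mixtures.** Tattoo–dermis blends use volume-fraction density mixing,
`ρ_mix = v ρ_ink + (1−v) ρ_dermis`, and mass-fraction weighting
`w_i = v_i ρ_i / Σ_j v_j ρ_j`, with the reticular dermis (1.1 g/cm³) as the
partner material. Internal values are kept at full precision; the printed
mixture-density table is reproduced with IEEE round-half-even on doubles
(base R `round()`), the convention that matches all 21 published cells —
decimal half-up does not (it disagrees on the 2.15 and 4.25 ties).

## Phantom geometry

Depth increases downward from the surface; layer intervals are half-open
`[top, bottom)`, so a point on a shared boundary belongs to the deeper
layer. The stack is: six epidermal sublayers (upper/middle/lower stratum
corneum at 1.3/1.2/1.1 g/cm³, granulosum, spinosum, basale; 100.1 µm
total), 0.4 mm papillary dermis, 1.9 mm reticular dermis containing the
0.3 mm tattoo sublayer at 1.25–1.55 mm, then a 10 cm water backing — thick
enough to saturate backscatter at these energies, which is the only role
the backing plays. The lateral slab is 3 × 3 cm², wider than the 1 × 1 cm²
field so laterally scattered particles are not lost at the field edge.

Scoring uses the standard mesh: 24 depth bins of 0.1 mm over 0–2.4 mm and
2 mm lateral bins across the field. For quadrant (multi-color) layouts the
lateral bins widen to 2.5 mm so bins nest inside the 5 mm quadrants and no
bin straddles two materials; both widths are exposed in `build_phantom()`.
The geometry grid is exact (sub-voxel 8 µm sublayers are represented as
their own z-zones) and independent of the scoring grid.

## The transport engine

A deliberately simplified voxel Monte Carlo, implemented in C++ (Rcpp),
replaces a general-purpose code at desk scale while keeping the interaction
physics the dose-enhancement effect rests on.

**Photons** use Woodcock (delta) tracking against a per-energy majorant, so
flight sampling is exact in the layered geometry without boundary logic.
Interactions: photoelectric absorption (full energy to a photoelectron),
Compton scattering sampled from the Klein–Nishina differential cross
section with exact energy–momentum conservation, and pair production above
1.022 MeV with the pair energy split uniformly and two 0.511 MeV
annihilation photons emitted isotropically at the positron's end of track.
Photons below 10 keV deposit locally.

**Cross sections** are analytic models combined by Bragg additivity
(mass-fraction weighting at every grid energy, tabulated on a log grid from
10 keV to 25 MeV):

* incoherent: Klein–Nishina total cross section × electron density (Z/A);
* photoelectric: a Z⁴·⁵/E³ power law anchored at a packaged water
  reference point — adequate because the photoelectric channel is
  negligible above ~0.5 MeV where the beams of interest live;
* pair production: a Bethe–Heitler-shaped `Z(Z+1)(ln 2k − b)` law with the
  two constants calibrated to packaged water pair values at 6 and 18 MeV.
  Because the calibration is done on water, neglected screening and
  Coulomb corrections make the model run ~10–20% high for iron-group
  elements near 18 MeV; this is the engine's largest known bias and it
  inflates the 18 MV enhancement statistics by a comparable amount (see
  Limitations).

**Electrons and positrons** use condensed-history CSDA steps: Bethe
collision stopping power with Bragg-additivity mean excitation energies and
an asymptotic density-effect correction, plus a Berger-style radiative term
(`S_rad ≈ S_col · Z_eff E / 750`). Radiative losses are removed from the
electron but *not* deposited locally — bremsstrahlung photons are not
generated, on the grounds that their interaction probability within a
2.4 mm slab is second-order. Angular deflection per step combines a
Highland/Lynch–Dahl Gaussian core with a screened-Rutherford single-scatter
tail (θ > 0.4 rad, at most ~0.2 expected hard events per step by step-size
control), which restores the large-angle/backscatter component a pure
Gaussian model lacks. Steps are capped at `min(0.02 mm, 5% energy loss)`
inside the skin slab and 1 mm in the water backing, and are always split at
material interfaces (z-zone boundaries and, inside the tattoo sublayer,
the quadrant planes); without the split, interface bins acquire
percent-level deposit-rate artifacts. Secondary electrons below 50 keV
deposit locally, except inside the tattoo sublayer where the cutoff drops
to 10 keV — the analogue of a finer production cut where gradients are
steepest. Electrons deeper in the backing than their residual range can
never return to the scored slab and are terminated on the spot.

**Scoring** accumulates both dose-to-medium and dose-to-water (the skin
dosimetry convention, and the package default); the conversion multiplies
each collision deposit by the water/medium mass collision stopping-power
ratio at the depositing electron's current energy. Per-voxel statistical
uncertainty comes from 10 independent batches. The RNG is a counter-based
PCG32 seeded per history from the run seed, so results are bit-identical
for a fixed seed and independent of execution order.

**Beams** are modeled as monoenergetic with a Gaussian energy spread of
σ = 2% of nominal (a configurable default; no spectrum is packaged, though
`beam_spec()` accepts any nominal energy), collimated parallel to a
1 × 1 cm² field at the surface. At SSD 100 cm the divergence across 2.4 mm
is negligible, but a point-divergent source mode exists.

## Analysis conventions

* Depth profiles average laterally; the default mask is the central
  6 × 6 mm (penumbra-free), while `mask = "field"` averages the full field
  and is used for all headline statistics.
* The "tattoo-layer mean DEF" averages the four 0.1 mm bins spanning
  1.2–1.6 mm — the bins *covering* the 1.25–1.55 mm sublayer, since the
  sublayer edges fall mid-bin. The bin set is recorded in the result
  because the averaging region is a convention, not a given.
* The sub-layer deficit statistic is the minimum DEF over 1.6–2.0 mm,
  "immediately beneath" the pigment.
* Peak DEF is taken over all 24 bins (0–2.4 mm), not only the layer.
* The quadrant uniformity statistic is the maximum pairwise relative
  difference between quadrant means of the depth-summed lateral map.

## Problem sizes

Headline statistics in the test suite and the acceptance script use 10⁶
electron histories and 1–2 × 10⁶ photon histories per run — sizes chosen so
a full control/tattoo comparison completes in minutes on one CPU while
keeping per-bin DEF uncertainty at the percent level (electron primaries
cross every depth bin, so electron-beam DEF statistics are far tighter than
photon-beam ones at equal n). Uncertainty scales as 1/√n and the engine
sustains ~10⁶ electron histories per minute in this geometry, so 10⁷-class
runs are possible where sub-percent photon statistics are needed.

## What the synthetic generators do and do not emulate

`make_random_ink()` draws trace-metal ppm log-uniformly (0.01–10⁵ ppm),
dry-matter fractions from the surveyed 0.31–0.62 range, and a dominant
compound from the packaged list. It emulates the *schema* and plausible
ranges of ink surveys — enough to property-test the chemistry-to-material
pipeline on arbitrary compositions — but not the correlation structure of
real formulations (batch variance is unreported in the source surveys, so
the dispersion here is a free choice). `make_toy_dose_grid()` produces
uniform/ramp/quadrant dose patterns with closed-form summaries for testing
the analysis operations; it contains no transport physics. Consequently,
green tests on these fixtures validate bookkeeping and algebra, not
dosimetric realism; realism rests on the physics-oracle tests (attenuation,
Klein–Nishina moments, CSDA range) and the cross-modality behavior of the
engine itself.

## Numerical choices and degenerate inputs

Mass fractions are validated to sum to 1 within 1e-9 (materials) and
renormalized exactly; mixtures with zero total mass, loadings outside
0–100 vol%, dry fractions outside (0, 1], empty lateral masks, non-positive
control dose bins (undefined DEF) and geometry with the tattoo outside the
reticular dermis all raise immediate errors rather than propagating.
Boundary ties in the geometry go to the deeper voxel; lateral quadrant
boundaries go to the right/top. Log-log linear interpolation is used on all
tabulated physics. The pair-production component is clamped to exactly zero
below threshold.

## Limitations

* The engine is a surrogate, not a commissioning tool: no Rayleigh
  scattering, atomic relaxation, explicit bremsstrahlung photons,
  delta-ray (Møller) secondaries, or electron energy-loss straggling.
  Quantitative agreement with general-purpose codes is expected at the
  ±10–20% level for DEF-type ratios, better for electron beams than photon
  beams.
* The water-calibrated pair-production law overestimates high-Z pair cross
  sections by ~10–20% near 18 MeV; 18 MV enhancement statistics
  (particularly means over the layer) inherit an upward bias of roughly
  that size, while orderings and peak locations are unaffected.
* Interface bins can show percent-level structure from condensed-history
  step granularity even after boundary splitting.
* The simulated DEF(z) under photon beams is broader in depth than
  general-purpose codes produce: CSDA transport without delta-ray
  generation or energy-loss straggling lets secondary electrons deposit
  farther and more uniformly, so peak values run slightly low while
  layer-averaged values run high. Summary statistics averaged over the
  tattoo-layer bins inherit an upward bias of order 10-20% under photons.
* DEF uncertainties propagated in quadrature from per-voxel batch
  estimates assume independent bins; because one secondary electron
  deposits across many bins, the true run-to-run spread of layer-averaged
  DEF statistics is ~2-3x the propagated value. Seed-to-seed replication
  is the reliable way to assess the uncertainty of a summary statistic.
* 100 vol% loading is a parametric upper bound, not a biological pigment
  concentration (realistic tattoos are ≲25 vol%); results at full loading
  bound, rather than estimate, clinical effects.
* The skin model is planar and uniform in composition across strata; no
  patient anatomy, curvature, or bolus.
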