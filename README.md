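# tattoodose

Monte Carlo modeling of how intradermal tattoo pigments perturb skin dose
during megavoltage radiotherapy.

About a third of adults carry tattoos, and most cancer patients receive
external-beam radiotherapy at some point. Commercial tattoo inks contain
metal pigments — iron oxide in browns, aluminium hydroxide in oranges — plus
regulated trace metals (Cr, Ni, Co, Pb) that frequently exceed EU REACH
limits. Because pigment sits in the reticular dermis at ~1.3–1.6 mm depth,
inside the steep superficial gradient of clinical beams, high-Z pigment can
locally change the dose the dermis actually receives. `tattoodose` is a
self-contained R package for quantifying that perturbation: it is aimed at
medical physicists and dosimetry researchers who want a reproducible,
desk-scale model of the effect without deploying a general-purpose Monte
Carlo toolkit.

## What it computes

The package chains five stages:

1. **Ink chemistry** — packaged elemental compositions of three commercial
   inks (wet-basis ppm), converted to the dry pigment retained in skin via
   `c_dry = c_wet / f_dry` with the surveyed dry-matter fraction
   `f_dry = 0.47`, compound density assignment (Fe₂O₃ 5.3, Al(OH)₃ 2.4,
   carbon black 1.8 g/cm³), and REACH compliance screening.
2. **Mixture materials** — tattoo–dermis blends at 0–100 vol% loading using
   volume-fraction density mixing, `ρ_mix = v·ρ_ink + (1−v)·ρ_dermis`, and
   mass-fraction weighting `w_i = v_i ρ_i / Σ_j v_j ρ_j`.
3. **Phantom** — a voxelized multilayer skin slab: six epidermal sublayers
   (100.1 µm), papillary and reticular dermis, a 0.3 mm tattoo sublayer at
   1.25–1.55 mm, optional four-quadrant multi-color layout, water backing.
4. **Transport** — a simplified, seeded voxel Monte Carlo engine (C++ via
   Rcpp): Klein–Nishina Compton sampling with exact kinematics,
   photoelectric absorption, pair production with positron annihilation,
   and condensed-history electron transport (Bethe stopping power, Highland
   multiple scattering with a screened-Rutherford hard tail). Dose is scored
   to water and to medium on the standard mesh (0.1 mm depth bins over
   0–2.4 mm, 2 mm lateral bins over a 1 × 1 cm² field).
5. **Analysis** — depth-dose profiles `D(z) = mean_xy D(x,y,z)`, integrated
   skin dose, the dose enhancement factor
   `DEF(z) = D_tattoo(z) / D_control(z)` with peak/layer-mean/integrated
   summaries, and 2D lateral maps with quadrant uniformity statistics.

It is *not* a general-purpose MC code: no Rayleigh scattering, atomic
relaxation, bremsstrahlung photon generation, linac head models, or ion
transport. See the methods vignette (`vignettes/tattoo-dose-modeling.Rmd`)
for the model, its assumptions and its limits.

## Worked example

DEF for a 100 vol% iron-oxide (brown) tattoo sublayer under a 6 MV photon
beam, 1 × 1 cm² field at SSD 100 cm:

```r
library(tattoodose)

tab     <- load_reference_tables()
control <- build_phantom(NULL, tables = tab)
tattoo  <- build_phantom(tattoo_mixture("brown", 100, tables = tab), tables = tab)

beam <- beam_spec("photon", 6)
rc <- run_simulation(control, beam, n_histories = 2e6, seed = 11)
rt <- run_simulation(tattoo,  beam, n_histories = 2e6, seed = 12)

def_statistics(depth_profile(rt, "field"), depth_profile(rc, "field"))
#> <def_result> peak DEF 1.876 at 1.55 mm | tattoo-layer mean 1.605 | integrated 1.5082 | sub-layer min 1.663
```

Reading: the dense Fe₂O₃ sublayer nearly doubles the local dose at its
distal edge (peak DEF 1.88 at 1.55 mm), raises the mean dose across the
tattoo-layer bins by ~60%, and raises the integrated 0–2.4 mm skin dose by
~50% — a pronounced, depth-localized hotspot. The same pair of runs under a
6 MeV *electron* beam gives peak DEF ≈ 1.05 and an integrated change of
~1.3%: electron beams barely notice the pigment, while under 18 MeV
electrons the tissue just beneath the layer even shows a small deficit
(DEF ≈ 0.97).

Scenario-level layouts (loading series, four-quadrant multi-color maps,
table regeneration) are wrapped by `run_scenario()`; a thin CLI lives at
`inst/scripts/tattoodose_cli.R`.

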