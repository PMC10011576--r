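# nitriflux

Quantitative analysis of how aquatic acidification affects nitrification
and nitrification-derived N₂O in estuarine and coastal waters, built
around ¹⁵N-tracer incubation experiments. Intended for aquatic
biogeochemists running (or simulating) CO₂/pH manipulation incubations who
need the full chain from raw observables to global-scale context:

1. **Tracer rates** — nitrification from ¹⁵N accumulation in the
   NO₃⁻ + NO₂⁻ (NOₓ⁻) pool, and N₂O production from mass-45/46
   isotopologue accumulation, with both the published estimator and an
   atom-balance diagnostic.
2. **Carbonate chemistry** — pH/DIC/TA/pCO₂ speciation and inverse solves
   (Mehrbach K₁/K₂ as refit by Dickson & Millero, seawater scale),
   including the treatment-design direction for pCO₂ × pH factorials.
3. **Isotopomer partitioning** — N₂O site-preference (SP) two-endmember
   mixing to apportion emissions between NH₂OH-oxidation and
   NO₂⁻-reduction pathways, with Monte-Carlo uncertainty.
4. **Dose–response** — percent change of a rate vs ΔpH, polynomial fits
   constrained through the origin, evaluation at policy-relevant ΔpH.
5. **Upscaling** — emission-increase and share-of-anthropogenic
   arithmetic for scenario analysis.
6. **Synthetic data** — a seeded forward simulator with known ground
   truth for every stage, so the whole pipeline is testable end to end.

## The core model

With tracer atom fraction `F = [¹⁵NH₄⁺] / ([¹⁴NH₄⁺] + [¹⁵NH₄⁺])`, the
nitrification rate over an incubation interval is

    R_nit = ( r15(t)·[NOx⁻]_t − r15(t0)·[NOx⁻]_t0 ) / (t − t0) · 1/F

(µmol inputs, nmol L⁻¹ h⁻¹ output), and N₂O production follows from the
accumulation of the mass-45 and mass-46 isotopologues. The published N₂O
estimator carries an extra 1/F on the mass-46 term; under binomial pairing
(p₄₅ = 2F(1−F), p₄₆ = F²) it returns exactly (2 − F) times the true N-atom
rate, while the atom-balance form `(Δ45 + 2·Δ46)/(F·Δt·V)` is exact. Both
are provided and the identity is verified in the tests — see the methods
vignette (`vignettes/acidification-nitrification-methods.Rmd`) for the
derivation and all modelling choices.

## Worked example

```r
library(nitriflux)

# a simulated 4 L vessel, 24 h, true rate 150 nmol L-1 h-1, 5% noise
cfg <- sim_config(true_nitrification_rate = 150, noise_cv = 0.05, seed = 42)
sim <- simulate_incubation(cfg)
nitrification_rate(sim$time_h, sim$nox_umol_L, sim$r15_nox, F = cfg$F)
#> <rate_result [eq1]> 149.595 nmol L^-1 h^-1 over [0, 24] h

n2o_rate_printed(sim$time_h, sim$n2o45_pmol, sim$n2o46_pmol, cfg$F, cfg$volume)
#> <rate_result [eq3_printed]> 9.12089 pmol N2O-N L^-1 h^-1 over [0, 24] h
n2o_rate_atom_balance(sim$time_h, sim$n2o45_pmol, sim$n2o46_pmol, cfg$F, cfg$volume)
#> <rate_result [atom_balance]> 4.97395 pmol N2O-N L^-1 h^-1 over [0, 24] h
```

The estimate 149.6 sits within noise of the generating 150; the printed
N₂O estimator exceeds the atom-balance value by the factor
2 − F ≈ 1.83 discussed above (true N-atom rate here: 5).

```r
speciate_from_ph_dic(8.1, 2000, temperature = 25, salinity = 35)[, 1:6]
#>    ph  dic      ta   pco2 co2_star    hco3
#> 1 8.1 2000 2343.92 335.95     9.54 1746.77

pts <- simulate_dose_response(coefficients = c(-40, -60), noise_cv = 0.1, seed = 7)
fit_response(pts, degree = 2)
#> <response_curve> %change = -35.61 x^1 -79.96 x^2  (R2 = 0.994, P = 5.37e-15, n = 15, domain [0, 1.05])
evaluate_response(fit_response(pts), 0.21)
#> [1] -11.00  # percent change at a 0.21 pH-unit decrease

share_of_anthropogenic(c(0.05, 0.15), 6.9)
#> [1] 0.7 2.2  # percent of the global anthropogenic N2O total
```

A fitted curve near −36x − 80x² recovered from a generating −40x − 60x²
at 10 % replicate noise evaluates to about −11 % at the projected mean
coastal acidification of 0.21 pH units; an emission increase of 0.05–0.15
Tg N₂O-N yr⁻¹ is 0.7–2.2 % of a 6.9 Tg N₂O-N yr⁻¹ anthropogenic total.

`run_pipeline(outdir, seed)` chains simulate → rates → response → upscale
and writes CSVs, a JSON report, and a run manifest, byte-identical for a
fixed seed.

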