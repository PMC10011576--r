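---
title: "Methods: tracer rate estimation, carbonate chemistry and N2O accounting in nitriflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer rate estimation, carbonate chemistry and N2O accounting in nitriflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitriflux)
```

# The scientific problem

Estuarine and coastal waters acidify faster than the open ocean because
eutrophication-driven respiration adds CO~2~ on top of the atmospheric
signal. Nitrification — the microbial oxidation of ammonia via nitrite to
nitrate — depends on NH~3~ (not NH~4~^+^) as substrate, so falling pH
shrinks the available substrate pool and stresses the ammonia oxidizers,
while at the same time rising CO~2~ can fertilize these chemoautotrophs.
Nitrification is also a source of the greenhouse gas N~2~O. `nitriflux`
implements the quantitative chain used to study this system with
^15^N-tracer incubations: rate estimation, carbonate-system speciation,
N~2~O isotopomer source partitioning, acidification dose–response curves,
and global emission upscaling — plus a seeded forward simulator so every
stage can be validated against known ground truth.

# Tracer rate estimators

An incubation receives ^15^NH~4~Cl at less than 20 % of the ambient
NH~4~^+^ concentration, so the substrate pool has atom fraction

$$F = \frac{[^{15}\mathrm{NH_4^+}]}{[^{14}\mathrm{NH_4^+}] + [^{15}\mathrm{NH_4^+}]}$$

(`atom_fraction()`). The nitrification rate follows from the accumulation
of ^15^N in the combined NO~3~^−^ + NO~2~^−^ (NO~x~^−^) pool:

$$R_{nit} = \frac{r_{15}(t)\,[\mathrm{NO_x^-}]_t - r_{15}(t_0)\,[\mathrm{NO_x^-}]_{t_0}}{t - t_0}\cdot\frac{1}{F}$$

Inputs are in µmol L^−1^ (the working unit of colorimetric nutrient
analysis); the output is multiplied by 1000 to the conventional
nmol L^−1^ h^−1^. The two-point (`method = "endpoints"`) form matches
incubations sampled at the start and end of a 24 h run; the
`"regression"` form takes the least-squares slope of ^15^NO~x~^−^ against
time for multi-timepoint protocols such as enrichment-culture assays.
Negative estimates (a declining labelled pool) are returned as-is with a
`negative` flag and a warning — never clamped — because silently truncating
at zero would bias treatment means upward.

## The two N~2~O estimators and the (2 − F) identity

N~2~O production is measured from the accumulation of the mass-45 (one
^15^N) and mass-46 (two ^15^N) isotopologues. `n2o_rate_printed()`
implements the published estimator verbatim:

$$R_{N_2O} = \frac{1}{F}\left(\frac{\Delta^{45}}{\Delta t} +
  2\,\frac{\Delta^{46}}{\Delta t}\cdot\frac{1}{F}\right)\frac{1}{V}$$

with the second $1/F$ applying only to the mass-46 term. Whether that
asymmetry is intended or typographical cannot be decided from the source
alone, so the package does not "correct" it; instead it ships the
atom-balance diagnostic `n2o_rate_atom_balance()`,

$$R_{N_2O} = \frac{\Delta^{45} + 2\,\Delta^{46}}{F\,\Delta t\,V},$$

which simply counts labelled N atoms (one per mass-45 molecule, two per
mass-46) and divides by $F$.

Under *binomial pairing* — both N atoms of each N~2~O molecule drawn
independently from the labelled pool, so $p_{45} = 2F(1-F)$ and
$p_{46} = F^2$ — a true N-atom production rate $R$ yields
$\Delta^{45} + 2\Delta^{46} \propto 2F$, and the atom balance returns $R$
exactly for every $F$. The printed form instead evaluates to

$$\frac{1}{F}\bigl(2F(1-F) + 2F\bigr)\cdot\frac{R}{2} = (2 - F)\,R,$$

an overestimate by the factor $(2-F) \in (1,2)$. Both estimators are
reported side by side by `rates_from_incubation()`, and the identity
`printed / atom_balance == 2 - F` is asserted to 10^−9^ in the test suite
across $F \in \{0.05, 0.1, 0.2, 0.5\}$. A hybrid mechanism in which only
one N atom comes from the ammonium pool (`pairing_model = "single_label"`,
$p_{45} = F$, $p_{46} = 0$) is supported in simulation since the true
pairing in natural samples is not observable from these data.

# Carbonate system

`carb_constants()` evaluates the published functional forms: K~1~/K~2~
from the Mehrbach measurements as refit by Dickson & Millero (1987) on the
seawater pH scale, K~0~ (Weiss 1974), K~B~ (Dickson 1990, converted
total→seawater scale through the bisulfate and fluoride equilibria), K~W~
(Millero 1995), and the Uppström (1974) boron–salinity ratio. Surface
pressure is assumed; supported ranges are −2–40 °C and salinity 0–45.

Total alkalinity is truncated to the carbonate, borate and water terms:

$$TA = [\mathrm{HCO_3^-}] + 2[\mathrm{CO_3^{2-}}] + [\mathrm{B(OH)_4^-}]
 + [\mathrm{OH^-}] - [\mathrm{H^+}]$$

Nutrient contributions are omitted: at the ≤10 µM ammonium levels of these
incubations they are far below the ~1 µmol kg^−1^ closure tolerance of the
identities the solver guarantees. Three directions are provided:

* `speciate_from_ph_dic()` — closed-form ionization fractions at
  $[\mathrm{H^+}] = 10^{-pH}$; the measurement direction (pH and DIC are
  what is measured; TA and pCO~2~ are derived).
* `solve_ph_from_ta_dic()` — root of $TA(pH, DIC) - TA$ bracketed on
  pH ∈ [2, 12] (`uniroot`, tolerance 10^−10^ pH). An input pair with no
  root in the bracket is an error, never an extrapolation.
* `solve_from_ta_pco2()` / `state_from_ph_pco2()` — the treatment-design
  direction: what state a continuously bubbled vessel relaxes to, and what
  alkalinity acid/base dosing must set to hold a (pCO~2~, pH) cell of a
  factorial design. `simulate_carbonate_factorial()` tabulates the four
  cells of a 400/800 µatm × pH 8.1/7.8 design this way.

pH scale: the solver treats input pH as being on its working (seawater)
scale. Glass-electrode measurements are nominally NBS; the explicit
converter `ph_nbs_to_sws()` (Takahashi fH factor, an offset near −0.15 at
25 °C/S 35) is provided but not applied automatically, because applying an
uncertain scale correction silently would be worse than documenting the
choice. Concentrations are per kg of solution; for incubation bookkeeping
the 1 L ≈ 1 kg approximation is left to the caller.

At 25 °C, S = 35, TA = 2300 µmol kg^−1^ the solver places pH at about 8.03
under 400 µatm and 7.78 under 800 µatm — a gap of ~0.25 pH units,
consistent with a factorial design pairing those pCO~2~ levels with pH
targets 8.1/7.8.

# Isotopomer source partitioning

The site preference $SP = \delta^{15}N^{\alpha} - \delta^{15}N^{\beta}$ of
emitted N~2~O discriminates production pathways: NH~2~OH oxidation yields
high SP, NO~2~^−^ reduction (nitrifier denitrification plus heterotrophic
denitrification) low SP. `fraction_from_reduction()` applies two-endmember
linear mixing on the SP axis only — δ^18^O is carried as data but not
modelled, because SP is the axis on which the two source classes separate
cleanly while δ^18^O also responds to substrate water and consumption.
Estimates outside [0, 1] are clipped with an explicit flag.
`mc_fraction()` propagates normal uncertainty in the sample and both
endmembers by Monte Carlo (seeded, clip events counted).

The shipped endmember defaults (+30 ‰ production, 0 ‰ reduction, sd 3 ‰
each) are literature-typical class values and deliberately marked
non-authoritative configuration: site-calibrated endmembers should be
supplied for real data. No Rayleigh correction for partial N~2~O
consumption is applied.

# Dose–response curves

`build_response_points()` converts per-replicate treatment rates into
percent changes against the *mean* of the control replicates (treatments
at different acidification levels are independent vessels, so replicate
pairing would be artificial). `fit_response()` fits

$$y = \beta_1\,\Delta pH + \beta_2\,\Delta pH^2 \;(+\,\beta_3\,\Delta pH^3)$$

with the intercept structurally zero: at $\Delta pH = 0$ the percent
change is zero by construction, so the origin is a constraint, not a
parameter. Degree defaults to 2 (a knob over 1–3): curvature is evident in
acidification responses, while a cubic is rarely identifiable from 4–6
levels. Significance is an F-test against the all-zero null with no
multiple-testing correction across sites (curves are reported per site).
The degenerate all-zero response returns zero coefficients and p = 1.
`evaluate_response()` warns on extrapolation beyond the fitted ΔpH span;
0.21 pH units — the projected mean acidification of estuarine and coastal
waters — is the evaluation point of headline interest.

# Emission upscaling

`emission_increase()` is deliberately simple arithmetic:
baseline × nitrifier share × fractional response, evaluated at both ends
of the response range, and `share_of_anthropogenic()` expresses the result
as a percentage of the global anthropogenic N~2~O total (default
6.9 Tg N~2~O-N yr^−1^), rounded half-up to one decimal. There is no
authoritative baseline default: `reconstructed_baseline_tg()` documents a
*synthetic* placeholder (~1.05–1.09 Tg N~2~O-N yr^−1^) obtained by
algebraically inverting a 0.05–0.15 Tg yr^−1^ increase range under share
0.5 and responses 0.095–0.275 — a consistency reconstruction, not an
inventory value. The pipeline report rounds the increase to two decimals
(its natural precision in Tg) before computing the share, so the two
reported lines are arithmetically consistent with each other.

# The synthetic-data generator

`simulate_incubation()` forward-simulates exactly the model the
estimators assume: linear NO~x~^−^ growth at the true rate, newly
produced NO~x~^−^ labelled at the constant tracer fraction $F$ (no
ammonium-pool dilution by remineralization over 24 h with tracer ≤ 20 % of
ambient), N~2~O molecules at half the N-atom rate split by the pairing
model, and *multiplicative* Gaussian noise (default CV 5 %, an
instrument-like error model) applied independently per observation.
Defaults describe one realistic vessel: 4 L, sampled at 0 and 24 h,
ambient NH~4~^+^ 10 µmol L^−1^ with 2 µmol L^−1^ tracer (F ≈ 0.167), true
nitrification rate 100 nmol L^−1^ h^−1^, true N~2~O production
5 pmol N L^−1^ h^−1^, initial NO~x~^−^ ^15^N fraction at natural abundance
(0.00366, toggleable). All randomness is seeded; zero-noise output is
exact, which is what makes the 10^−9^ recovery tests meaningful.

What the simulator does *not* emulate: microbial growth dynamics,
headspace–liquid exchange kinetics, O~2~ dynamics, pool dilution, or any
site-to-site heterogeneity beyond the configured noise. Passing the
recovery tests therefore demonstrates the correctness of the estimators
under their own assumptions — not that field data meet those assumptions.
Field-measured response magnitudes depend on samples and supplementary
tables not shipped here and are covered procedurally (the same computation
on synthetic data), never asserted numerically.

# Pipeline and problem sizes

`run_pipeline()` chains simulate → rates → response → upscale with all
randomness derived from one run seed (per-vessel seeds spawned
deterministically), writes full-precision CSVs, a JSON report and a run
manifest (package version, config echo, config MD5), and is byte-identical
across runs with the same seed. Its default generating curve
(−40 ΔpH − 60 ΔpH², percent) is confined to levels ≤ 0.75 where the
implied true rate stays positive; `simulate_dose_response()` accepts the
full 0.10–1.05 level span since it draws percent changes directly.

Validation problem sizes were chosen to characterize the estimators well
while keeping the suite quick to run routinely: 100-point solver
consistency grids, 50 brute-force oracle comparisons, a 500-seed
dose–response recovery study (3 replicates × 5 levels, CV 10 %, requiring
coefficient recovery within 3 fitted SEs in ≥ 95 % of fits), and 10^4^–10^5^
Monte-Carlo draws checked against a numeric clipped-normal expectation.

# Known limitations

* No nutrient alkalinity, pressure correction, freshwater constant sets,
  or pH scales beyond NBS/SWS; numeric parity with any particular CO2SYS
  option set is not asserted.
* The mixing model is two-endmember and SP-only; three-endmember or
  SP × δ^18^O mapping is out of scope.
* The upscaling propagates only the low/high response range — no
  distributional uncertainty, no spatial resolution.
* The printed N~2~O estimator's (2 − F) factor is documented, not
  adjudicated: users comparing absolute N~2~O rates across studies should
  state which estimator they used.
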