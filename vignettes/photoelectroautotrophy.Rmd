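---
title: "Evaluating photo-electro-autotrophic pathway designs in the E. coli core network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating photo-electro-autotrophic pathway designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbfix)
```

## The design problem

A heterotroph such as *E. coli* can in principle be converted into an
anaerobic photo-electro-autotroph by combining three engineered subsystems:

1. a **carbon fixation cycle** that builds pyruvate (and from it all biomass
   precursors) out of CO2/HCO3-;
2. an **electron uptake system** that regenerates intracellular electron
   donors (NADPH and reduced ferredoxin) from an external electron source
   (cathode, formate, H2), modeled generically as an exchange of
   extracellular electrons `e_e` plus two regeneration reactions
   (`2 e- + H+ + NADP+ -> NADPH`; `e- + Fd_ox -> Fd_red`). NADH is never
   regenerated directly -- the native transhydrogenase converts NADPH;
3. a **proton-pumping rhodopsin (PPR)** photosystem for ATP: because the
   core network has no periplasm, the pump is a single translocation
   `H+(cytoplasm) -> H+(medium)`, capped at 0-50 mmol H+/gCDW/h (light
   enters the model only through this cap). The native ATP synthase then
   recovers the proton motive force at 4 H+ per ATP.

`carbfix` implements this design space over the published core metabolic
network of *E. coli* (95 reactions, 72 metabolites, shipped as a plain-text
fixture) and six fixation pathways: the Calvin cycle, the reductive TCA
cycle (rTCA), the 3-hydroxypropionate-4-hydroxybutyrate cycle (3HP-4HB, run
anaerobically with pyruvate synthase assimilation), the
dicarboxylate-4-hydroxybutyrate cycle (DC-4HB), and two synthetic
pyruvate-synthase bicycles with a glyoxylate assimilation loop
(PyrS-PyrC-Glx and PyrS-PEPC-Glx).

```{r pathways}
pathway_names()
get_pathway("rtca")
```

## Scenario models and flux balance analysis

`build_scenario()` extends the core model with the pathway's missing
reactions and the energy module, closes oxygen and glucose exchanges,
leaves CO2 uptake unconstrained, and (by default) closes every carbon
exchange except CO2 so that no reduced by-product can be secreted --
by-product formation otherwise siphons electrons into acetate/formate
export for extra ATP. Blocking is done by closing exchanges rather than
deleting internal reactions: it matches the stated intent with minimal
model surgery, and at the optimum the secretion fluxes are zero either way.

Two maintenance scenarios are studied: the standard non-growth-associated
maintenance (NGAM) of 8.39 mmol ATP/gCDW/h and a low estimate of 1.00
typical of anaerobic electro-autotrophs. NGAM is the lower bound of the
ATP maintenance reaction; the growth-associated maintenance (59.81 mmol
ATP/gCDW) sits inside the biomass reaction.

```{r fba}
core <- load_core_model()
sm <- build_scenario(core, scenario_config("rtca", ngam = 1.00,
                                           ppr_upper_bound = 50))
sol <- maximize_growth(sm)
sol
uptake_summary(sol)
```

Growth is ATP-limited: sweeping the PPR cap shows growth is only possible
above a threshold pumping rate that covers the maintenance through the
4 H+/ATP synthase -- 4 x NGAM, i.e. 34.0 (high NGAM) and 4.0 (low NGAM)
mmol H+/gCDW/h on a 0.5-unit grid:

```{r sweep}
sw <- sweep_ppr(core, scenario_config("rtca", ngam = 8.39),
                grid = seq(30, 40, by = 0.5))
attr(sw, "threshold")
```

The linear programs are solved by a package-internal deterministic
two-phase simplex (dense tableau, Dantzig pivoting with a Bland fallback,
final re-solve of the basic system against the original data). It is
exercised against an exhaustive basis-enumeration oracle and closed-form
planted optima in the test suite; repeated runs are bit-identical, which
makes the full report reproducible byte for byte.

Flux variability analysis (`flux_variability()`) probes degeneracy at the
optimum. As in the study, the exchange fluxes (CO2, electrons) have
zero-width ranges; only futile side cycles vary. A structural consequence
worth noting: with CO2 the sole carbon source and `e_e` the sole electron
source, both uptakes per unit biomass are fixed by the biomass composition
alone (~42.5 mmol CO2 and ~174.8 mmol e- per gCDW) and are therefore
identical across pathways -- pathways differ in growth *rate* because they
differ in ATP demand, not in yield per carbon.

## ATP accounting

`precursor_atp_costs()` traces the ATP embodied in each of the twelve
biomass precursors from inorganic carbon along the reactions active in the
FBA solution. Each active reaction passes the cost of its carbon substrates
plus its own ATP expenditure to its carbon products, allocated by carbon
share; CoA moieties are excluded from the carbon counts (acetyl-CoA carries
2 carbons, not 23); AMP-forming synthetases count 2 ATP; ATP made by
substrate-level phosphorylation on a route (e.g. pyruvate kinase in the
Calvin scenario) is credited. Cycles need no special treatment: the
allocation equations of a cycle are coupled and resolve to its per-turn net
ATP stoichiometry. Metabolites produced by several active reactions get the
flux-weighted mean cost; on request (`check_unique = TRUE`) an FVA check
refuses to attribute costs when the producing routes are degenerate.

```{r atp}
costs <- precursor_atp_costs(sol, sm)
round(costs, 2)
total_atp_per_biomass(costs, sm)
```

The totals reproduce the published span -- about 124 (rTCA) to 238
(Calvin) mmol ATP/gCDW including the GAM -- and anticorrelate with the FBA
growth rates across the six pathways.

## Thermodynamics: max-min driving force

`mdf()` maximizes the smallest driving force -ΔrG' over metabolite
log-concentrations: a linear program `max B` subject to
`-ΔrG'0 - δ - RT Σ s ln c >= B`, concentration ranges (1 µM-10 mM by
default), fixed concentrations (CO2 0.3 mM, HCO3- 7 mM, Pi 10 mM, PPi
1 mM, CoA 1 mM) and exact cofactor ratios in log space (ATP/ADP 10,
ADP/AMP 1, NADPH/NADP+ 10, NADH/NAD+ 0.1, Fd_red/Fd_ox 10). Water and
protons live inside the transformed energies and are never concentration
variables. Reactions are taken exactly as written -- no normalization of
stoichiometric coefficients. With `use_uncertainty = TRUE` each reaction
energy may shift by at most one standard error of its estimate; this is a
deliberate simplification of the full covariance treatment of
component-contribution uncertainties (independent slack per reaction), and
it is the default in `run_full_report()` because the ferredoxin-coupled
carboxylations of the rTCA cycle are only feasible under it. The pure-LP
formulation replaces sequential least-squares optimization: the optimum is
identical, deterministic, and needs no initialization.

The packaged ΔrG'0 table (`thermo_reactions_synthetic.tsv`) is a
**synthetic reconstruction**: values anchored on standard reference
energies (phosphoanhydride and thioester hydrolysis, two-electron redox
potentials, textbook pathway energies) at pH 7.5 and ionic strength 0.2 M,
with component-contribution-scale standard errors. Regenerating it against
a Gibbs-energy estimation service is the intended upgrade path; until
then, absolute MDF values are fixture-dependent and only the qualitative
pattern is load-bearing: all six pathways are feasible (MDF > 0) at
standard conditions, and the 3HP-4HB and DC-4HB cycles are the most
favorable. For the fumarate reductase of the rTCA-family cycles the thermo
table assumes an NAD(H)-level donor; the ubiquinol-dependent native
reaction used in the flux model would render that single step endergonic.
Other pH values (grid 5.0-9.0) are derived by a first-order proton-release
slope per reaction.

```{r mdf}
res <- mdf(thermo_table("rtca"), use_uncertainty = TRUE)
res
mdf_sensitivity("rtca", "fd_ratio", grid = c(0.5, 10),
                use_uncertainty = TRUE)
```

The sensitivity sweep reproduces the study's qualitative findings: the
ferredoxin-dependent cycles (rTCA in particular) lose feasibility when the
Fd_red/Fd_ox ratio drops to 0.5, and the Calvin cycle's standing depends
strongly on the NADH/NAD+ ratio because its reductive step uses the native
NADH-linked glyceraldehyde-3-phosphate dehydrogenase (an NADPH variant is
selectable with `thermo_table("calvin", gapd_nadph = TRUE)`).

## Kinetics and protein burden

The flux-force efficacy `ffe(B)` = (e^(B/RT)-1)/(e^(B/RT)+1) converts the
MDF into the net-forward fraction of flux through the bottleneck reaction.
All thermodynamic arithmetic, including FFE, defaults to 298.15 K: the
published two-decimal FFE values are consistent with 298.15 K (e.g. 0.73
for a driving force of 4.61 kJ/mol) and not with 310.15 K; the latter
remains selectable via `thermo_settings(310.15)`. One published value
(0.82 at 5.66 kJ/mol) is not reproducible at either temperature -- Eq-level
evaluation gives 0.815, one unit in the last printed digit away.

The pathway specific activity `psa()` = 1/Σ(w_i/V_i) composes enzyme
specific activities V_i (µmol/mg/min, saturation assumed for all
substrates including the carbon species) with their per-pyruvate
stoichiometric coefficients w_i. Specific activities for the
ferredoxin-oxidoreductases come from BRENDA-style observation collections
aggregated by `aggregate_specific_activity()`: sort, discard the lower 50%
and upper 10% (floors, so n < 2 discards nothing), average the rest. The
packaged collections are synthetic but the aggregation rule is exact and
hand-verified.

Protein burden converts a flux F (mmol/gCDW/h) and an activity into the
protein mass fraction needed to carry it: `PB = (F·1000/60)/(n·SA)`
mg/gCDW, with n an explicit stoichiometric divisor (3 carbons per pyruvate
for a fixation pathway; the published formate-dehydrogenase burden of
23.8% corresponds to n = 1 despite the stated 2 e-/formate, so n is left
to the caller). At the maximal pumping rate the PPR alone costs 8.1% of
cell dry weight (~16% of a proteome that is 50% of CDW) and ~500,000
pumps per cell -- the central engineering bottleneck identified by the
analysis.

```{r burden}
sa <- specific_activity_from_turnover(300, 29)  # proteorhodopsin, kDa
protein_burden(50, n = 1, activity = sa)$percent_cdw
molecules_per_cell(50, 300)
```

## The integrated report

```{r report}
rep <- run_full_report()
knitr::kable(rep[, 1:7], digits = 3)
```

## Synthetic fixtures and what the tests show

Every optimizer is tested against independently constructed answers:
energy-coupled toy FBA models with the closed-form optimum
`(ppr/k - ngam)/a`; linear thermodynamic chains whose equal-partition MDF
is known analytically and which are also compared against brute-force grid
search (0.01 log-unit grid); activity collections carrying their own
hand-evaluated trimmed mean. Generation never solves with the engine under
test. These fixtures emulate the *structure* of the real problems, not
their biology: passing them demonstrates correct optimization and
accounting, while agreement with the published growth rates, thresholds
and ATP totals (test-acceptance.R) validates the network reconstruction
itself. What they cannot show is the accuracy of the synthetic ΔrG'0 and
specific-activity fixtures -- those are reconstructions, and the absolute
MDF/PSA columns of the report inherit their uncertainty.

## Numerical choices and problem sizes

Simplex pivot tolerance 1e-9, optimality tolerance 1e-9 on reduced costs,
Bland's rule after 4000 iterations; scenario LPs have ~115 variables and
solve in tens of milliseconds, so a full two-scenario, six-pathway report
takes under a second and a 101-point PPR sweep about two seconds. FVA
pins growth with a 1e-9 slack; ranges wider than 1e-6 are reported as
variable. MDF bottlenecks are all reactions within 1e-6 kJ/mol of the
optimum. The test suite uses 100-seed property sweeps for the MDF oracle
and 50 for the FBA oracle, sized to run in seconds.

## Known limitations

- Two compartments only; periplasmic chemistry (and photon flux) is outside
  the model by construction.
- The published rTCA electron uptake (35.7 mmol e-/gCDW/h) is internally
  inconsistent with its growth rate (0.209 h^-1) given the fixed
  electron-per-biomass ratio of the core network; the package reports the
  structurally consistent 36.5.
- ΔrG'0 and specific-activity fixtures are synthetic reconstructions
  (labelled so in their filenames); absolute MDF and PSA values should be
  re-derived from a Gibbs-energy service and curated activity data before
  being used quantitatively.
- No aerobic or nitrate-respiring scenarios, no parsimonious or dynamic
  FBA, no Km-level saturation kinetics.
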