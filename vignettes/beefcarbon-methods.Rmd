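---
title: "Methods: whole-farm beef GHG accounting in beefcarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-farm beef GHG accounting in beefcarbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beefcarbon)
```

## Scope and model structure

`beefcarbon` computes the cradle-to-farm-gate carbon footprint of beef
farming systems: all greenhouse-gas emissions arising up to the point
cattle leave the farm, including the embedded emissions of purchased
inputs, but excluding processing and excluding the upstream burden of
purchased cattle. The system boundary follows the structure common to
national whole-farm/LCA tools: on-farm sources (enteric CH4; manure CH4
and N2O in storage and at pasture; soil N2O from applied N; indirect
N2O via volatilization and leaching; lime CO2) and off-farm sources
(fertilizer manufacture, concentrate production, electricity and fuel
chains), with carbon sequestration by grassland and hedgerows as a
separate sink term. Purchased cattle contribute only the emissions of
their residence time on the farm, mirrored on the output side by a
functional unit of live-weight gain (LWG) that subtracts purchased
weight.

One farm-year is a snapshot: the package does not simulate herd
demography over time, soil-carbon dynamics, or non-GHG impact
categories.

### Emission equations

All quantities are carried in SI base units (kg, ha, m, MJ, L, kWh,
year); percentages are on the 0–100 scale.

* **Enteric CH4, tier 2**: `GEI × (Ym/100) × 365 / 55.65` kg
  CH4/head/yr, where GEI is gross energy intake (MJ/head/day) and
  55.65 MJ/kg is the energy content of methane. `Ym` defaults to 6.5%
  of GEI for roughage-based diets; the Spanish-flavoured set uses 6.0%
  reflecting concentrate-heavy finishing diets.
* **Enteric CH4, per-head table**: national tier-3 style factors in kg
  CH4/head/yr by animal category. The packaged French-flavoured table
  is a placeholder calibrated only to exceed the tier-2 output for
  cohorts within the generator's intake bounds, reproducing the
  qualitative between-tool difference rather than any published table.
* **Manure CH4**: `VS × 365 × B0 × 0.67 × MCF/100` per head, with B0 =
  0.17 m³ CH4/kg VS and 0.67 kg/m³ the density of methane. The housed
  fraction of the year (days_housed/365) is split across storage
  systems by the farm's manure-system shares renormalized over the
  non-pasture systems; the grazing fraction uses the pasture MCF and is
  reported under `grazing_returns`, keeping `manure_storage` strictly
  housed.
* **Manure and soil N2O**: storage N2O-N = housed-period N excretion ×
  EF3(system); pasture deposition = Nex × (days_grazing/365) × EF3_prp
  (0.02); applied N (synthetic fertilizer, and spread manure N taken as
  the housed-period excretion with no storage-loss netting) × EF1
  (0.01); indirect N2O-N = volatilized N × EF4 (0.01) + leached N × EF5
  (0.0075), with Frac_gas 0.10 for synthetic N and 0.20 for manure N,
  Frac_leach 0.30 for both. N2O-N converts to N2O by 44/28.
* **CO2 and embedded CO2e**: lime × 0.44 kg CO2/kg; diesel, electricity,
  fertilizer manufacture and concentrate factors are only available
  pre-aggregated in CO2e, so those inventory entries carry a
  `co2e_preaggregated` flag and are weighted by 1 during GWP
  aggregation rather than re-weighted as CO2.

The IPCC loss-factor defaults above are packaged configuration, not
hard-coded: the point of the framework is that region-specific factor
sets are pluggable, and every factor can be overridden in a YAML/JSON
config file.

### Aggregation, functional units and allocation

Gas masses aggregate to CO2 equivalents with 100-year GWP weights
standardized to 25 (CH4), 298 (N2O) and 1 (CO2). The net footprint is
the gross total less sequestration; sequestration is never netted
inside the inventory so both are always reportable, and a negative net
total (sink exceeding gross) is flagged rather than clamped — clamping
would hide information.

`LWG = (LW sold + closing stock) − (LW purchased + opening stock)`.
A footprint is undefined (and errors) when LWG ≤ 0. Beef-only farms
allocate all emissions to live weight (`beef_fraction = 1`); a smaller
fraction supports dairy co-production, and purchased dairy calves enter
with zero embedded burden by the boundary rule. Footprints are reported
per kg LWG (primary basis), per kg LW sold, and per kg carcass weight.
The carcass-weight basis divides the *per-LW-sold* footprint by the 55%
dressing percentage, since dressing applies to marketed animals; per-kg
LWG and per-kg CW are therefore not interconvertible on farms with
large purchased inflows, and both are reported.

## Comparison harness

`compare_ef_sets()` evaluates every factor set on every farm; failed
cells (e.g. zero LWG) are recorded and excluded pairwise, never
imputed. `pairwise_mean_diff()` is the mean over common farms of the
footprint difference, signed so that a positive value means the first
set estimates higher. Ranking agreement is quantified with Kendall's
tau on within-set farm rankings; ties are broken by farm order in the
table (making tau-a and tau-b coincide), and the implementation
(`stats::cor` on tie-broken ranks) is cross-checked in the test suite
against brute-force pair enumeration. A "mixed-model" ranking — each
farm scored by a different set, cycling through the sets — is also
reported to demonstrate that mixing tools across farms destabilizes
rankings even when each tool ranks farms consistently.

## Mitigation engine

Measures act through exactly one mechanism. *Parameter overrides*
re-run the engine with named parameters replaced (e.g. `ym = 4.9` for a
ration methane suppressant, `seq_rate_grassland` for grassland
preservation, `hedgerow_length` for hedgerow planting); in a stacked
plan, overrides apply jointly with last-writer-wins per parameter and a
logged note on conflicts. *Intensity deltas* rescale the named gas
masses of the affected sources by a percentage; deltas hitting the same
(source, gas) combine multiplicatively by default, so stacked
reductions on one source can never exceed 100% — the package's reading
of the warning that measures acting on the same source are not
additive. An additive-capped rule is available for sensitivity
analysis. Per-measure contributions are reported as sequential marginal
reductions, which depend on measure order; under the multiplicative
rule the total does not (a tested invariant). LWG is held fixed unless
a measure overrides the weight-flow fields, so reductions are
reductions in emission intensity.

The packaged catalogue encodes four measure families — animal
performance and diet, soil and land use, manure, energy — with per-gas
signs and uncertainty flags. Magnitudes are illustrative configuration
values chosen once so that the families rank in that order of
mitigation potential, no single measure reaches the 15% reduction
target on the reference archetypes, and the stacked plan exceeds it.
The feed additive is modelled as an override capping Ym at 4.9% of
gross energy intake (below the 5% bound reported for such additives)
and is restricted to housed finishing systems, where ration-delivered
additives are practical. `evaluate_target()` compares a scenario's
percentage reduction in net footprint per kg LWG against the 15%
project target.

## Synthetic farm generator

The generator emulates the *structure* of a 20-farm, four-country
case-study panel (five farms per country): Ireland with one farm of
each of the five systems; France with two suckler-to-weaning, two
suckler-to-beef and one fattening farm; Italy with four intensive
maize-based fattening farms and one suckler-to-beef; Spain with three
suckler-to-beef farms with purchases and two very small (< 5 ha)
intensive fattening units. Each archetype is a set of uniform low/high
bounds on areas, headcounts, weights, intakes, N rates, concentrate use
and grazing days; sampling is uniform and independent within bounds
(the simplest model consistent with the archetype descriptions — no
correlation structure). Category-level biology (GEI, N excretion,
volatile solids, live weights, daily gains) uses bounds typical of
western-European suckler and finishing cattle; Irish systems graze
longest (210–250 days), continental fattening units are essentially
housed year-round. Suckler-to-weaning archetypes carry a fixed
8-month sale age, with sold weight derived as birth weight plus
pre-weaning gain over that age.

Bounds were calibrated once, by inspection of the generated suite, so
that footprints land in the plausible published range for
developed-country beef (roughly 7–24 kg CO2e/kg LWG gross; suckler
systems ~19–43 kg CO2e/kg CW), system medians order weaning ≥
suckler-to-beef ≥ fattening, and enteric fermentation is the largest
source on grass-based suckler farms — the qualitative pattern national
tools report. This is not a reconstruction of any published farm panel:
real activity data show correlations (stocking rate with N rate,
intake with weight) and climate/soil covariates the generator omits,
so passing tests demonstrate the engine's arithmetic and the
framework's structural behaviour, not predictive accuracy on real
farms.

Determinism: `generate_suite(seed)` draws 20 sub-seeds from the given
seed and generates each farm under `withr::with_seed`, so identical
seeds give bit-identical farms and suites.

## Numerical and interface choices

* Constants: CH4 energy density 55.65 MJ/kg, N2O-N→N2O 44/28, dressing
  55%, methane density 0.67 kg/m³.
* Validation is data-first: `validate_farm()` returns a findings table
  (farm, field, rule) instead of raising; engine entry points abort
  with the full findings list. Manure shares must sum to 1 within
  1e-9; cohort grazing + housing days must equal 365.
* Zero-livestock or zero-input farms yield explicit all-zero
  inventories on a fixed source–gas grid (no missing rows), and a
  zero-gross inventory makes the emission profile an error rather than
  a division by zero.
* Serialization: factor sets round-trip bit-exactly (JSON at 17
  significant digits; YAML with named vectors as maps). Reports are
  written at 4 significant digits with deterministic column order, so
  identical configs and seeds give byte-identical reports.
* If a farm's housed manure shares are all zero while animals are
  housed, housed-system emissions are zero (the herd is treated as
  effectively year-round pasture); the validator flags shares that do
  not sum to 1 before this can occur silently.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: the 20-farm reference suite (seed 42) for footprint, comparison
and mitigation checks, 100 generated farms for the inventory
equivalence check, and three independent 20-farm suites for the
conservation/normalization property suite. These sizes keep the full
run to a few minutes while exercising every archetype.

## Known limitations

* Enteric and manure parameters are diet-invariant within a factor
  set; diet quality enters only through GEI, VS and the per-set Ym.
* Spread-manure N is not netted for storage losses before EF1 is
  applied, a slight overestimate of the spreading pathway.
* Sequestration is a fixed per-area/per-length rate (defaults 250 kg
  CO2e/ha/yr grassland, 1.25 kg CO2e/m/yr hedgerow, chosen
  conservatively); no dynamic soil-carbon model, no saturation.
* The mitigation catalogue's magnitudes are design values for the
  framework, not measured abatement potentials; analyses of real
  programmes should replace the catalogue config with locally
  estimated values.
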