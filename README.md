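# beefcarbon

Cradle-to-farm-gate greenhouse-gas accounting for beef farming systems,
for researchers and advisors who need to quantify, compare and reduce
the carbon footprint of beef production across regions.

Beef farms emit methane from enteric fermentation and manure, nitrous
oxide from manure and fertilized soils, and carbon dioxide from lime,
fuel and the embedded emissions of purchased inputs (fertilizer,
concentrate feed, electricity). National carbon-footprint tools account
for the same sources but with region-specific emission factors, so the
same farm gets different footprints under different tools. `beefcarbon`
implements a common accounting engine with *pluggable emission-factor
sets*, a harness to compare those sets on the same farms, and a
mitigation-scenario engine evaluated against a 15% footprint-reduction
target.

## The accounting model

For each farm-year the engine computes per-source, per-gas masses:

- **Enteric CH4** — IPCC tier-2, `CH4 = GEI × (Ym/100) × 365 / 55.65`
  kg/head/yr from gross energy intake (MJ/d) and the methane conversion
  factor Ym (% of GEI), or a per-head table (tier-3 style) depending on
  the factor set;
- **Manure CH4** — `VS × 365 × B0 × 0.67 × MCF/100`, with the year
  split between pasture and housed storage systems;
- **Manure, soil and grazing N2O** — the EF3 (storage), EF1 (applied N),
  EF3_prp (pasture deposition) chain plus indirect N2O from
  volatilization (Frac_gas × EF4) and leaching (Frac_leach × EF5),
  converted by 44/28;
- **CO2 and embedded CO2e** — lime, diesel, electricity, fertilizer
  manufacture and concentrate production (off-farm factors carried as
  pre-aggregated CO2e).

Masses are aggregated with GWP100 weights standardized to 25 (CH4),
298 (N2O) and 1 (CO2). The functional unit is live-weight gain:
`LWG = (LW sold + closing stock) − (LW purchased + opening stock)`, so
purchased cattle carry no upstream burden. Results are reported gross
and net (`net = gross − sequestration` by grassland and hedgerows), per
kg LWG, per kg LW sold, and per kg carcass weight using a 55% dressing
percentage.

Three region-flavoured factor sets ship with the package: `IE_style`
(tier-2 enteric, grass-system defaults), `FR_style` (higher per-head
enteric factors), `ES_style` (lower Ym, higher concentrate factors).
All factors are plain YAML/JSON config and fully overridable.

## Worked example

```r
library(beefcarbon)

suite <- generate_suite(seed = 42)       # 20 synthetic case-study farms
fp <- farm_footprint(suite, "IE_style")  # footprints under the Irish-style set
fp[1:5, c("farm_id", "system", "gross_per_lwg", "net_per_lwg", "per_cw")]
#>   farm_id system              gross_per_lwg net_per_lwg per_cw
#> 1 IE1     suckler_to_beef             14.9        14.1   27.1
#> 2 IE2     suckler_to_weaning          23.5        21.9   42.8
#> 3 IE3     dairy_calf_to_beef          10.0         9.41  16.6
#> 4 IE4     dairy_calf_to_store         11.3        10.6   17.7
#> 5 IE5     beef_fattening               8.40        8.01   3.38
```

Gross footprints are kg CO2e per kg live-weight gain: the
suckler-to-weaning farm is highest (a full cow herd amortized over
weanling output), fattening lowest. `per_cw` relates gross emissions to
carcass weight sold. Comparing factor sets on the same farms:

```r
cmp <- compare_ef_sets(suite, list("IE_style", "FR_style", "ES_style"))
pairwise_mean_diff(cmp, "IE_style", "FR_style")  # -2.18 kg CO2e/kg LWG
pairwise_mean_diff(cmp, "IE_style", "ES_style")  # +0.01 kg CO2e/kg LWG
ranking_concordance(cmp)                         # Kendall tau 0.86-0.93
```

The Irish-style set estimates lower footprints than the French-style
set (whose per-head enteric factors run higher) and marginally higher
than the Spanish-style set; farm *rankings* agree closely within any
one set but degrade when a mixture of sets is applied. Mitigation:

```r
sc <- stack_plan(suite, "IE_style", default_plan())
glance(sc)   # median net-footprint reduction 26.7% (range 24.4-32.6%)
evaluate_target(sc, target_pct = 15)  # all 20 farms pass
```

No single catalogue measure reaches 15% on its own (the largest,
a ration methane suppressant capping Ym below 5% of GEI, achieves about
10%); the stacked plan comfortably exceeds the target.

Each result type has `autoplot()`, `tidy()` and `glance()` methods, and
a command-line interface (`inst/cli/beefcarbon`) exposes `simulate`,
`footprint`, `compare` and `mitigate` subcommands over farm files.

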