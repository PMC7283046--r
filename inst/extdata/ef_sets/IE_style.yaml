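# Irish-flavoured emission-factor set: IPCC tier-2 enteric methane from
# gross energy intake, grass-system defaults elsewhere.
name: IE_style
enteric_mode: tier2
ym: 6.5
b0: 0.17
mcf:
  slurry_tank: 17
  solid_storage: 4
  pasture_deposition: 1
ef3_storage:
  slurry_tank: 0.005
  solid_storage: 0.005
ef3_prp: 0.02
ef1: 0.01
frac_gas_synthetic: 0.10
frac_gas_manure: 0.20
frac_leach: 0.30
ef4: 0.01
ef5: 0.0075
ef_lime: 0.44
ef_fert_manufacture: 6.0
ef_concentrate:
  cereal_mix: 0.75
  protein_mix: 1.1
  maize_meal: 0.65
  compound_feed: 0.85
  milk_replacer: 1.6
ef_diesel: 2.67
ef_electricity: 0.45
seq_rate_grassland: 250
seq_rate_hedgerow: 1.25
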