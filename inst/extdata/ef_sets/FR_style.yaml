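# French-flavoured emission-factor set: national per-head enteric methane
# factors (tier-3 style), which run higher per animal than the tier-2
# energy-intake equation for comparable cattle. Other factors shared with
# the Irish-flavoured set so the sets differ only in the dimensions that
# diverge between the underlying national tools.
name: FR_style
enteric_mode: per_head_table
ym: 6.5
per_head_enteric:
  suckler_cow: 100
  dairy_origin_calf: 30
  weanling: 45
  store: 65
  finishing_bull: 75
  finishing_steer: 72
  finishing_heifer: 60
  breeding_bull: 110
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
ef_fert_manufacture: 6.2
ef_concentrate:
  cereal_mix: 0.8
  protein_mix: 1.15
  maize_meal: 0.7
  compound_feed: 0.9
  milk_replacer: 1.6
ef_diesel: 2.67
ef_electricity: 0.4
seq_rate_grassland: 250
seq_rate_hedgerow: 1.25
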