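# Packaged mitigation-measure catalogue. Four measure families with
# per-gas signs; magnitudes are illustrative configuration values chosen
# so that family potentials rank animal performance & diet > soil & land
# use > manure > energy, no single measure reaches the 15% net-footprint
# reduction target on the reference archetypes, and the stacked plan
# exceeds it. Measures flagged 'uncertainty' carry high uncertainty in
# the achievable reduction.
measures:
  - name: improved_genetic_merit
    category: animal_performance_diet
    mechanism: intensity_delta
    deltas: {CH4: -7, N2O: -5, CO2: -2}
    affected_sources: [enteric, manure_storage, manure_spreading, grazing_returns]
    applicable_systems: all
  - name: improved_animal_health
    category: animal_performance_diet
    mechanism: intensity_delta
    deltas: {CH4: -6, N2O: -6, CO2: -3}
    affected_sources: [enteric, manure_storage, manure_spreading, grazing_returns]
    applicable_systems: all
  - name: feed_additive_ch4_suppressant
    category: animal_performance_diet
    mechanism: parameter_override
    # caps the methane conversion factor below 5% of gross energy intake;
    # delivered in the ration, so applicable to housed finishing systems
    overrides: {ym: 4.9}
    applicable_systems: [beef_fattening, dairy_calf_to_beef]
    uncertainty: true
  - name: improved_forage_quality
    category: animal_performance_diet
    mechanism: intensity_delta
    deltas: {CH4: -5, N2O: -3}
    affected_sources: [enteric, grazing_returns]
    applicable_systems: all
  - name: low_carbon_concentrate_sourcing
    category: animal_performance_diet
    mechanism: intensity_delta
    deltas: {CO2: -20}
    affected_sources: [concentrate]
    applicable_systems: all
  - name: white_clover_swards
    category: soil_land_use
    mechanism: intensity_delta
    deltas: {N2O: -20, CO2: -20}
    affected_sources: [soil_fertilizer, fert_manufacture, indirect_n]
    applicable_systems: all
    uncertainty: true
  - name: protected_urea_fertilizer
    category: soil_land_use
    mechanism: intensity_delta
    deltas: {N2O: -12}
    affected_sources: [soil_fertilizer, indirect_n]
    applicable_systems: all
    uncertainty: true
  - name: preserve_permanent_grassland
    category: soil_land_use
    mechanism: parameter_override
    overrides: {seq_rate_grassland: 350}
    applicable_systems: all
    uncertainty: true
  - name: hedgerow_maintenance_planting
    category: soil_land_use
    mechanism: parameter_override
    # maintain and plant hedgerows up to a reference stock of 4 km
    overrides: {hedgerow_length: 4000}
    applicable_systems: all
  - name: slurry_store_cover
    category: manure
    mechanism: intensity_delta
    deltas: {CH4: -15, N2O: -10}
    affected_sources: [manure_storage]
    applicable_systems: all
  - name: low_emission_slurry_spreading
    category: manure
    mechanism: intensity_delta
    deltas: {N2O: -15}
    affected_sources: [manure_spreading, indirect_n]
    applicable_systems: all
  - name: renewable_electricity
    category: energy
    mechanism: intensity_delta
    deltas: {CO2: -30}
    affected_sources: [energy]
    applicable_systems: all
  - name: fuel_efficient_machinery
    category: energy
    mechanism: intensity_delta
    deltas: {CO2: -10}
    affected_sources: [energy]
    applicable_systems: all
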