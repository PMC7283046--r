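# Small fixtures built in code: a bare emission-factor set whose factors
# are easy to hand-evaluate, and minimal farms for unit arithmetic.

test_efs <- function(...) {
  defaults <- list(
    name = "test",
    enteric_mode = "tier2", ym = 6.5,
    b0 = 0.17,
    mcf = c(slurry_tank = 17, solid_storage = 1, pasture_deposition = 1),
    ef3_storage = c(slurry_tank = 0.005, solid_storage = 0.005),
    ef3_prp = 0.02, ef1 = 0.01,
    frac_gas_synthetic = 0.10, frac_gas_manure = 0.20,
    frac_leach = 0.30, ef4 = 0.01, ef5 = 0.0075,
    ef_lime = 0.44, ef_fert_manufacture = 6.0,
    ef_concentrate = c(cereal_mix = 0.8, compound_feed = 0.85),
    ef_diesel = 2.67, ef_electricity = 0.45,
    seq_rate_grassland = 700, seq_rate_hedgerow = 1.0
  )
  dots <- list(...)
  # later duplicates win, so wrappers can layer overrides
  if (length(dots)) dots <- dots[!duplicated(names(dots), fromLast = TRUE)]
  do.call(ef_set, utils::modifyList(defaults, dots))
}

# A fully housed single cohort: the simplest unit for source arithmetic.
housed_cohort <- function(headcount = 1, gei = 200, nex = 80, vs = 2.5,
                          days_grazing = 0) {
  animal_cohort("suckler_cow", headcount = headcount,
                avg_live_weight = 600, daily_gain = 0,
                gross_energy_intake = gei, n_excretion = nex,
                volatile_solids = vs, days_grazing = days_grazing)
}

tiny_farm <- function(farm_id = "T1", cohorts = housed_cohort(),
                      shares = c(slurry_tank = 1),
                      grassland_area = 40, lw_sold = 15000,
                      concentrate_fed = c(cereal_mix = 5000),
                      fert_n_applied = 3000, lime_applied = 1000,
                      diesel_used = 2000, electricity_used = 8000,
                      hedgerow_length = 2000, ...) {
  farm_record(farm_id = farm_id, system = "suckler_to_beef",
              grassland_area = grassland_area, cropland_area = 0,
              cohorts = cohorts, lw_sold = lw_sold,
              concentrate_fed = concentrate_fed,
              fert_n_applied = fert_n_applied, lime_applied = lime_applied,
              diesel_used = diesel_used,
              electricity_used = electricity_used,
              manure_system_shares = shares,
              hedgerow_length = hedgerow_length, ...)
}

# Brute-force Kendall tau by pair enumeration: the independent oracle
# for the concordance statistic (no ties assumed).
tau_brute <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    }
  }
  s / (n * (n - 1) / 2)
}
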