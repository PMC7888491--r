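# Shared builders for the test suite; all fixtures are generated in code.

# bundled ingredient GE assays in the ingredient_energy() input schema
rsm_assays <- function() {
  comp <- rsm_composition()
  data.frame(ingredient = comp$ingredient,
             ge_mj_per_kg_dm = comp$ge_mj_per_kg_dm)
}

# zero-noise simulated experiment under the bundled study conditions
zero_noise_sim <- function(seed = 101, ...) {
  generate_experiment(rsm_study_preset(noise = noise_cv(0), seed = seed, ...))
}

# one hand-built pig-period record with fed windows inverted from a known
# daily heat production and a fasted window inverted from a known FHP
toy_record <- function(thp_kj_per_d = 12000, fhp_kj_per_d = 8040,
                       rq_fed = 1.10, rq_fasted = 0.81,
                       fasting_n_g = 8) {
  rec <- data.frame(
    pig_id = "p1", diet_id = "d1", period = 1L, bw_kg = 47.82,
    dm_intake_kg_per_d = 1.30, ge_intake_kj_per_d = 20900,
    fecal_energy_kj_per_d = 2530, urinary_energy_kj_per_d = 400,
    ch4_l_per_d = 50, n_intake_g_per_d = 39.3, fecal_n_g_per_d = 5.0,
    urinary_n_g_per_d = 13.5,
    intake_cp_g_per_d = 245.6, fecal_cp_g_per_d = 31.4)
  fed_gas <- gas_from_heat(thp_kj_per_d, rq_fed, ch4_l = 50,
                           urinary_n_g = 13.5)
  fas_gas <- gas_from_heat(fhp_kj_per_d / 3, rq_fasted, 0, fasting_n_g / 3)
  gas <- data.frame(
    pig_id = "p1", diet_id = "d1", period = 1L, day = c(1L, 2L, 3L),
    state = c("fed", "fed", "fasted"), duration_h = c(24, 24, 8),
    o2_l = c(fed_gas$o2_l, fed_gas$o2_l, fas_gas$o2_l),
    co2_l = c(fed_gas$co2_l, fed_gas$co2_l, fas_gas$co2_l),
    ch4_l = c(50, 50, 0), urinary_n_g = c(13.5, 13.5, fasting_n_g))
  list(records = rec, gas = gas)
}
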