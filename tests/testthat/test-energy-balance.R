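test_that("ATTD is the percentage of intake not excreted", {
  expect_equal(attd(100, 0), 100)
  expect_equal(attd(100, 12.8), 87.2)
  expect_equal(attd(39.3, 5.0), 87.27735, tolerance = 1e-6)
  expect_error(attd(0, 1), "intake")
  expect_error(attd(10, -1), "fecal")
})

test_that("ATTD is scale invariant", {
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 10, 100); b <- runif(1, 0, a); k <- runif(1, 0.1, 50)
    expect_equal(attd(k * a, k * b), attd(a, b))
  }
})

test_that("nitrogen balance subtracts fecal and urinary losses", {
  expect_equal(nitrogen_balance(0, 0, 0), 0)
  expect_equal(nitrogen_balance(39.3, 5.0, 13.5), 20.8)
  expect_equal(nitrogen_balance(46.9, 6.8, 22), 18.1)
  expect_warning(out <- nitrogen_balance(10, 8, 5), "negative")
  expect_equal(out, -3)
})

test_that("retained protein energy applies 6.25 x 23.86 kJ/g on BW^0.6", {
  expect_equal(retained_protein_energy(0, 50), 0)
  expect_equal(retained_protein_energy(20.7, 47.82), 303.218056,
               tolerance = 1e-8)
  # daily basis via unit metabolic weight
  expect_equal(retained_protein_energy(25.3, 1), 3772.8625)
  expect_error(retained_protein_energy(10, 0), "bw_kg")
})

test_that("diet DE and ME account for fecal, urinary and methane losses", {
  # no losses: DE = ME = GE per kg DM
  z <- diet_energy_values(13000, 0, 0, 0, 1.3)
  expect_equal(z$de_mj_per_kg_dm, 10)
  expect_equal(z$me_mj_per_kg_dm, 10)
  v <- diet_energy_values(20900, 2530, 400, 50, 1.30)
  expect_equal(v$de_mj_per_kg_dm, 14.13076923, tolerance = 1e-8)
  expect_equal(v$me_mj_per_kg_dm, 12.30230769, tolerance = 1e-8)
  expect_equal(v$urinary_e_pct_of_de, 2.177463, tolerance = 1e-6)
  expect_error(diet_energy_values(100, 0, 0, 0, 0), "dm_intake")
})

test_that("retained energy and diet NE identities hold", {
  expect_equal(retained_energy(1989, 1214), 775)
  expect_equal(retained_energy(1979, 1207), 772)
  expect_equal(retained_energy(500, 500), 0)
  expect_equal(diet_ne(0, 8040, 1), 8.040)
  expect_equal(diet_ne(7890, 8040, 1.30), 12.25384615, tolerance = 1e-8)
  expect_error(diet_ne(100, 100, 0), "dm_intake")
})

test_that("energy_balance recovers the heat values its windows encode", {
  toy <- toy_record(thp_kj_per_d = 12000, fhp_kj_per_d = 8040)
  pe <- energy_balance(toy$records, toy$gas)
  expect_s3_class(pe, "pig_energy")
  expect_equal(pe$thp_kj_per_d, 12000, tolerance = 1e-10)
  expect_equal(pe$fhp_kj_per_d, 8040, tolerance = 1e-10)
  expect_equal(pe$rq_fed, 1.10, tolerance = 1e-12)
  expect_equal(pe$rq_fasted, 0.81, tolerance = 1e-12)
  # partition arithmetic
  expect_equal(pe$de_mj_per_kg_dm, 14.13076923, tolerance = 1e-8)
  expect_equal(pe$me_mj_per_kg_dm, 12.30230769, tolerance = 1e-8)
  me_int <- pe$me_mj_per_kg_dm * 1.30 * 1000
  expect_equal(pe$re_kj_per_d, me_int - 12000)
  expect_equal(pe$ne_mj_per_kg_dm, (me_int - 12000 + 8040) / 1300)
  # RE split identity and nutrient digestibility
  expect_equal(pe$re_p_kj_per_d + pe$re_l_kj_per_d, pe$re_kj_per_d)
  expect_equal(pe$n_retention_g_per_d, 39.3 - 5.0 - 13.5)
  expect_equal(pe$attd_cp, attd(245.6, 31.4))
  expect_equal(pe$attd_ge, attd(20900, 2530))
})

test_that("FHP policies change which fasting heat enters NE", {
  toy <- toy_record()
  r2 <- toy$records; r2$pig_id <- "p2"
  g2 <- toy$gas; g2$pig_id <- "p2"
  # second pig with a different fasted window (FHP 9000 kJ/d)
  fg <- gas_from_heat(9000 / 3, 0.81, 0, 8 / 3)
  g2[g2$state == "fasted", c("o2_l", "co2_l")] <- fg
  records <- rbind(toy$records, r2)
  gas <- rbind(toy$gas, g2)
  own <- energy_balance(records, gas, fhp_policy = "per-pig")
  expect_equal(own$fhp_kj_per_d, c(8040, 9000), tolerance = 1e-9)
  dm <- energy_balance(records, gas, fhp_policy = "diet-mean")
  expect_equal(dm$fhp_kj_per_d[1], dm$fhp_kj_per_d[2])
  fx <- energy_balance(records, gas, fhp_policy = "fixed", fhp_value = 790)
  expect_equal(fx$fhp_kj_per_d, 790 * metabolic_weight(records$bw_kg))
  expect_error(energy_balance(records, gas, fhp_policy = "fixed"),
               "fhp_value")
})

test_that("summarize_diet averages pigs and keeps the RE split identity", {
  toy <- toy_record()
  pe <- energy_balance(toy$records, toy$gas)
  d1 <- summarize_diet(pe)
  expect_s3_class(d1, "diet_energy")
  expect_equal(d1$n_obs, 1L)
  expect_equal(d1$ne_mj_per_kg_dm, pe$ne_mj_per_kg_dm)
  # several pigs: means respect RE = RE_P + RE_L exactly
  sim <- zero_noise_sim(seed = 5, n_pigs_per_diet = 3)
  des <- summarize_diet(energy_balance(sim$records, sim$gas))
  expect_equal(des$re_p_kj_per_mbw + des$re_l_kj_per_mbw,
               des$re_kj_per_mbw, tolerance = 1e-12)
  expect_true(all(des$de_mj_per_kg_dm >= des$me_mj_per_kg_dm))
  expect_true(all(des$me_mj_per_kg_dm >= des$ne_mj_per_kg_dm))
})

test_that("schema violations are reported with the missing columns", {
  toy <- toy_record()
  bad <- toy$records; bad$bw_kg <- NULL
  expect_error(energy_balance(bad, toy$gas), "bw_kg")
  badg <- toy$gas; badg$o2_l <- NULL
  expect_error(energy_balance(toy$records, badg), "o2_l")
  # records without any fed windows are refused
  nofed <- toy$gas[toy$gas$state == "fasted", ]
  expect_error(energy_balance(toy$records, nofed), "fed gas windows")
})
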