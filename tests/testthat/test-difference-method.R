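test_that("basal mixture energy divides by the mixture DM fraction", {
  expect_equal(basal_mixture_energy(0), 0)
  expect_equal(basal_mixture_energy(12.05), 12.35897436, tolerance = 1e-8)
  expect_equal(basal_mixture_energy(16.08), 16.49230769, tolerance = 1e-8)
  expect_error(basal_mixture_energy(-1), "basal_diet_value")
  expect_error(basal_mixture_energy(10, mixture_fraction = 0), "mixture_fraction")
})

test_that("dm_fractions converts formulations to mixture/test fractions", {
  forms <- rsm_diet_formulations()
  basal <- dm_fractions(forms[forms$diet_id == "basal", ])
  expect_equal(basal$f_mix, 0.975)
  expect_equal(basal$f_test, 0)
  test <- dm_fractions(forms[forms$diet_id == "EP-RSM-1", ])
  expect_equal(test$f_mix, 0.78)
  expect_equal(test$f_test, 0.195)
  # equal DM contents reduce the DM policy to the as-fed fallback
  f <- forms[forms$diet_id == "EP-RSM-1", ]
  f$dm_pct <- 88
  eq <- dm_fractions(f, policy = "dm")
  expect_equal(eq$f_mix, test$f_mix)
  expect_equal(eq$f_test, test$f_test)
  # unequal DM contents shift the fractions
  f$dm_pct <- ifelse(f$role == "test", 93, 87)
  ue <- dm_fractions(f, policy = "dm")
  expect_gt(ue$f_test, 0.195)
  f$dm_pct <- NULL
  expect_error(dm_fractions(f, policy = "dm"), "dm_pct")
  bad <- forms[forms$diet_id == "basal", ]
  bad$as_fed_pct[1] <- 70
  expect_error(dm_fractions(bad), "sum to")
})

test_that("difference method subtracts the mixture contribution", {
  # homogeneous diet: ingredient equals the mixture
  expect_equal(ingredient_by_difference(12, 12, 0.8, 0.2), 12)
  expect_equal(ingredient_by_difference(11.59, 12.05 / 0.975, 0.78, 0.195),
               10, tolerance = 1e-10)
  expect_equal(ingredient_by_difference(15.94, 16.08 / 0.975, 0.78, 0.195),
               15.77435897, tolerance = 1e-8)
  expect_error(ingredient_by_difference(10, 10, 0.8, 0), "f_test")
  expect_warning(ingredient_by_difference(5, 12, 0.8, 0.195), "negative")
})

test_that("a shift in the diet value propagates as delta over f_test", {
  set.seed(11)
  for (i in 1:10) {
    diet <- runif(1, 10, 16); mix <- runif(1, 10, 17)
    f_test <- runif(1, 0.1, 0.3); f_mix <- 1 - f_test - 0.025
    delta <- runif(1, -1, 1)
    base <- suppressWarnings(
      ingredient_by_difference(diet, mix, f_mix, f_test))
    moved <- suppressWarnings(
      ingredient_by_difference(diet + delta, mix, f_mix, f_test))
    expect_equal(moved - base, delta / f_test, tolerance = 1e-10)
  }
})

test_that("ratio chaining multiplies measured GE by the cumulative ratios", {
  u <- ratio_chain(18, 18, 18, 18, 18)
  expect_equal(u$de_final, 18)
  expect_equal(u$ne_final, 18)
  v <- ratio_chain(20, 20, 15, 13.5, 9.72)
  expect_equal(v$de_ge_pct, 75)
  expect_equal(v$me_de_pct, 90)
  expect_equal(v$ne_me_pct, 72)
  expect_equal(v$de_final, 15)
  expect_equal(v$me_final, 13.5)
  expect_equal(v$ne_final, 9.72)
  # reconstruction: finals always satisfy the chained-ratio identity
  set.seed(3)
  ge_m <- runif(5, 18, 22); ge_r <- runif(5, 17, 21)
  de_r <- ge_r * runif(5, 0.6, 0.9); me_r <- de_r * runif(5, 0.85, 0.95)
  ne_r <- me_r * runif(5, 0.65, 0.8)
  w <- ratio_chain(ge_m, ge_r, de_r, me_r, ne_r)
  expect_equal(w$de_final, ge_m * w$de_ge_pct / 100)
  expect_equal(w$me_final, w$de_final * w$me_de_pct / 100)
  expect_equal(w$ne_final, w$me_final * w$ne_me_pct / 100)
})

test_that("non-positive raw values are flagged and left unchained", {
  expect_warning(x <- ratio_chain(20, 20, -1, 10, 8), "unchained")
  expect_true(x$flag_unchained)
  expect_true(is.na(x$de_final))
})

test_that("the difference method recovers planted ingredient values", {
  sim <- zero_noise_sim(seed = 21)
  de <- summarize_diet(energy_balance(sim$records, sim$gas))
  ie <- ingredient_energy(de, rsm_diet_formulations(), rsm_assays())
  ref <- rsm_ingredient_reference()
  ord <- match(ref$ingredient, ie$ingredient)
  expect_equal(ie$de_final[ord], ref$de_mj_per_kg_dm, tolerance = 1e-8)
  expect_equal(ie$me_final[ord], ref$me_mj_per_kg_dm, tolerance = 1e-8)
  expect_equal(ie$ne_final[ord], ref$ne_mj_per_kg_dm, tolerance = 1e-8)
})

test_that("ingredient_energy validates its inputs", {
  sim <- zero_noise_sim(seed = 22, n_pigs_per_diet = 1)
  de <- summarize_diet(energy_balance(sim$records, sim$gas))
  expect_error(ingredient_energy(de, rsm_diet_formulations(), rsm_assays(),
                                 basal_id = "nope"), "basal")
  assays <- rsm_assays()[1, ]
  expect_error(ingredient_energy(de, rsm_diet_formulations(), assays),
               "assay")
})
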