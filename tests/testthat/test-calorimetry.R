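test_that("Brouwer heat production reproduces hand-computed values", {
  w0 <- gas_window(0, 0, 0, state = "fed")
  expect_equal(brouwer_thp(w0), 0)
  expect_equal(brouwer_thp(gas_window(1, 0, 0)), 16.18)
  w <- gas_window(1500, 1650, ch4_l = 4, urinary_n_g = 13.5)
  expect_equal(brouwer_thp(w), 32463.455, tolerance = 1e-12)
  # data-frame input is vectorised
  df <- data.frame(o2_l = c(0, 1, 1500), co2_l = c(0, 0, 1650),
                   ch4_l = c(0, 0, 4), urinary_n_g = c(0, 0, 13.5))
  expect_equal(brouwer_thp(df), c(0, 16.18, 32463.455))
})

test_that("Brouwer value is linear with the printed coefficients", {
  base <- data.frame(o2_l = 800, co2_l = 700, ch4_l = 3, urinary_n_g = 10)
  b0 <- brouwer_thp(base)
  bump <- function(field) {
    d <- base; d[[field]] <- d[[field]] + 1
    brouwer_thp(d) - b0
  }
  expect_equal(bump("o2_l"), 16.18)
  expect_equal(bump("co2_l"), 5.02)
  expect_equal(bump("ch4_l"), -2.17)
  expect_equal(bump("urinary_n_g"), -5.99)
})

test_that("negative gas inputs are rejected naming the field", {
  expect_error(gas_window(-1, 0), "o2_l")
  expect_error(gas_window(1, -2), "co2_l")
  expect_error(brouwer_thp(data.frame(o2_l = 1, co2_l = 1, ch4_l = -1,
                                      urinary_n_g = 0)), "ch4_l")
  expect_error(gas_window(1, 1, duration_h = 0), "duration_h")
  expect_error(gas_window(1, 1, duration_h = 25), "duration_h")
})

test_that("respiratory quotient is CO2 over O2 and needs positive O2", {
  expect_equal(respiratory_quotient(100, 100), 1)
  expect_equal(respiratory_quotient(1650, 1500), 1.10)
  expect_equal(respiratory_quotient(81, 100), 0.81)
  expect_error(respiratory_quotient(100, 0), "o2_l")
})

test_that("methane energy uses the 39.54 kJ/L factor", {
  expect_equal(methane_energy(0), 0)
  expect_equal(methane_energy(1), 39.54)
  expect_equal(methane_energy(4), 158.16)
  expect_error(methane_energy(-1), "ch4_l")
})

test_that("metabolic body weight is BW^0.6", {
  expect_equal(metabolic_weight(1), 1)
  expect_equal(metabolic_weight(47.82), 10.18042112, tolerance = 1e-8)
  expect_equal(metabolic_weight(41.1), 9.296, tolerance = 1e-4)
  expect_error(metabolic_weight(0), "bw_kg")
  expect_error(metabolic_weight(-5), "bw_kg")
})

test_that("fasting heat production extrapolates an 8-h window to 24 h", {
  # gases chosen so the window's gas-exchange heat is exactly 2680 kJ
  w <- gas_window(2680 / 16.18, 0, duration_h = 8, state = "fasted")
  fhp <- fasting_heat_production(w)
  expect_equal(fhp$thp_kj_per_d, 8040)
  # daily fasting urinary N is charged once, not three times
  wn <- gas_window(2680 / 16.18, 0, duration_h = 8, state = "fasted",
                   urinary_n_g = 9)
  expect_equal(fasting_heat_production(wn)$thp_kj_per_d, 8040 - 5.99 * 9)
  # zero-gas window
  w0 <- gas_window(0, 0, duration_h = 8, state = "fasted")
  expect_equal(fasting_heat_production(w0)$thp_kj_per_d, 0)
  # per-metabolic-weight basis
  expect_equal(fasting_heat_production(w, bw_kg = 47.82)$per_mbw,
               8040 / 47.82^0.6)
  expect_error(fasting_heat_production(gas_window(1, 1, state = "fed")),
               "fasted")
})

test_that("fasting heat production scales linearly with 24/duration", {
  vals <- vapply(c(4, 8, 12), function(dur) {
    w <- gas_window(100, 81, duration_h = dur, state = "fasted")
    fasting_heat_production(w)$thp_kj_per_d
  }, numeric(1))
  expect_equal(vals / (24 / c(4, 8, 12)), rep(vals[2] / 3, 3))
})

test_that("gas_from_heat inverts the Brouwer equation", {
  z <- gas_from_heat(0, 1.0)
  expect_equal(unlist(z), c(o2_l = 0, co2_l = 0))
  g <- gas_from_heat(32463.455, 1.10, ch4_l = 4, urinary_n_g = 13.5)
  expect_equal(g$o2_l, 1500, tolerance = 1e-10)
  expect_equal(g$co2_l, 1650, tolerance = 1e-10)
  expect_error(gas_from_heat(100, 0.5), "rq")
  expect_error(gas_from_heat(100, 1.4), "rq")
  expect_error(gas_from_heat(-1, 1.0), "thp_kj")
})

test_that("Brouwer/gas_from_heat round trip holds over random valid inputs", {
  set.seed(42)
  for (i in 1:50) {
    thp <- runif(1, 0, 20000)
    rq <- runif(1, 0.65, 1.25)
    ch4 <- runif(1, 0, 10)
    n <- runif(1, 0, 30)
    g <- gas_from_heat(thp, rq, ch4, n)
    back <- brouwer_thp(data.frame(o2_l = g$o2_l, co2_l = g$co2_l,
                                   ch4_l = ch4, urinary_n_g = n))
    expect_equal(back, thp, tolerance = 1e-10)
    expect_equal(respiratory_quotient(g$co2_l, g$o2_l), rq,
                 tolerance = 1e-12)
  }
})
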