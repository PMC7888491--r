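# Per-pig and per-diet digestibility, nitrogen balance, and energy partition:
# DE, ME, THP, FHP, RE (protein + lipid), NE.

#' Apparent total-tract digestibility
#'
#' @param intake_g_per_d nutrient intake, g/d; strictly positive.
#' @param fecal_g_per_d fecal output of the same nutrient, g/d; non-negative.
#' @return ATTD in percent: `100 * (intake - fecal) / intake`.
#' @export
#' @examples
#' attd(100, 12.8)
attd <- function(intake_g_per_d, fecal_g_per_d) {
  if (any(!is.finite(intake_g_per_d)) || any(intake_g_per_d <= 0))
    stop("'intake_g_per_d' must be strictly positive", call. = FALSE)
  .check_nonneg(fecal_g_per_d, "fecal_g_per_d")
  100 * (intake_g_per_d - fecal_g_per_d) / intake_g_per_d
}

#' Nitrogen balance
#'
#' Nitrogen retention as intake minus fecal minus urinary excretion. Negative
#' retention is possible under measurement noise and is returned as-is with a
#' warning, never clamped.
#'
#' @param n_intake_g_per_d,fecal_n_g_per_d,urinary_n_g_per_d g N/d, all
#'   non-negative.
#' @return N retention, g/d.
#' @export
#' @examples
#' nitrogen_balance(46.9, 6.8, 22)
nitrogen_balance <- function(n_intake_g_per_d, fecal_n_g_per_d,
                             urinary_n_g_per_d) {
  .check_nonneg(n_intake_g_per_d, "n_intake_g_per_d")
  .check_nonneg(fecal_n_g_per_d, "fecal_n_g_per_d")
  .check_nonneg(urinary_n_g_per_d, "urinary_n_g_per_d")
  ret <- n_intake_g_per_d - fecal_n_g_per_d - urinary_n_g_per_d
  if (any(ret < 0))
    warning("negative nitrogen retention in ", sum(ret < 0), " record(s)",
            call. = FALSE)
  ret
}

#' Energy retained as protein, per metabolic body weight
#'
#' RE_P = N retention (g/d) x 6.25 x 23.86 kJ/g, scaled by BW^0.6. Divide by
#' `metabolic_weight(bw_kg)` yourself if you need the daily total: the daily
#' value is `n_retention * 6.25 * 23.86` kJ/d (use `bw_kg = 1`).
#'
#' @param n_retention_g_per_d nitrogen retention, g/d (may be negative).
#' @param bw_kg body weight, kg; strictly positive.
#' @return RE_P in kJ/kg BW^0.6/d.
#' @export
#' @examples
#' retained_protein_energy(20.7, 47.82)
retained_protein_energy <- function(n_retention_g_per_d, bw_kg) {
  if (any(!is.finite(bw_kg)) || any(bw_kg <= 0))
    stop("'bw_kg' must be strictly positive", call. = FALSE)
  n_retention_g_per_d * 6.25 * 23.86 / metabolic_weight(bw_kg)
}

#' Dietary DE and ME per kg of dry matter
#'
#' DE subtracts fecal energy from gross-energy intake; ME further subtracts
#' urinary energy and the energy of methane produced.
#'
#' @param ge_intake_kj_per_d gross-energy intake, kJ/d.
#' @param fecal_energy_kj_per_d,urinary_energy_kj_per_d energy losses, kJ/d.
#' @param ch4_l_per_d methane production, L/d.
#' @param dm_intake_kg_per_d dry-matter intake, kg/d; strictly positive.
#' @param coeffs a [brouwer_coefficients()] set (for the methane conversion).
#' @return A data frame with `de_mj_per_kg_dm`, `me_mj_per_kg_dm`, and
#'   `urinary_e_pct_of_de` (urinary energy as percent of DE).
#' @export
#' @examples
#' diet_energy_values(20900, 2530, 400, 50, 1.30)
diet_energy_values <- function(ge_intake_kj_per_d, fecal_energy_kj_per_d,
                               urinary_energy_kj_per_d, ch4_l_per_d,
                               dm_intake_kg_per_d,
                               coeffs = brouwer_coefficients()) {
  if (any(!is.finite(dm_intake_kg_per_d)) || any(dm_intake_kg_per_d <= 0))
    stop("'dm_intake_kg_per_d' must be strictly positive", call. = FALSE)
  .check_nonneg(ge_intake_kj_per_d, "ge_intake_kj_per_d")
  .check_nonneg(fecal_energy_kj_per_d, "fecal_energy_kj_per_d")
  .check_nonneg(urinary_energy_kj_per_d, "urinary_energy_kj_per_d")
  de_kj <- ge_intake_kj_per_d - fecal_energy_kj_per_d
  me_kj <- de_kj - urinary_energy_kj_per_d - methane_energy(ch4_l_per_d, coeffs)
  data.frame(
    de_mj_per_kg_dm = de_kj / dm_intake_kg_per_d / 1000,
    me_mj_per_kg_dm = me_kj / dm_intake_kg_per_d / 1000,
    urinary_e_pct_of_de = ifelse(de_kj > 0,
                                 100 * urinary_energy_kj_per_d / de_kj,
                                 NA_real_)
  )
}

#' Retained energy
#'
#' RE = ME intake - total heat production, on a daily kJ basis. Division by
#' dry-matter intake (or metabolic weight) is applied at reporting.
#'
#' @param me_intake_kj_per_d ME intake, kJ/d.
#' @param thp_kj_per_d total heat production, kJ/d.
#' @return RE, kJ/d; may be negative under noise (flagged downstream).
#' @export
#' @examples
#' retained_energy(1989, 1214)
retained_energy <- function(me_intake_kj_per_d, thp_kj_per_d) {
  me_intake_kj_per_d - thp_kj_per_d
}

#' Dietary net energy per kg of dry matter
#'
#' NE = (RE + FHP) / DM intake. The fasting heat production should be the
#' same pig's own FHP (the default policy in [energy_balance()]).
#'
#' @param re_kj_per_d retained energy, kJ/d.
#' @param fhp_kj_per_d fasting heat production, kJ/d.
#' @param dm_intake_kg_per_d dry-matter intake, kg/d; strictly positive.
#' @return NE in MJ/kg DM.
#' @export
#' @examples
#' diet_ne(7890, 8040, 1.30)
diet_ne <- function(re_kj_per_d, fhp_kj_per_d, dm_intake_kg_per_d) {
  if (any(!is.finite(dm_intake_kg_per_d)) || any(dm_intake_kg_per_d <= 0))
    stop("'dm_intake_kg_per_d' must be strictly positive", call. = FALSE)
  (re_kj_per_d + fhp_kj_per_d) / dm_intake_kg_per_d / 1000
}

.nutrients <- c("dm", "om", "cp", "ndf", "adf", "ee")

#' Per-pig energy and nitrogen balance
#'
#' Computes, for every pig x period record, the nutrient digestibilities,
#' nitrogen balance, total and fasting heat production from the gas-exchange
#' windows, and the full energy partition (DE, ME, RE, RE_P, RE_L, NE),
#' reported per kg DM and per kg metabolic body weight.
#'
#' @param records data frame of pig-period collection records; see
#'   [read_energy_records()] for the schema.
#' @param gas data frame of gas-exchange windows; see [read_gas_windows()].
#' @param coeffs a [brouwer_coefficients()] set.
#' @param fhp_policy which FHP enters each pig's NE: the pig's own fasted
#'   window (`"per-pig"`, default), the diet mean of per-metabolic-weight FHP
#'   (`"diet-mean"`), or a fixed value in kJ/kg BW^0.6/d (`"fixed"`, with
#'   `fhp_value`).
#' @param fhp_value fixed FHP in kJ/kg BW^0.6/d when `fhp_policy = "fixed"`.
#' @return A data frame of class `pig_energy`, one row per pig x period, with
#'   digestibilities (`attd_*`, %), nitrogen balance (g/d), energy values
#'   (MJ/kg DM), heat and retained energy (kJ/d and kJ/kg BW^0.6/d), energy
#'   ratios (%), respiratory quotients, and logical flags
#'   `flag_negative_n_retention`, `flag_negative_re`.
#' @seealso [summarize_diet()] for diet-level means.
#' @export
energy_balance <- function(records, gas, coeffs = brouwer_coefficients(),
                           fhp_policy = c("per-pig", "diet-mean", "fixed"),
                           fhp_value = NULL) {
  fhp_policy <- match.arg(fhp_policy)
  if (fhp_policy == "fixed" &&
      (is.null(fhp_value) || !is.finite(fhp_value) || fhp_value <= 0))
    stop("fhp_policy = \"fixed\" requires a positive 'fhp_value' (kJ/kg BW^0.6/d)",
         call. = FALSE)
  check_columns(records, schema_energy_records(), "records")
  check_columns(gas, schema_gas_windows(), "gas")
  if (!all(gas$state %in% c("fed", "fasted")))
    stop("gas 'state' must be \"fed\" or \"fasted\"", call. = FALSE)

  key <- paste(records$pig_id, records$period, sep = "\r")
  gkey <- paste(gas$pig_id, gas$period, sep = "\r")
  fed <- gas$state == "fed"

  # fed windows: scale gases and N jointly to a 24-h basis, then Brouwer
  sc <- 24 / gas$duration_h
  thp_fed <- .brouwer(gas$o2_l * sc, gas$co2_l * sc, gas$ch4_l * sc,
                      gas$urinary_n_g * sc, coeffs)
  thp_d <- tapply(thp_fed[fed], gkey[fed], mean)
  o2_fed <- tapply(gas$o2_l[fed], gkey[fed], sum)
  co2_fed <- tapply(gas$co2_l[fed], gkey[fed], sum)

  # fasted windows: 24-h N charged once, gases extrapolated
  fhp_meas <- .fhp24(gas$o2_l, gas$co2_l, gas$ch4_l, gas$urinary_n_g,
                     gas$duration_h, coeffs)
  fhp_d <- tapply(fhp_meas[!fed], gkey[!fed], mean)
  o2_fas <- tapply(gas$o2_l[!fed], gkey[!fed], sum)
  co2_fas <- tapply(gas$co2_l[!fed], gkey[!fed], sum)

  miss <- setdiff(key, names(thp_d))
  if (length(miss))
    stop("records without fed gas windows: ",
         paste(gsub("\r", "/", miss), collapse = ", "), call. = FALSE)

  out <- records[, c("pig_id", "diet_id", "period", "bw_kg",
                     "dm_intake_kg_per_d")]
  out$mbw_kg <- metabolic_weight(records$bw_kg)
  out$thp_kj_per_d <- as.numeric(thp_d[key])
  out$rq_fed <- as.numeric((co2_fed / o2_fed)[key])
  out$fhp_measured_kj_per_d <- as.numeric(fhp_d[key])
  out$rq_fasted <- as.numeric((co2_fas / o2_fas)[key])

  # FHP entering NE, by policy
  fhp_meas_mbw <- out$fhp_measured_kj_per_d / out$mbw_kg
  out$fhp_kj_per_d <- switch(fhp_policy,
    "per-pig" = out$fhp_measured_kj_per_d,
    "diet-mean" = {
      dm <- tapply(fhp_meas_mbw, out$diet_id, mean, na.rm = TRUE)
      as.numeric(dm[as.character(out$diet_id)]) * out$mbw_kg
    },
    "fixed" = fhp_value * out$mbw_kg)
  if (fhp_policy == "per-pig" && anyNA(out$fhp_kj_per_d))
    stop("fhp_policy = \"per-pig\" requires a fasted window for every record",
         call. = FALSE)

  # energy partition
  ev <- diet_energy_values(records$ge_intake_kj_per_d,
                           records$fecal_energy_kj_per_d,
                           records$urinary_energy_kj_per_d,
                           records$ch4_l_per_d,
                           records$dm_intake_kg_per_d, coeffs)
  out$ge_mj_per_kg_dm <- records$ge_intake_kj_per_d /
    records$dm_intake_kg_per_d / 1000
  out$de_mj_per_kg_dm <- ev$de_mj_per_kg_dm
  out$me_mj_per_kg_dm <- ev$me_mj_per_kg_dm
  out$urinary_e_pct_of_de <- ev$urinary_e_pct_of_de
  me_int <- ev$me_mj_per_kg_dm * records$dm_intake_kg_per_d * 1000
  out$me_intake_kj_per_d <- me_int
  out$re_kj_per_d <- retained_energy(me_int, out$thp_kj_per_d)
  out$ne_mj_per_kg_dm <- diet_ne(out$re_kj_per_d, out$fhp_kj_per_d,
                                 records$dm_intake_kg_per_d)

  # nitrogen balance and RE split
  out$n_intake_g_per_d <- records$n_intake_g_per_d
  out$fecal_n_g_per_d <- records$fecal_n_g_per_d
  out$urinary_n_g_per_d <- records$urinary_n_g_per_d
  out$n_retention_g_per_d <- suppressWarnings(
    nitrogen_balance(records$n_intake_g_per_d, records$fecal_n_g_per_d,
                     records$urinary_n_g_per_d))
  out$re_p_kj_per_d <- out$n_retention_g_per_d * 6.25 * 23.86
  out$re_l_kj_per_d <- out$re_kj_per_d - out$re_p_kj_per_d

  # per-metabolic-weight reporting
  for (v in c("me_intake", "thp", "fhp", "re", "re_p", "re_l"))
    out[[paste0(v, "_kj_per_mbw")]] <-
      out[[paste0(v, "_kj_per_d")]] / out$mbw_kg
  out$me_de_pct <- 100 * out$me_mj_per_kg_dm / out$de_mj_per_kg_dm
  out$ne_me_pct <- 100 * out$ne_mj_per_kg_dm / out$me_mj_per_kg_dm

  # digestibilities for every nutrient with intake and fecal columns
  for (nut in .nutrients) {
    ic <- paste0("intake_", nut, "_g_per_d")
    fc <- paste0("fecal_", nut, "_g_per_d")
    if (all(c(ic, fc) %in% names(records)))
      out[[paste0("attd_", nut)]] <- attd(records[[ic]], records[[fc]])
  }
  out$attd_ge <- attd(records$ge_intake_kj_per_d, records$fecal_energy_kj_per_d)

  out$flag_negative_n_retention <- out$n_retention_g_per_d < 0
  out$flag_negative_re <- out$re_kj_per_d < 0
  if (any(out$flag_negative_re))
    warning("negative retained energy in ", sum(out$flag_negative_re),
            " record(s)", call. = FALSE)
  class(out) <- c("pig_energy", "data.frame")
  out
}

#' Diet-level summary of per-pig energy balances
#'
#' Unweighted arithmetic means of the per-pig quantities for each diet. The
#' lipid component of retained energy is computed per pig (RE_L = RE - RE_P)
#' before averaging, so RE = RE_P + RE_L holds exactly for the means too.
#'
#' @param pig_energy a `pig_energy` data frame from [energy_balance()].
#' @return A data frame of class `diet_energy`, one row per diet, with the
#'   mean of every numeric column plus `n_obs`.
#' @export
summarize_diet <- function(pig_energy) {
  if (!inherits(pig_energy, "pig_energy"))
    stop("'pig_energy' must come from energy_balance()", call. = FALSE)
  if (nrow(pig_energy) < 1L) stop("no records to summarise", call. = FALSE)
  num <- vapply(pig_energy, is.numeric, logical(1))
  num[names(num) == "period"] <- FALSE
  diets <- unique(as.character(pig_energy$diet_id))
  rows <- lapply(diets, function(d) {
    sub <- pig_energy[pig_energy$diet_id == d, , drop = FALSE]
    m <- as.data.frame(lapply(sub[, num, drop = FALSE], mean))
    cbind(data.frame(diet_id = d, n_obs = nrow(sub)), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(with(out, de_mj_per_kg_dm < me_mj_per_kg_dm)))
    warning("diet mean ME exceeds DE; check inputs", call. = FALSE)
  class(out) <- c("diet_energy", "data.frame")
  out
}

#' @export
print.diet_energy <- function(x, digits = 2, ...) {
  if (!all(c("diet_id", "n_obs") %in% names(x))) return(NextMethod())
  cat("Diet energy balance (means of", paste(unique(x$n_obs), collapse = "/"),
      "observations per diet)\n\n")
  show <- c(bw_kg = "Body weight (kg)",
            dm_intake_kg_per_d = "DM intake (kg/d)",
            attd_dm = "ATTD DM (%)", attd_cp = "ATTD CP (%)",
            attd_om = "ATTD OM (%)", attd_ndf = "ATTD NDF (%)",
            attd_adf = "ATTD ADF (%)", attd_ee = "ATTD EE (%)",
            attd_ge = "ATTD GE (%)",
            n_intake_g_per_d = "N intake (g/d)",
            n_retention_g_per_d = "N retention (g/d)",
            me_intake_kj_per_mbw = "ME intake (kJ/kg BW^0.6/d)",
            thp_kj_per_mbw = "THP (kJ/kg BW^0.6/d)",
            fhp_kj_per_mbw = "FHP (kJ/kg BW^0.6/d)",
            re_p_kj_per_mbw = "RE protein (kJ/kg BW^0.6/d)",
            re_l_kj_per_mbw = "RE lipid (kJ/kg BW^0.6/d)",
            re_kj_per_mbw = "Total RE (kJ/kg BW^0.6/d)",
            rq_fed = "RQ fed", rq_fasted = "RQ fasted",
            urinary_e_pct_of_de = "Urinary energy (% of DE)",
            me_de_pct = "ME/DE (%)", ne_me_pct = "NE/ME (%)",
            de_mj_per_kg_dm = "DE (MJ/kg DM)",
            me_mj_per_kg_dm = "ME (MJ/kg DM)",
            ne_mj_per_kg_dm = "NE (MJ/kg DM)")
  show <- show[names(show) %in% names(x)]
  mat <- t(as.matrix(x[, names(show), drop = FALSE]))
  rownames(mat) <- show
  colnames(mat) <- x$diet_id
  kj <- grepl("kJ/kg", rownames(mat))
  fm <- formatC(mat, format = "f", digits = digits)
  fm[kj, ] <- formatC(mat[kj, , drop = FALSE], format = "f", digits = 0)
  print(fm, quote = FALSE, right = TRUE)
  invisible(x)
}
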