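# Synthetic chamber experiments with known ground truth: energy-conserving
# pig-period records and gas-exchange windows, plus an ingredient-panel
# generator with a configurable correlation structure.

#' Noise settings for the chamber-experiment generator
#'
#' Coefficients of variation of multiplicative log-normal noise per
#' observable (each factor has mean exactly 1), plus the standard deviation
#' of logit-scale noise applied to nutrient digestibilities so that they stay
#' in (0, 1). Defaults are calibrated so diet-level standard errors over six
#' pigs have the magnitudes typical of respiration-chamber studies (a few
#' percent on intakes and heat, more on urinary and methane losses).
#'
#' @param scale multiplies every CV and the logit SD; `noise_cv(0)` is the
#'   exact zero-noise setting used for closure tests.
#' @param intake CV of realised ME intake (feed allowance, refusals).
#' @param fecal_energy,urinary_energy,methane CVs of the energy losses.
#' @param gas CV applied to O2 and CO2 volumes of each window.
#' @param fecal_n,urinary_n_fasting,n_retention CVs of the nitrogen terms.
#' @param digestibility_logit_sd SD of logit-scale digestibility noise.
#' @param bw_sd_kg SD of body weight around the period mean, kg (additive).
#' @return A list of class `noise_cv`.
#' @export
#' @examples
#' noise_cv(0)
noise_cv <- function(scale = 1, intake = 0.02, fecal_energy = 0.05,
                     urinary_energy = 0.10, methane = 0.10, gas = 0.03,
                     fecal_n = 0.08, urinary_n_fasting = 0.10,
                     n_retention = 0.08, digestibility_logit_sd = 0.10,
                     bw_sd_kg = 2.2) {
  out <- list(intake = intake, fecal_energy = fecal_energy,
              urinary_energy = urinary_energy, methane = methane, gas = gas,
              fecal_n = fecal_n, urinary_n_fasting = urinary_n_fasting,
              n_retention = n_retention,
              digestibility_logit_sd = digestibility_logit_sd,
              bw_sd_kg = bw_sd_kg)
  out <- lapply(out, function(v) v * scale)
  if (any(unlist(out) < 0)) stop("noise CVs must be non-negative",
                                 call. = FALSE)
  class(out) <- "noise_cv"
  out
}

# multiplicative log-normal factors with mean exactly 1
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

.logit_noise <- function(p_pct, sd) {
  if (sd <= 0) return(p_pct)
  p <- pmin(pmax(p_pct / 100, 1e-6), 1 - 1e-6)
  100 * plogis(qlogis(p) + rnorm(length(p), 0, sd))
}

#' Ground-truth configuration for a simulated chamber experiment
#'
#' Defines the study conditions of a simulated net-energy experiment: the
#' diets with their true energy values, composition and digestibilities; the
#' design size; feeding level and fasting heat production on the metabolic
#' body-weight basis; respiratory quotients; and the noise model.
#'
#' @param diets data frame with one row per diet: `diet_id`,
#'   `test_ingredient` (`NA` for the basal diet), true `ge`, `de`, `me`, `ne`
#'   (MJ/kg DM, with GE >= DE >= ME >= NE), composition columns `cp_pct_dm`,
#'   `om_pct_dm`, `ndf_pct_dm`, `adf_pct_dm`, `ee_pct_dm`, digestibility
#'   columns `attd_dm`, `attd_cp`, `attd_om`, `attd_ndf`, `attd_adf`,
#'   `attd_ee` (percent), and `n_ret_frac` (N retained / N intake).
#' @param n_pigs_per_diet,n_periods design size; pig `i` of each diet is
#'   measured in period `((i - 1) mod n_periods) + 1`.
#' @param true_fhp_per_mbw fasting heat production, kJ/kg BW^0.6/d.
#' @param feeding_level_per_mbw ME allowance, kJ ME/kg BW^0.6/d.
#' @param rq_fed,rq_fasted respiratory quotients of the two states.
#' @param bw_start_kg mean body weight in period 1, kg.
#' @param bw_gain_per_period_kg mean body-weight gain per period, kg.
#' @param n_fed_days number of 24-h fed measurement windows per record.
#' @param fasted_window_h length of the fasted measurement window, hours.
#' @param fasting_urinary_n_g 24-h urinary N excretion while fasting, g.
#' @param ch4_share share of the DE-to-ME gap lost as methane (the rest is
#'   urinary energy).
#' @param noise a [noise_cv()] object.
#' @param seed optional integer seed; `generate_experiment()` seeds the RNG
#'   with it.
#' @return A list of class `truth_config`. Configurations that imply negative
#'   energy components (e.g. retained energy non-positive at the stated
#'   feeding level and FHP) are rejected before any sampling.
#' @seealso [rsm_study_preset()] for the bundled rapeseed-meal conditions.
#' @export
truth_config <- function(diets, n_pigs_per_diet = 6, n_periods = 6,
                         true_fhp_per_mbw = 790,
                         feeding_level_per_mbw = 2000,
                         rq_fed = 1.07, rq_fasted = 0.81,
                         bw_start_kg = 41.1, bw_gain_per_period_kg = 2.6,
                         n_fed_days = 5, fasted_window_h = 8,
                         fasting_urinary_n_g = 8, ch4_share = 0.10,
                         noise = noise_cv(), seed = NULL) {
  req <- c("diet_id", "test_ingredient", "ge", "de", "me", "ne",
           "cp_pct_dm", "om_pct_dm", "ndf_pct_dm", "adf_pct_dm", "ee_pct_dm",
           "attd_dm", "attd_cp", "attd_om", "attd_ndf", "attd_adf", "attd_ee",
           "n_ret_frac")
  check_columns(diets, req, "diets")
  with(diets, {
    if (any(!(ge >= de & de >= me & me >= ne & ne > 0)))
      stop("diet energies must satisfy GE >= DE >= ME >= NE > 0",
           call. = FALSE)
    attds <- cbind(attd_dm, attd_cp, attd_om, attd_ndf, attd_adf, attd_ee)
    if (any(attds <= 0 | attds >= 100))
      stop("digestibilities must lie in (0, 100)", call. = FALSE)
    if (any(n_ret_frac <= 0 | n_ret_frac >= 1))
      stop("'n_ret_frac' must lie in (0, 1)", call. = FALSE)
  })
  if (feeding_level_per_mbw <= 0) stop("feeding level must be positive",
                                       call. = FALSE)
  if (true_fhp_per_mbw <= 0) stop("FHP must be positive", call. = FALSE)
  if (ch4_share < 0 || ch4_share >= 1)
    stop("'ch4_share' must lie in [0, 1)", call. = FALSE)
  if (!inherits(noise, "noise_cv")) stop("'noise' must come from noise_cv()",
                                         call. = FALSE)
  # expected retained energy per metabolic weight must be positive: the
  # config would otherwise imply negative components before any sampling
  re_exp <- feeding_level_per_mbw * diets$ne / diets$me - true_fhp_per_mbw
  if (any(re_exp <= 0))
    stop("config implies non-positive retained energy for diet(s): ",
         paste(diets$diet_id[re_exp <= 0], collapse = ", "), call. = FALSE)
  structure(list(diets = diets, n_pigs_per_diet = n_pigs_per_diet,
                 n_periods = n_periods,
                 true_fhp_per_mbw = true_fhp_per_mbw,
                 feeding_level_per_mbw = feeding_level_per_mbw,
                 rq_fed = rq_fed, rq_fasted = rq_fasted,
                 bw_start_kg = bw_start_kg,
                 bw_gain_per_period_kg = bw_gain_per_period_kg,
                 n_fed_days = n_fed_days, fasted_window_h = fasted_window_h,
                 fasting_urinary_n_g = fasting_urinary_n_g,
                 ch4_share = ch4_share, noise = noise, seed = seed),
            class = "truth_config")
}

#' Rapeseed-meal study conditions for the generator
#'
#' The bundled ground truth: a corn-soybean-meal basal diet plus five test
#' diets each substituting 19.5% of one rapeseed-meal source for corn and
#' soybean meal. True ingredient energy values are the bundled reference
#' values ([rsm_ingredient_reference()], with measured GE from
#' [rsm_composition()]); the basal-mixture truth is the basal diet divided by
#' its 0.975 mixture fraction, and each test diet's truth is composed as
#' 0.78 x mixture + 0.195 x ingredient. Compositions and digestibilities come
#' from the bundled diet tables, converted to the DM basis.
#'
#' @param ... overrides passed to [truth_config()] (e.g. `noise`,
#'   `n_pigs_per_diet`, `seed`).
#' @return A `truth_config`.
#' @export
#' @examples
#' cfg <- rsm_study_preset(noise = noise_cv(0), seed = 1)
rsm_study_preset <- function(...) {
  comp <- rsm_composition()
  ref <- rsm_ingredient_reference()
  dietc <- rsm_diet_composition()
  dref <- rsm_diet_reference()

  basal <- dref[dref$diet_id == "basal", ]
  basal_ge <- basal$de_mj_per_kg_dm / (basal$attd_ge / 100)
  mix <- c(ge = basal_ge, de = basal$de_mj_per_kg_dm,
           me = basal$me_mj_per_kg_dm, ne = basal$ne_mj_per_kg_dm) / 0.975

  ord <- match(ref$ingredient, comp$ingredient)
  ing <- data.frame(ingredient = ref$ingredient,
                    ge = comp$ge_mj_per_kg_dm[ord],
                    de = ref$de_mj_per_kg_dm, me = ref$me_mj_per_kg_dm,
                    ne = ref$ne_mj_per_kg_dm)

  ids <- c("basal", ing$ingredient)
  en <- rbind(mix * 0.975,
              t(vapply(seq_len(nrow(ing)), function(i)
                0.78 * mix + 0.195 * unlist(ing[i, c("ge", "de", "me", "ne")]),
                numeric(4))))
  colnames(en) <- c("ge", "de", "me", "ne")

  dc <- dietc[match(ids, dietc$diet_id), ]
  to_dm <- function(x) 100 * x / dc$dm_pct_asfed
  diets <- data.frame(
    diet_id = ids,
    test_ingredient = c(NA, ing$ingredient),
    en,
    cp_pct_dm = to_dm(dc$cp_pct_asfed),
    om_pct_dm = 100 - to_dm(dc$ash_pct_asfed),
    ndf_pct_dm = to_dm(dc$ndf_pct_asfed),
    adf_pct_dm = to_dm(dc$adf_pct_asfed),
    ee_pct_dm = to_dm(dc$ee_pct_asfed),
    attd_dm = dref$attd_dm, attd_cp = dref$attd_cp, attd_om = dref$attd_om,
    attd_ndf = dref$attd_ndf, attd_adf = dref$attd_adf,
    attd_ee = dref$attd_ee,
    n_ret_frac = dref$n_retention_g_per_d / dref$n_intake_g_per_d)
  truth_config(diets, ...)
}

#' Generate a synthetic chamber experiment
#'
#' Simulates a complete respiration-chamber experiment under a ground-truth
#' configuration. Body weights are drawn per pig, ME intake follows the
#' feeding level on the BW^0.6 basis, diet energy flows are decomposed from
#' the true GE/DE/ME/NE (fecal, urinary and methane losses; heat; retained
#' energy split into protein and lipid via a nitrogen-retention draw), and
#' fed and fasted gas-exchange windows are back-computed from the heat values
#' with [gas_from_heat()] so that the Brouwer equation reproduces them. All
#' noise is multiplicative log-normal per observable (logit-scale for
#' digestibilities); at `noise_cv(0)` the records satisfy exact energy
#' closure: GE intake = fecal + urinary + methane + THP + RE.
#'
#' @param config a [truth_config()].
#' @return A list of class `sim_experiment` with `records` (pig-period
#'   table), `gas` (window table) — both in the schemas the pipeline reads —
#'   and `truth` (the config and the composed per-diet true values).
#' @export
#' @examples
#' sim <- generate_experiment(rsm_study_preset(noise = noise_cv(0), seed = 1))
#' head(sim$records)
generate_experiment <- function(config) {
  if (!inherits(config, "truth_config"))
    stop("'config' must come from truth_config()", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- config$diets
  nz <- config$noise
  npd <- config$n_pigs_per_diet
  nd <- nrow(d)
  n <- nd * npd

  idx <- rep(seq_len(nd), each = npd)
  within_diet <- rep(seq_len(npd), times = nd)
  period <- ((within_diet - 1L) %% config$n_periods) + 1L
  tr <- d[idx, ]

  bw <- rnorm(n, config$bw_start_kg +
                (period - 1) * config$bw_gain_per_period_kg, nz$bw_sd_kg)
  if (any(bw <= 0)) stop("drawn body weight non-positive; reduce bw_sd_kg",
                         call. = FALSE)
  mbw <- metabolic_weight(bw)

  me_int <- config$feeding_level_per_mbw * mbw * .lnoise(n, nz$intake)
  dmi <- me_int / (tr$me * 1000)
  ge_int <- dmi * tr$ge * 1000

  fhp_true <- config$true_fhp_per_mbw * mbw
  re_true <- tr$ne * 1000 * dmi - fhp_true
  thp_true <- me_int - re_true

  coeffs <- brouwer_coefficients()
  fecal_e <- dmi * (tr$ge - tr$de) * 1000 * .lnoise(n, nz$fecal_energy)
  gap <- dmi * (tr$de - tr$me) * 1000
  ch4_e <- gap * config$ch4_share * .lnoise(n, nz$methane)
  ch4_l <- ch4_e / coeffs$methane_ge
  ur_e <- gap * (1 - config$ch4_share) * .lnoise(n, nz$urinary_energy)

  # nitrogen flows
  n_int <- dmi * tr$cp_pct_dm * 10 / 6.25
  attd_cp_real <- .logit_noise(tr$attd_cp, nz$digestibility_logit_sd)
  fecal_n <- n_int * (1 - attd_cp_real / 100) * .lnoise(n, nz$fecal_n)
  n_ret <- n_int * tr$n_ret_frac * .lnoise(n, nz$n_retention)
  urinary_n <- n_int - fecal_n - n_ret
  if (any(urinary_n < 0))
    warning("noise drew negative urinary N in ", sum(urinary_n < 0),
            " record(s); set to 0", call. = FALSE)
  urinary_n <- pmax(urinary_n, 0)

  records <- data.frame(
    pig_id = sprintf("pig%03d", seq_len(n)),
    diet_id = tr$diet_id, period = period, bw_kg = bw,
    dm_intake_kg_per_d = dmi, ge_intake_kj_per_d = ge_int,
    fecal_energy_kj_per_d = fecal_e, urinary_energy_kj_per_d = ur_e,
    ch4_l_per_d = ch4_l, n_intake_g_per_d = n_int,
    fecal_n_g_per_d = fecal_n, urinary_n_g_per_d = urinary_n)

  # nutrient flows for digestibility reporting
  comp <- cbind(dm = rep(100, n), om = tr$om_pct_dm, cp = tr$cp_pct_dm,
                ndf = tr$ndf_pct_dm, adf = tr$adf_pct_dm, ee = tr$ee_pct_dm)
  attds <- cbind(dm = tr$attd_dm, om = tr$attd_om, cp = attd_cp_real,
                 ndf = tr$attd_ndf, adf = tr$attd_adf, ee = tr$attd_ee)
  for (nut in colnames(comp)) {
    a <- if (nut == "cp") attds[, "cp"]
         else .logit_noise(attds[, nut], nz$digestibility_logit_sd)
    intake <- dmi * comp[, nut] * 10
    records[[paste0("intake_", nut, "_g_per_d")]] <- intake
    records[[paste0("fecal_", nut, "_g_per_d")]] <- intake * (1 - a / 100)
  }

  # fed windows: one 24-h window per measurement day, gases inverted from
  # the true daily heat so Brouwer recovers it, then gas noise applied
  nf <- config$n_fed_days
  ridx <- rep(seq_len(n), each = nf)
  fed_gas <- gas_from_heat(thp_true[ridx], config$rq_fed, ch4_l[ridx],
                           urinary_n[ridx], coeffs)
  fed <- data.frame(
    pig_id = records$pig_id[ridx], diet_id = records$diet_id[ridx],
    period = records$period[ridx], day = rep(seq_len(nf), times = n),
    state = "fed", duration_h = 24,
    o2_l = fed_gas$o2_l * .lnoise(n * nf, nz$gas),
    co2_l = fed_gas$co2_l * .lnoise(n * nf, nz$gas),
    ch4_l = ch4_l[ridx], urinary_n_g = urinary_n[ridx])

  # fasted window: gases carry the window's share of the daily fasting N so
  # the 24-h extrapolation charges it exactly once
  frac <- config$fasted_window_h / 24
  n_fast <- config$fasting_urinary_n_g * .lnoise(n, nz$urinary_n_fasting)
  fas_gas <- gas_from_heat(fhp_true * frac, config$rq_fasted, 0,
                           n_fast * frac, coeffs)
  fasted <- data.frame(
    pig_id = records$pig_id, diet_id = records$diet_id,
    period = records$period, day = nf + 1L,
    state = "fasted", duration_h = config$fasted_window_h,
    o2_l = fas_gas$o2_l * .lnoise(n, nz$gas),
    co2_l = fas_gas$co2_l * .lnoise(n, nz$gas),
    ch4_l = 0, urinary_n_g = n_fast)

  structure(list(records = records, gas = rbind(fed, fasted),
                 truth = list(config = config, diets = d)),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("Simulated chamber experiment: %d diets x %d pigs (%d records, %d gas windows)\n",
              nrow(x$truth$diets), x$truth$config$n_pigs_per_diet,
              nrow(x$records), nrow(x$gas)))
  cat("True diet NE (MJ/kg DM):",
      paste(sprintf("%s %.2f", x$truth$diets$diet_id, x$truth$diets$ne),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated experiment to pipeline input files
#'
#' Writes `records.tsv`, `gas.tsv` and `truth.tsv` (the per-diet true energy
#' values) into a directory, in exactly the schemas [read_energy_records()]
#' and [read_gas_windows()] read, closing the simulate-then-analyze loop.
#'
#' @param sim a `sim_experiment` from [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  if (!inherits(sim, "sim_experiment"))
    stop("'sim' must come from generate_experiment()", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$records, file.path(dir, "records.tsv"))
  write_tsv(sim$gas, file.path(dir, "gas.tsv"))
  write_tsv(sim$truth$diets, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Configuration for the synthetic ingredient panel
#'
#' Composition is drawn from a multivariate normal with the given means,
#' SDs and correlation matrix (defaults plant the correlation signs seen in
#' rapeseed meals: ether extract against crude protein negative, NDF with ADF
#' positive, starch against the fibres negative). Energies are then derived
#' sequentially from configurable linear models plus normal noise: by default
#' GE rises with ether extract (tightly, so the planted EE-GE correlation is
#' about 0.98), DE falls with NDF, ME is proportional to DE, and
#' NE = 0.85 ME - 1.48 with residual SD 0.36 MJ/kg DM.
#'
#' @param mu,sd named means and SDs of the composition columns (% of DM).
#' @param correlation correlation matrix of the composition columns; must be
#'   positive definite.
#' @param energy named list of linear models, in evaluation order, each a
#'   list with `intercept`, `coef` (named vector over composition and
#'   earlier-energy columns) and `sd`.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(mu = c(cp = 40, ee = 4.8, starch = 3.2, ndf = 36,
                                adf = 22.5, ash = 7.8),
                         sd = c(cp = 1.7, ee = 3.0, starch = 0.8, ndf = 4.5,
                                adf = 2.0, ash = 0.9),
                         correlation = NULL,
                         energy = list(
                           ge = list(intercept = 19.0, coef = c(ee = 0.19),
                                     sd = 0.12),
                           de = list(intercept = -0.9,
                                     coef = c(ge = 1.0, ndf = -0.11),
                                     sd = 0.40),
                           me = list(intercept = 0, coef = c(de = 0.905),
                                     sd = 0.15),
                           ne = list(intercept = -1.48, coef = c(me = 0.85),
                                     sd = 0.36))) {
  vars <- names(mu)
  if (is.null(correlation)) {
    correlation <- diag(length(vars))
    dimnames(correlation) <- list(vars, vars)
    set_r <- function(a, b, r) {
      correlation[a, b] <<- r
      correlation[b, a] <<- r
    }
    set_r("cp", "ee", -0.83)
    set_r("ndf", "adf", 0.93)
    set_r("starch", "ndf", -0.69)
    set_r("starch", "adf", -0.75)
  }
  ok <- tryCatch({ chol(correlation); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("composition correlation matrix is not positive definite",
         call. = FALSE)
  if (!identical(names(sd), vars) ||
      !identical(rownames(correlation), vars))
    stop("'mu', 'sd' and 'correlation' must share the same variable names",
         call. = FALSE)
  structure(list(mu = mu, sd = sd, correlation = correlation,
                 energy = energy),
            class = "panel_config")
}

#' Generate a synthetic ingredient sample panel
#'
#' Draws `n_samples` ingredient samples (composition plus GE/DE/ME/NE) under
#' a [panel_config()]. Rows with a negative composition value or an energy
#' ordering violation (GE >= DE >= ME >= NE required) are redrawn.
#'
#' @param n_samples number of samples (>= 3).
#' @param config a [panel_config()].
#' @param seed optional integer seed.
#' @return A data frame in the sample-panel schema: `sample_id`, composition
#'   columns (% of DM), and `ge`, `de`, `me`, `ne` (MJ/kg DM).
#' @export
#' @examples
#' generate_ingredient_panel(8, seed = 1)
generate_ingredient_panel <- function(n_samples, config = panel_config(),
                                      seed = NULL) {
  if (!inherits(config, "panel_config"))
    stop("'config' must come from panel_config()", call. = FALSE)
  if (n_samples < 3) stop("need at least 3 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- diag(config$sd) %*% config$correlation %*% diag(config$sd)
  dimnames(Sigma) <- dimnames(config$correlation)

  draw <- function(k) {
    comp <- as.data.frame(MASS::mvrnorm(k, mu = config$mu, Sigma = Sigma))
    if (k == 1) names(comp) <- names(config$mu)
    for (nm in names(config$energy)) {
      m <- config$energy[[nm]]
      val <- rep(m$intercept, k)
      for (v in names(m$coef)) val <- val + m$coef[[v]] * comp[[v]]
      comp[[nm]] <- val + rnorm(k, 0, m$sd)
    }
    comp
  }
  panel <- draw(n_samples)
  for (round in 1:50) {
    bad <- apply(panel[names(config$mu)] < 0, 1, any)
    if (all(c("ge", "de", "me", "ne") %in% names(panel)))
      bad <- bad | !(panel$ge >= panel$de & panel$de >= panel$me &
                       panel$me >= panel$ne & panel$ne > 0)
    if (!any(bad)) break
    panel[bad, ] <- draw(sum(bad))
    if (round == 50)
      stop("could not draw a valid panel; check panel_config", call. = FALSE)
  }
  cbind(sample_id = sprintf("sample%02d", seq_len(n_samples)), panel)
}
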