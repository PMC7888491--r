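# Ingredient GE/DE/ME/NE by the difference method: basal-mixture correction,
# contribution subtraction, and gross-energy ratio chaining.

#' Energy value of the basal mixture
#'
#' The basal diet's energy value divided by the dry-matter fraction of the
#' energy-yielding mixture in the basal diet (default 0.975, i.e. corn plus
#' soybean meal with a 2.5% mineral/premix fraction treated as energy-free).
#'
#' @param basal_diet_value energy value of the basal diet, MJ/kg DM.
#' @param mixture_fraction fraction of the basal diet made up by the
#'   energy-yielding mixture.
#' @return Energy value of the mixture, MJ/kg DM.
#' @export
#' @examples
#' basal_mixture_energy(12.05)
basal_mixture_energy <- function(basal_diet_value, mixture_fraction = 0.975) {
  .check_nonneg(basal_diet_value, "basal_diet_value")
  if (!is.finite(mixture_fraction) || mixture_fraction <= 0 ||
      mixture_fraction > 1)
    stop("'mixture_fraction' must be in (0, 1]", call. = FALSE)
  basal_diet_value / mixture_fraction
}

#' Dry-matter inclusion fractions of a diet formulation
#'
#' Converts as-fed inclusion percentages into the fractions of diet dry
#' matter contributed by the basal mixture and the test ingredient. With
#' `policy = "dm"` the conversion uses each ingredient's DM content
#' (columns `as_fed_pct` and `dm_pct`), normalising by total diet DM; with
#' `policy = "as-fed"` (the documented fallback when ingredient DM contents
#' are not available) the as-fed fractions are used directly. Mineral and
#' premix ingredients (`role == "mineral"`) are counted in the denominator
#' but treated as contributing zero energy.
#'
#' @param formulation data frame for one diet with columns `ingredient`,
#'   `as_fed_pct`, `role` (one of `"mixture"`, `"test"`, `"mineral"`) and,
#'   for the DM policy, `dm_pct`.
#' @param policy `"as-fed"` or `"dm"`.
#' @return A list with `f_mix` and `f_test`, each in `[0, 1]`.
#' @export
dm_fractions <- function(formulation, policy = c("as-fed", "dm")) {
  policy <- match.arg(policy)
  req <- c("ingredient", "as_fed_pct", "role")
  check_columns(formulation, req, "formulation")
  if (!all(formulation$role %in% c("mixture", "test", "mineral")))
    stop("formulation 'role' must be mixture, test or mineral", call. = FALSE)
  tot <- sum(formulation$as_fed_pct)
  if (abs(tot - 100) > 0.01)
    stop(sprintf("as-fed inclusions sum to %.3f, not 100", tot), call. = FALSE)
  w <- formulation$as_fed_pct
  if (policy == "dm") {
    if (!"dm_pct" %in% names(formulation) || anyNA(formulation$dm_pct))
      stop("policy = \"dm\" requires a complete 'dm_pct' column", call. = FALSE)
    w <- w * formulation$dm_pct / 100
  }
  f_mix <- sum(w[formulation$role == "mixture"]) / sum(w)
  f_test <- sum(w[formulation$role == "test"]) / sum(w)
  if (f_mix < 0 || f_mix > 1 || f_test < 0 || f_test > 1)
    stop("inclusion fractions outside [0, 1]", call. = FALSE)
  list(f_mix = f_mix, f_test = f_test)
}

#' Test-ingredient energy value by difference
#'
#' Subtracts the basal mixture's contribution from a test diet's energy value
#' and divides by the test-ingredient inclusion fraction.
#'
#' @param diet_value test diet energy value, MJ/kg DM.
#' @param mixture_value basal-mixture energy value, MJ/kg DM (see
#'   [basal_mixture_energy()]).
#' @param f_mix,f_test dry-matter fractions of mixture and test ingredient in
#'   the test diet; `f_test` must be strictly positive.
#' @return Raw ingredient energy value, MJ/kg DM. Negative results (possible
#'   under noise) are returned with a warning, never clamped.
#' @export
#' @examples
#' ingredient_by_difference(15.94, 16.08 / 0.975, 0.78, 0.195)
ingredient_by_difference <- function(diet_value, mixture_value, f_mix, f_test) {
  if (any(!is.finite(f_test)) || any(f_test <= 0))
    stop("'f_test' must be strictly positive", call. = FALSE)
  val <- (diet_value - f_mix * mixture_value) / f_test
  if (any(val < 0))
    warning("negative ingredient energy value by difference", call. = FALSE)
  val
}

#' Chain raw difference values onto the measured gross energy
#'
#' Computes the DE/GE, ME/DE and NE/ME ratios from the raw difference-method
#' values and applies them cumulatively to the ingredient's measured gross
#' energy, giving the final DE, ME and NE. Rows with non-positive raw GE, DE
#' or ME are flagged and their ratios and finals set to `NA` (chaining a
#' negative value has no physical meaning).
#'
#' @param ge_measured measured gross energy of the ingredient, MJ/kg DM.
#' @param ge_raw,de_raw,me_raw,ne_raw raw difference-method values, MJ/kg DM.
#' @param ingredient optional ingredient labels.
#' @return A data frame of class `ingredient_energy` with the raw values,
#'   ratios (`de_ge_pct`, `me_de_pct`, `ne_me_pct`) and chained finals
#'   (`de_final`, `me_final`, `ne_final`), plus a `flag_unchained` logical.
#' @export
#' @examples
#' ratio_chain(21.35, 21.35, 15.78, 14.04, 10.14)
ratio_chain <- function(ge_measured, ge_raw, de_raw, me_raw, ne_raw,
                        ingredient = NULL) {
  .check_nonneg(ge_measured, "ge_measured")
  n <- length(ge_measured)
  bad <- ge_raw <= 0 | de_raw <= 0 | me_raw <= 0
  if (any(bad))
    warning("non-positive raw energy values; ", sum(bad),
            " ingredient(s) left unchained", call. = FALSE)
  de_ge <- ifelse(bad, NA_real_, 100 * de_raw / ge_raw)
  me_de <- ifelse(bad, NA_real_, 100 * me_raw / de_raw)
  ne_me <- ifelse(bad, NA_real_, 100 * ne_raw / me_raw)
  de_f <- ge_measured * de_ge / 100
  me_f <- de_f * me_de / 100
  ne_f <- me_f * ne_me / 100
  out <- data.frame(
    ingredient = if (is.null(ingredient)) paste0("ingredient", seq_len(n))
                 else ingredient,
    ge_measured_mj_per_kg_dm = ge_measured,
    ge_raw = ge_raw, de_raw = de_raw, me_raw = me_raw, ne_raw = ne_raw,
    de_ge_pct = de_ge, me_de_pct = me_de, ne_me_pct = ne_me,
    de_final = de_f, me_final = me_f, ne_final = ne_f,
    flag_unchained = bad
  )
  class(out) <- c("ingredient_energy", "data.frame")
  out
}

#' Ingredient energy values by the difference method
#'
#' Full difference-method workflow: derives the basal-mixture GE/DE/ME/NE from
#' the basal diet, subtracts its contribution from every test diet, divides by
#' the test-ingredient inclusion fraction, and chains the resulting ratios
#' onto each ingredient's measured gross energy.
#'
#' @param diet_energy a `diet_energy` summary from [summarize_diet()], or any
#'   data frame with columns `diet_id`, `ge_mj_per_kg_dm`, `de_mj_per_kg_dm`,
#'   `me_mj_per_kg_dm`, `ne_mj_per_kg_dm`.
#' @param formulations long-format formulation table (columns `diet_id`,
#'   `ingredient`, `as_fed_pct`, `role`, optionally `dm_pct`); see
#'   [read_formulations()].
#' @param assays ingredient assay table with columns `ingredient` and
#'   `ge_mj_per_kg_dm` (the measured GE used for chaining).
#' @param basal_id `diet_id` of the basal diet.
#' @param dm_policy inclusion-fraction policy passed to [dm_fractions()].
#' @return An `ingredient_energy` data frame (see [ratio_chain()]), one row
#'   per test diet.
#' @export
ingredient_energy <- function(diet_energy, formulations, assays,
                              basal_id = "basal",
                              dm_policy = c("as-fed", "dm")) {
  dm_policy <- match.arg(dm_policy)
  check_columns(diet_energy,
                c("diet_id", "ge_mj_per_kg_dm", "de_mj_per_kg_dm",
                  "me_mj_per_kg_dm", "ne_mj_per_kg_dm"), "diet_energy")
  check_columns(formulations, c("diet_id", "ingredient", "as_fed_pct", "role"),
                "formulations")
  check_columns(assays, c("ingredient", "ge_mj_per_kg_dm"), "assays")
  if (!basal_id %in% diet_energy$diet_id)
    stop("basal diet '", basal_id, "' not found in diet_energy", call. = FALSE)

  vals <- function(id, col) diet_energy[[col]][diet_energy$diet_id == id][1]
  f_basal <- dm_fractions(formulations[formulations$diet_id == basal_id, ],
                          policy = dm_policy)
  mix <- vapply(c("ge_mj_per_kg_dm", "de_mj_per_kg_dm", "me_mj_per_kg_dm",
                  "ne_mj_per_kg_dm"),
                function(col) basal_mixture_energy(vals(basal_id, col),
                                                   f_basal$f_mix),
                numeric(1))

  test_ids <- setdiff(unique(as.character(diet_energy$diet_id)), basal_id)
  rows <- lapply(test_ids, function(id) {
    form <- formulations[formulations$diet_id == id, , drop = FALSE]
    if (!nrow(form))
      stop("no formulation rows for diet '", id, "'", call. = FALSE)
    f <- dm_fractions(form, policy = dm_policy)
    if (f$f_test <= 0)
      stop("diet '", id, "' has no test ingredient", call. = FALSE)
    ingr <- form$ingredient[form$role == "test"][1]
    ge_meas <- assays$ge_mj_per_kg_dm[assays$ingredient == ingr]
    if (!length(ge_meas))
      stop("no measured GE assay for ingredient '", ingr, "'", call. = FALSE)
    raw <- vapply(seq_along(mix), function(i) {
      col <- names(mix)[i]
      suppressWarnings(
        ingredient_by_difference(vals(id, col), mix[i], f$f_mix, f$f_test))
    }, numeric(1))
    data.frame(ingredient = ingr, diet_id = id, ge_measured = ge_meas[1],
               ge_raw = raw[1], de_raw = raw[2], me_raw = raw[3],
               ne_raw = raw[4])
  })
  raw <- do.call(rbind, rows)
  out <- ratio_chain(raw$ge_measured, raw$ge_raw, raw$de_raw, raw$me_raw,
                     raw$ne_raw, ingredient = raw$ingredient)
  out$diet_id <- raw$diet_id
  out
}

#' @export
print.ingredient_energy <- function(x, ...) {
  cols <- c("ingredient", "ge_measured_mj_per_kg_dm", "de_ge_pct",
            "me_de_pct", "ne_me_pct", "de_final", "me_final", "ne_final")
  if (!all(cols %in% names(x))) return(NextMethod())
  cat("Ingredient energy values by the difference method (MJ/kg DM)\n\n")
  df <- as.data.frame(x)[, cols]
  names(df) <- c("ingredient", "GE", "DE/GE%", "ME/DE%", "NE/ME%",
                 "DE", "ME", "NE")
  df[-1] <- lapply(df[-1], function(v) formatC(v, format = "f", digits = 2))
  print(df, row.names = FALSE)
  if (any(x$flag_unchained))
    cat("\nNote:", sum(x$flag_unchained), "ingredient(s) not chained",
        "(non-positive raw values)\n")
  invisible(x)
}
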