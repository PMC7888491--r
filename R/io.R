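# Tabular input/output: schema validation, delimiter-separated readers and
# writers, and accessors for the bundled rapeseed-meal reference tables.

#' Validate required columns of a table
#'
#' @param df data frame to check.
#' @param required character vector of required column names.
#' @param what label used in the error message.
#' @return `df`, invisibly; errors naming every missing column otherwise.
#' @export
check_columns <- function(df, required, what = "input") {
  if (!is.data.frame(df)) stop("'", what, "' must be a data frame",
                               call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Column schemas for the pipeline tables
#'
#' Required columns of the pig-period collection table and the gas-exchange
#' window table.
#'
#' @return Character vector of required column names.
#' @export
schema_energy_records <- function() {
  c("pig_id", "diet_id", "period", "bw_kg", "dm_intake_kg_per_d",
    "ge_intake_kj_per_d", "fecal_energy_kj_per_d", "urinary_energy_kj_per_d",
    "ch4_l_per_d", "n_intake_g_per_d", "fecal_n_g_per_d",
    "urinary_n_g_per_d")
}

#' @rdname schema_energy_records
#' @export
schema_gas_windows <- function() {
  c("pig_id", "diet_id", "period", "day", "state", "duration_h", "o2_l",
    "co2_l", "ch4_l", "urinary_n_g")
}

.read_tsv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read pipeline input tables
#'
#' Tab-delimited text with a header row; the schema is validated on read and
#' violations are reported with the offending column names.
#'
#' @param path file path.
#' @return A validated data frame.
#' @export
read_energy_records <- function(path) {
  df <- .read_tsv(path)
  check_columns(df, schema_energy_records(), path)
  if (any(df$dm_intake_kg_per_d <= 0))
    stop(path, ": 'dm_intake_kg_per_d' must be strictly positive",
         call. = FALSE)
  if (any(df$bw_kg <= 0))
    stop(path, ": 'bw_kg' must be strictly positive", call. = FALSE)
  df
}

#' @rdname read_energy_records
#' @export
read_gas_windows <- function(path) {
  df <- .read_tsv(path)
  check_columns(df, schema_gas_windows(), path)
  if (!all(df$state %in% c("fed", "fasted")))
    stop(path, ": 'state' must be \"fed\" or \"fasted\"", call. = FALSE)
  if (any(df$duration_h <= 0 | df$duration_h > 24))
    stop(path, ": 'duration_h' must be in (0, 24]", call. = FALSE)
  df
}

#' @rdname read_energy_records
#' @export
read_formulations <- function(path) {
  df <- .read_tsv(path)
  check_columns(df, c("diet_id", "ingredient", "as_fed_pct", "role"), path)
  df
}

#' @rdname read_energy_records
#' @export
read_sample_panel <- function(path) {
  df <- .read_tsv(path)
  check_columns(df, c("sample_id", "ne"), path)
  df
}

#' Write a pipeline table
#'
#' Tab-delimited, header row, no quoting or row names, full precision —
#' the machine-readable counterpart of the formatted print methods.
#'
#' @param df data frame to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "neval")
  if (path == "") stop("bundled file not found: ", file, call. = FALSE)
  path
}

#' Bundled rapeseed-meal reference tables
#'
#' Small reference tables for a six-diet rapeseed-meal (RSM) chamber
#' experiment with growing pigs: analyzed composition of the five RSM
#' ingredients (two expeller-pressed, three solvent-extracted),
#' formulations and analyzed composition of the basal and five test diets,
#' the diet-level energy and nitrogen balance summary, the per-ingredient
#' digestibility/energy reference, and the five-sample prediction panel
#' (composition joined with determined energy values). `rsm_panel()` also
#' documents the append template (`rsm_panel_template.tsv`) for extending the
#' panel with additional determined samples before refitting equations.
#'
#' @return A data frame (see each file's header for columns and units:
#'   composition in % of DM, energies in MJ/kg DM, balance terms in kJ/kg
#'   BW^0.6/d).
#' @export
rsm_composition <- function() .read_tsv(.extdata("rsm_composition.tsv"))

#' @rdname rsm_composition
#' @export
rsm_diet_formulations <- function() read_formulations(
  .extdata("diet_formulations.tsv"))

#' @rdname rsm_composition
#' @export
rsm_diet_composition <- function() .read_tsv(.extdata("diet_composition.tsv"))

#' @rdname rsm_composition
#' @export
rsm_diet_reference <- function() .read_tsv(.extdata("diet_energy_reference.tsv"))

#' @rdname rsm_composition
#' @export
rsm_ingredient_reference <- function()
  .read_tsv(.extdata("ingredient_energy_reference.tsv"))

#' @rdname rsm_composition
#' @export
rsm_panel <- function() read_sample_panel(.extdata("rsm_panel.tsv"))

#' Catalogue of published-form NE prediction equations
#'
#' The four stepwise NE prediction equations for rapeseed meal shipped with
#' the package, in long form: one row per term with its estimate, plus the
#' equation-level metrics (R2, AIC, RMSE, p, n). Terms use lowercase
#' predictor names (`de`, `cp`, `me`, `ge`, `ee`, `ash`, `intercept`);
#' composition is % of DM, energies MJ/kg DM. Pass a subset to
#' [apply_equation()] to predict NE for a sample.
#'
#' @param number optional equation number(s) to filter to.
#' @return A data frame with columns `equation`, `term`, `estimate`, `r2`,
#'   `aic`, `rmse`, `p_value`, `n`.
#' @export
#' @examples
#' apply_equation(ne_equations(2), data.frame(me = 14.04))
ne_equations <- function(number = NULL) {
  df <- .read_tsv(.extdata("ne_equations.tsv"))
  if (!is.null(number)) df <- df[df$equation %in% number, , drop = FALSE]
  df
}
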