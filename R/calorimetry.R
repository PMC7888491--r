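# Indirect calorimetry: Brouwer heat production, respiratory quotient,
# fasting heat production, and the inverse gas-from-heat computation used by
# the synthetic-data generator. Canonical units throughout: kJ, L, g, kg.

.check_nonneg <- function(x, field) {
  if (any(!is.finite(x)) | any(x < 0))
    stop(sprintf("'%s' must be finite and non-negative", field), call. = FALSE)
  invisible(x)
}

#' Brouwer coefficient set
#'
#' Coefficients of the Brouwer equation for heat production from gas exchange
#' and urinary nitrogen, plus the energetic value of methane. Defaults are the
#' standard constants used in pig calorimetry:
#' THP (kJ) = 16.18 O2 (L) + 5.02 CO2 (L) - 2.17 CH4 (L) - 5.99 urinary N (g),
#' with methane carrying 39.54 kJ of gross energy per litre.
#'
#' @param o2,co2,ch4 kJ per litre of O2 consumed, CO2 produced, CH4 produced.
#' @param urinary_n kJ per gram of urinary nitrogen.
#' @param methane_ge gross energy of methane, kJ per litre.
#' @return An object of class `brouwer_coefficients`.
#' @export
#' @examples
#' brouwer_coefficients()
brouwer_coefficients <- function(o2 = 16.18, co2 = 5.02, ch4 = 2.17,
                                 urinary_n = 5.99, methane_ge = 39.54) {
  vals <- c(o2 = o2, co2 = co2, ch4 = ch4, urinary_n = urinary_n,
            methane_ge = methane_ge)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Brouwer coefficients must be finite and strictly positive",
         call. = FALSE)
  structure(as.list(vals), class = "brouwer_coefficients")
}

#' @export
print.brouwer_coefficients <- function(x, ...) {
  cat("Brouwer coefficients (kJ/L; urinary N kJ/g):\n")
  cat(sprintf("  O2 %.2f  CO2 %.2f  CH4 %.2f  urinary N %.2f  CH4 GE %.2f\n",
              x$o2, x$co2, x$ch4, x$urinary_n, x$methane_ge))
  invisible(x)
}

#' Gas-exchange measurement window
#'
#' One chamber measurement window: gas volumes over a stated duration, the
#' nutritional state of the animal, and the urinary nitrogen excretion
#' attributable to the window. For fed windows `urinary_n_g` is the excretion
#' over the window itself; for fasted windows it is, by convention, the full
#' 24-h fasting excretion (see [fasting_heat_production()]).
#'
#' @param o2_l,co2_l,ch4_l gas volumes over the window, L.
#' @param duration_h window length in hours, in (0, 24].
#' @param state `"fed"` or `"fasted"`.
#' @param urinary_n_g urinary nitrogen, g.
#' @return An object of class `gas_window`.
#' @export
#' @examples
#' gas_window(1500, 1650, ch4_l = 4, urinary_n_g = 13.5)
gas_window <- function(o2_l, co2_l, ch4_l = 0, duration_h = 24,
                       state = c("fed", "fasted"), urinary_n_g = 0) {
  state <- match.arg(state)
  .check_nonneg(o2_l, "o2_l")
  .check_nonneg(co2_l, "co2_l")
  .check_nonneg(ch4_l, "ch4_l")
  .check_nonneg(urinary_n_g, "urinary_n_g")
  if (!is.finite(duration_h) || duration_h <= 0 || duration_h > 24)
    stop("'duration_h' must be in (0, 24]", call. = FALSE)
  structure(list(o2_l = o2_l, co2_l = co2_l, ch4_l = ch4_l,
                 duration_h = duration_h, state = state,
                 urinary_n_g = urinary_n_g),
            class = "gas_window")
}

#' @export
print.gas_window <- function(x, ...) {
  cat(sprintf("<gas_window %s, %g h>  O2 %g L  CO2 %g L  CH4 %g L  urinary N %g g\n",
              x$state, x$duration_h, x$o2_l, x$co2_l, x$ch4_l, x$urinary_n_g))
  invisible(x)
}

# vectorised Brouwer kernel, kJ
.brouwer <- function(o2_l, co2_l, ch4_l, urinary_n_g, coeffs) {
  coeffs$o2 * o2_l + coeffs$co2 * co2_l - coeffs$ch4 * ch4_l -
    coeffs$urinary_n * urinary_n_g
}

#' Heat production over a window (Brouwer equation)
#'
#' Applies the Brouwer equation to the gases and urinary nitrogen of a
#' measurement window and returns the heat produced over that window in kJ.
#' No clamping is applied; impossible (negative) inputs raise errors.
#'
#' @param window a [gas_window()], or a data frame with columns `o2_l`,
#'   `co2_l`, `ch4_l`, `urinary_n_g` (vectorised over rows).
#' @param coeffs a [brouwer_coefficients()] set.
#' @return Heat production in kJ over the window (numeric, one per row for
#'   data-frame input).
#' @export
#' @examples
#' brouwer_thp(gas_window(1500, 1650, ch4_l = 4, urinary_n_g = 13.5))
brouwer_thp <- function(window, coeffs = brouwer_coefficients()) {
  if (inherits(window, "gas_window")) {
    return(.brouwer(window$o2_l, window$co2_l, window$ch4_l,
                    window$urinary_n_g, coeffs))
  }
  if (is.data.frame(window)) {
    for (f in c("o2_l", "co2_l", "ch4_l", "urinary_n_g"))
      .check_nonneg(window[[f]], f)
    return(.brouwer(window$o2_l, window$co2_l, window$ch4_l,
                    window$urinary_n_g, coeffs))
  }
  stop("'window' must be a gas_window or a data frame of windows",
       call. = FALSE)
}

#' Respiratory quotient
#'
#' Ratio of CO2 produced to O2 consumed over a window.
#'
#' @param co2_l CO2 produced, L.
#' @param o2_l O2 consumed, L; must be strictly positive.
#' @return Dimensionless RQ.
#' @export
#' @examples
#' respiratory_quotient(1650, 1500)
respiratory_quotient <- function(co2_l, o2_l) {
  .check_nonneg(co2_l, "co2_l")
  if (any(!is.finite(o2_l)) || any(o2_l <= 0))
    stop("'o2_l' must be strictly positive", call. = FALSE)
  co2_l / o2_l
}

#' Energy lost as methane
#'
#' @param ch4_l methane produced, L.
#' @param coeffs a [brouwer_coefficients()] set (uses `methane_ge`, kJ/L).
#' @return Energy in kJ.
#' @export
#' @examples
#' methane_energy(4)
methane_energy <- function(ch4_l, coeffs = brouwer_coefficients()) {
  .check_nonneg(ch4_l, "ch4_l")
  coeffs$methane_ge * ch4_l
}

#' Metabolic body weight
#'
#' Body weight raised to the 0.6 power, the scaling base used for feed
#' allowance and heat production in growing pigs.
#'
#' @param bw_kg body weight, kg; strictly positive.
#' @return BW^0.6, kg^0.6.
#' @export
#' @examples
#' metabolic_weight(47.82)
metabolic_weight <- function(bw_kg) {
  if (any(!is.finite(bw_kg)) || any(bw_kg <= 0))
    stop("'bw_kg' must be strictly positive", call. = FALSE)
  bw_kg^0.6
}

# 24-h fasting heat production from a fasted window. urinary_n_g is the
# 24-h fasting excretion: duration_h/24 of it is charged to the window before
# Brouwer, and the whole window is then rescaled by 24/duration_h, which is
# algebraically the gas terms scaled to 24 h minus the full daily N term.
.fhp24 <- function(o2_l, co2_l, ch4_l, urinary_n_daily_g, duration_h, coeffs) {
  scale <- 24 / duration_h
  (coeffs$o2 * o2_l + coeffs$co2 * co2_l - coeffs$ch4 * ch4_l) * scale -
    coeffs$urinary_n * urinary_n_daily_g
}

#' Fasting heat production on a 24-h basis
#'
#' Computes fasting heat production (FHP) from a fasted-state window
#' (typically the last 8 h of the fasting day) and extrapolates it linearly
#' to a 24-h period. The window's `urinary_n_g` is interpreted as the full
#' 24-h fasting urinary nitrogen excretion; `duration_h/24` of it is assigned
#' to the window before applying the Brouwer equation, so the rescaled result
#' charges the daily nitrogen exactly once.
#'
#' @param window a fasted-state [gas_window()].
#' @param bw_kg optional body weight, kg, for the per-metabolic-weight value.
#' @param coeffs a [brouwer_coefficients()] set.
#' @return An object of class `heat_production`: a list with
#'   `thp_kj_per_d` (kJ/d), `per_mbw` (kJ/kg BW^0.6/d, `NA` without `bw_kg`)
#'   and `rq`.
#' @export
#' @examples
#' w <- gas_window(100, 81, duration_h = 8, state = "fasted", urinary_n_g = 9)
#' fasting_heat_production(w, bw_kg = 45)
fasting_heat_production <- function(window, bw_kg = NULL,
                                    coeffs = brouwer_coefficients()) {
  if (!inherits(window, "gas_window"))
    stop("'window' must be a gas_window", call. = FALSE)
  if (window$state != "fasted")
    stop("fasting heat production requires a fasted-state window",
         call. = FALSE)
  thp <- .fhp24(window$o2_l, window$co2_l, window$ch4_l, window$urinary_n_g,
                window$duration_h, coeffs)
  per_mbw <- if (is.null(bw_kg)) NA_real_ else thp / metabolic_weight(bw_kg)
  rq <- if (window$o2_l > 0) window$co2_l / window$o2_l else NA_real_
  structure(list(thp_kj_per_d = thp, per_mbw = per_mbw, rq = rq),
            class = "heat_production")
}

#' @export
print.heat_production <- function(x, ...) {
  cat(sprintf("Heat production: %.0f kJ/d", x$thp_kj_per_d))
  if (!is.na(x$per_mbw)) cat(sprintf("  (%.0f kJ/kg BW^0.6/d)", x$per_mbw))
  if (!is.na(x$rq)) cat(sprintf("  RQ %.2f", x$rq))
  cat("\n")
  invisible(x)
}

#' Gas volumes implied by a heat production and respiratory quotient
#'
#' Inverts the Brouwer equation: given a target heat production, an RQ, and
#' the methane and urinary-nitrogen terms, returns the O2 and CO2 volumes
#' that reproduce the heat exactly. Used by the synthetic-data generator so
#' that simulated chamber records conserve energy by construction.
#'
#' @param thp_kj heat production to reproduce, kJ (non-negative).
#' @param rq respiratory quotient, in (0.6, 1.3).
#' @param ch4_l methane over the window, L.
#' @param urinary_n_g urinary nitrogen charged to the window, g.
#' @param coeffs a [brouwer_coefficients()] set.
#' @return A data frame with columns `o2_l` and `co2_l` (vectorised).
#' @export
#' @examples
#' gas_from_heat(32463.455, rq = 1.10, ch4_l = 4, urinary_n_g = 13.5)
gas_from_heat <- function(thp_kj, rq, ch4_l = 0, urinary_n_g = 0,
                          coeffs = brouwer_coefficients()) {
  .check_nonneg(thp_kj, "thp_kj")
  .check_nonneg(ch4_l, "ch4_l")
  .check_nonneg(urinary_n_g, "urinary_n_g")
  if (any(!is.finite(rq)) || any(rq <= 0.6) || any(rq >= 1.3))
    stop("'rq' must lie in (0.6, 1.3)", call. = FALSE)
  denom <- coeffs$o2 + coeffs$co2 * rq
  if (any(denom <= 0))
    stop("non-positive Brouwer denominator; check coefficients", call. = FALSE)
  o2 <- (thp_kj + coeffs$ch4 * ch4_l + coeffs$urinary_n * urinary_n_g) / denom
  data.frame(o2_l = o2, co2_l = rq * o2)
}
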