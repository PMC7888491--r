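---
title: "Net energy evaluation of pig feeds: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net energy evaluation of pig feeds: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neval)
```

## The problem

Feed tables for pigs express the useful energy of an ingredient at three
levels: digestible energy (DE) nets out fecal losses from gross energy (GE),
metabolizable energy (ME) further nets out urinary and methane losses, and
net energy (NE) additionally nets out the heat increment of feeding. NE is
the level that tracks animal performance best — especially for high-fibre
protein sources such as rapeseed meal, whose heat increment is large — but it
is also the hardest to measure: it requires indirect calorimetry in
respiration chambers. This package implements the complete calculation chain
of such an experiment, from raw gas-exchange and collection records to
ingredient NE values and prediction equations, together with a simulator
that generates whole experiments with known ground truth.

## Energy partition model

For each pig in each measurement period the package computes:

* **Total heat production (THP)** from gas exchange and urinary nitrogen by
  the Brouwer equation,
  `THP (kJ) = 16.18 O2 (L) + 5.02 CO2 (L) − 2.17 CH4 (L) − 5.99 N (g)`.
  The coefficients live in a single `brouwer_coefficients()` object so they
  are stated once and testable. Heat is never clamped: physically impossible
  inputs raise errors instead of being silently truncated.
* **Fasting heat production (FHP)** from a fasted-state window, by default
  the last 8 h of the fasting day, extrapolated linearly to 24 h
  (`× 24/duration`). Fasting urine is collected over 24 h, so the window is
  charged `duration/24` of the daily urinary N before scaling — algebraically
  the same as charging the daily N once, which is how
  `fasting_heat_production()` implements it.
* **DE and ME** per kg of dry matter from measured GE intake and fecal,
  urinary and methane energy (39.54 kJ per litre of CH4).
* **Retained energy** RE = ME intake − THP, split into protein retention
  RE~P~ = N retention × 6.25 × 23.86 kJ/g and lipid retention
  RE~L~ = RE − RE~P~. The split is computed per pig before any averaging, so
  RE = RE~P~ + RE~L~ holds exactly for diet means as well.
* **NE** = (RE + FHP)/DM intake. By default each pig's own FHP enters its NE
  (`fhp_policy = "per-pig"`), because FHP varies between pigs and using the
  same pig's value removes that variance from the diet contrast; diet-mean
  and fixed-value policies are available for sensitivity analysis.

Heat and retention quantities are reported per kg metabolic body weight,
BW^0.6^, the scaling base used for feed allowance in this kind of study. The
body weight used is the period record's weight; whether a study weighs pigs
at chamber entry or mid-period differs between labs, so the input schema
simply carries one `bw_kg` per record and the choice is the user's.

Internally everything is in kJ, L, g and kg; MJ appears only in reporting,
which avoids unit mistakes in the middle of the chain.

## The difference method and ratio chaining

Test diets substitute 19.5% of the test ingredient for the corn–soybean-meal
mixture of the basal diet (78% mixture, 2.5% minerals and premix). The
mineral fraction is treated as energy-free, which is why the basal diet's
values are divided by 0.975 to obtain the mixture's values
(`basal_mixture_energy()`). The ingredient's raw value is then

```
ingredient = (diet − f_mix × mixture) / f_test
```

Inclusion fractions are nominally on the dry-matter basis. When per-ingredient
DM contents are available, `dm_fractions(..., policy = "dm")` converts as-fed
inclusions through them; the default falls back to the as-fed fractions
(0.78/0.195), a documented approximation that is exact when all ingredients
have equal DM content. Because the difference formula is linear, differencing
per pig and then averaging gives the same answer as differencing the diet
means; the package computes on diet means and tests the linearity property
explicitly.

Raw difference values inherit the noise of two diets divided by a small
inclusion fraction, so the headline outputs are *ratio-chained*: the DE/GE,
ME/DE and NE/ME ratios from the raw values are applied cumulatively to the
ingredient's measured GE (`ratio_chain()`). Negative raw values, which can
occur under noise, are flagged and left unchained rather than propagated
into meaningless ratios.

## Prediction equations

`fit_ols()` reports the metric set used to select feed-evaluation equations:
R², RMSE with the residual degrees of freedom `n − p − 1`, and
AIC = `n·log(SSE/n) + 2(p + 1)`. This log-SSE AIC is the SAS PROC REG
definition; it is the only common variant that produces the negative AIC
values typical of these small panels, and it is what `best_subset()`
minimises. `stepwise_select()` is the SAS stepwise algorithm — forward entry
by the smallest partial-F p-value (default thresholds 0.15/0.15, the SAS
defaults, configurable), with backward elimination after each entry.
`ne_equation_search()` runs it within the four candidate families used for
NE equations (chemical composition only, or chemical composition plus GE,
DE or ME) and ranks the winners by greatest R², then least RMSE, then AIC.

Greedy stepwise search is not guaranteed to find the AIC-optimal subset; on
randomized four-predictor panels with the entry threshold calibrated to the
AIC comparison the two agree almost always, and the test suite asserts both
the agreement on such panels and the universal inequality (stepwise AIC ≥
best-subset AIC).

The four published-form equations shipped in `ne_equations()` were estimated
on eight rapeseed-meal samples; only five of those samples are bundled here
(the other three come from companion experiments), so the catalogue is
shipped as data rather than refitted, and `rsm_panel_template.tsv` documents
the schema for appending the missing samples — or new ones — before calling
`ne_equation_search()` on an extended panel.

## What the simulator emulates

`generate_experiment()` builds a complete chamber experiment under a
`truth_config()`. The bundled `rsm_study_preset()` encodes the study
conditions of a six-diet rapeseed-meal evaluation: 6 pigs per diet measured
across 6 periods, body weight 41.1 ± 2.2 kg at the start and growing by
2.6 kg per period (a realistic restricted-feeding gain that reproduces the
41→48 kg range across periods), feed allowance 2000 kJ ME/kg BW^0.6^/d, FHP
790 kJ/kg BW^0.6^/d, fed/fasted respiratory quotients 1.07/0.81, five 24-h
fed windows and one 8-h fasted window per pig. True diet energies are
composed from the bundled mixture and ingredient values, so the difference
method's target is known exactly.

The generator works backwards from the truth: ME intake follows the feeding
level, losses are decomposed from the true GE/DE/ME (with a configurable 10%
of the DE−ME gap as methane, the rest urinary), THP = ME − RE with RE fixed
by the true NE and FHP, and gas volumes are obtained by inverting the
Brouwer equation at the configured RQ (`gas_from_heat()`). Nitrogen flows
come from dietary crude protein, the true CP digestibility and a
retention-fraction draw; fasting urinary N defaults to 8 g/d, a typical
value for 45-kg fasted pigs. At zero noise this construction closes the
energy balance identically — GE intake = fecal + urinary + methane + THP +
RE to better than 10^−9^ relative — which is the property that makes the
whole pipeline verifiable end to end.

Noise is multiplicative log-normal per observable with mean exactly one
(CVs: intake 2%, gas volumes 3%, fecal energy 5%, urinary and methane energy
10%, nitrogen terms 8–10%), and logit-scale normal (SD 0.10) for
digestibilities so they stay in (0, 1). These defaults were chosen so
diet-level standard errors over six pigs have the magnitudes seen in
chamber studies of this size; per-observable CVs are not identifiable from
published standard errors alone, so the calibration is approximate by
design. One master seed drives a single base-R RNG stream consumed in a
fixed record order, which makes every dataset exactly reproducible from its
seed. What the simulator does *not* emulate: within-day activity patterns,
gas-analyzer drift, carry-over between periods, glucosinolate effects on
intake, and the intermediate maintenance-level feeding days — real
experiments insert those between the fed and fasted states, but their heat
data do not enter the balance, so they are not generated.

`generate_ingredient_panel()` plays the same role for the regression stage:
compositions are drawn from a multivariate normal whose default correlation
matrix plants the structure seen across rapeseed meals (EE–CP strongly
negative, NDF–ADF strongly positive, starch against the fibres negative),
and energies follow configurable linear truths (GE rising tightly with EE,
DE falling with NDF, NE = 0.85 ME − 1.48 with residual SD 0.36 MJ/kg DM).
Rows violating positivity or the GE ≥ DE ≥ ME ≥ NE ordering are redrawn,
which slightly truncates the tails but keeps every sample physically
meaningful.

Passing tests on simulated data show that the *calculations* are correct and
that the estimators recover known truths under realistic noise; they cannot
show that real chambers are free of the systematic errors (drift,
incomplete collection) that the noise model does not represent.

## Numerical choices and degenerate inputs

* Tolerances: energy closure is asserted to 10^−9^ relative, the
  Brouwer/`gas_from_heat()` round trip to 10^−10^, OLS against a
  normal-equations oracle to 10^−8^.
* A perfect fit (SSE = 0) yields RMSE 0 and AIC −∞; the overall F-test
  p-value is undefined and returned as `NA`.
* Rank-deficient regression designs are refused with the collinear columns
  named; constant columns make a correlation undefined and are likewise an
  error, not an `NA`.
* Negative nitrogen retention or retained energy is retained and flagged
  (`flag_negative_*` columns), never clamped; negative raw difference values
  warn and block ratio chaining for that ingredient only.
* Equation-family ties are broken by R², then RMSE, then AIC, in that order.
* Problem sizes in the test suite are chosen to keep the default run fast:
  the recovery study uses 200 replicate experiments of 36 pigs, the
  coverage study 1000 replicates of 8 samples, and property loops 10–50
  random cases each; the full suite runs in well under a minute.

## Known limitations

* The bundled reference tables are printed to 1–2 decimals; calculations
  that chain several printed ratios can differ from a printed final value by
  up to the propagated rounding (about 0.02 MJ/kg DM), which the tests
  account for explicitly.
* The difference method assumes the basal mixture's energy values are the
  same in basal and test diets; interactions between the test ingredient and
  the mixture (e.g. fibre depressing the digestibility of the rest of the
  diet) are attributed to the ingredient.
* Mixed-model inference across diets (standard errors, p-values with period
  and chamber as random effects) is out of scope; the summaries are
  unweighted means.
* The stepwise/best-subset agreement is an empirical regularity at
  calibrated thresholds, not a theorem; for definitive selection on small
  panels use `best_subset()` directly.
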