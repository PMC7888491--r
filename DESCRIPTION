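Package: neval
Title: Net Energy Evaluation of Pig Feeds from Indirect Calorimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for net-energy (NE) evaluation of pig feed ingredients from
    respiration-chamber experiments. Computes heat production from gas exchange
    and urinary nitrogen with the Brouwer equation, fasting heat production on a
    metabolic body-weight basis, apparent total-tract digestibility, nitrogen
    balance, and the full dietary energy partition (DE, ME, retained energy and
    its protein and lipid components, NE). Derives ingredient energy values from
    basal and test diets by the difference method with gross-energy ratio
    chaining, and builds NE prediction equations by SAS-style stepwise
    regression with R-squared, RMSE and AIC model selection. Includes an
    energy-conserving synthetic chamber-experiment generator with known ground
    truth so the whole pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
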