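# NE prediction: correlation analysis across ingredient samples, ordinary
# least squares with the SAS-style metric set (R2, RMSE, log-SSE AIC), SAS
# stepwise selection by partial F, an exhaustive best-subset oracle, and
# application of fitted or catalogued equations.

.as_pred_matrix <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  x
}

#' Ordinary least squares with SAS-style selection metrics
#'
#' Fits `y ~ intercept + x` by QR least squares and reports the metric set
#' used for equation selection: R2 = 1 - SSE/SST, RMSE = sqrt(SSE/(n-p-1))
#' with p predictors, AIC = n*log(SSE/n) + 2(p+1) (the log-SSE form used by
#' SAS PROC REG, which is the only form consistent with negative AIC values
#' at these problem sizes), and the overall F-test p-value. With zero
#' predictors an intercept-only model is fitted.
#'
#' @param y numeric response vector (MJ/kg DM for NE equations).
#' @param x matrix or data frame of predictors (columns named), or `NULL`.
#' @param response name of the response, for reporting.
#' @return An object of class `ne_model`: coefficients (intercept first),
#'   standard errors, `r2`, `rmse`, `aic`, `overall_p`, `n`, `df_residual`,
#'   fitted values and residuals. Supports [coef()], [predict()],
#'   [residuals()], [summary()] and [print()].
#' @export
#' @examples
#' fit_ols(c(1, 2, 2), data.frame(x = 1:3))
fit_ols <- function(y, x = NULL, response = "ne") {
  y <- as.numeric(y)
  X <- .as_pred_matrix(x)
  n <- length(y)
  p <- if (nrow(X)) ncol(X) else 0L
  if (p > 0 && nrow(X) != n) stop("nrow(x) must match length(y)", call. = FALSE)
  if (n <= p + 1)
    stop(sprintf("need n > p + 1 observations (n = %d, p = %d)", n, p),
         call. = FALSE)
  M <- cbind(`(intercept)` = rep(1, n), if (p) X)
  fit <- lm.fit(M, y)
  if (fit$rank < ncol(M)) {
    bad <- colnames(M)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  dfres <- n - p - 1
  sigma2 <- sse / dfres
  covb <- chol2inv(chol(crossprod(M))) * sigma2
  fstat <- if (p > 0 && sse > 0) ((sst - sse) / p) / sigma2 else NA_real_
  structure(list(
    response = response,
    predictors = if (p) colnames(X) else character(0),
    coefficients = fit$coefficients,
    se = sqrt(diag(covb)),
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = sqrt(sigma2),
    aic = if (sse > 0) n * log(sse / n) + 2 * (p + 1) else -Inf,
    overall_p = if (!is.na(fstat)) pf(fstat, p, dfres, lower.tail = FALSE)
                else NA_real_,
    n = n, df_residual = dfres, sse = sse,
    fitted = fit$fitted.values, residuals = res, y = y
  ), class = "ne_model")
}

#' @export
coef.ne_model <- function(object, ...) object$coefficients

#' @export
residuals.ne_model <- function(object, ...) object$residuals

#' @export
predict.ne_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  apply_equation(object, newdata)
}

#' @export
print.ne_model <- function(x, ...) {
  cat(sprintf("NE prediction model: %s ~ %s  (n = %d)\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$n))
  b <- x$coefficients
  terms <- sprintf("%+.4g x %s", b[-1], names(b)[-1])
  cat("  ", x$response, " = ", paste(c(terms, sprintf("%+.4g", b[1])),
                                     collapse = " "), "\n", sep = "")
  cat(sprintf("  R2 = %.3f  RMSE = %.3f  AIC = %.2f  p = %s\n",
              x$r2, x$rmse, x$aic, format.pval(x$overall_p, digits = 3)))
  invisible(x)
}

#' @export
summary.ne_model <- function(object, ...) {
  tval <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = tval,
               `Pr(>|t|)` = 2 * pt(-abs(tval), object$df_residual))
  out <- list(model = object, coefficients = tab)
  class(out) <- "summary.ne_model"
  out
}

#' @export
print.summary.ne_model <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  printCoefmat(x$coefficients)
  invisible(x)
}

# partial-F p-values for adding each candidate to the current predictor set
.entry_pvalues <- function(y, X, current, candidates) {
  n <- length(y)
  base <- fit_ols(y, if (length(current)) X[, current, drop = FALSE])
  vapply(candidates, function(j) {
    if (n <= length(current) + 2) return(NA_real_)
    trial <- fit_ols(y, X[, c(current, j), drop = FALSE])
    if (trial$sse <= 0) return(0)
    f <- (base$sse - trial$sse) / (trial$sse / trial$df_residual)
    pf(f, 1, trial$df_residual, lower.tail = FALSE)
  }, numeric(1))
}

#' Stepwise predictor selection by partial F-tests
#'
#' SAS-style stepwise regression: at each step the candidate with the
#' smallest partial-F p-value enters if it is at most `alpha_enter`, then
#' included predictors with p-values above `alpha_stay` are eliminated one at
#' a time. Stops when no predictor can enter or leave, or when a predictor
#' set repeats. If nothing qualifies, an intercept-only model is returned
#' with a warning.
#'
#' @param y numeric response vector.
#' @param x matrix or data frame of candidate predictors.
#' @param alpha_enter,alpha_stay significance levels to enter and to stay,
#'   both in (0, 1); 0.15 is the SAS default.
#' @param candidates optional character vector restricting the candidate
#'   columns of `x` (used for equation families, e.g. chemical-only or
#'   chemical + DE).
#' @return An `ne_model` (see [fit_ols()]) with a `steps` attribute tracing
#'   the selection path.
#' @export
stepwise_select <- function(y, x, alpha_enter = 0.15, alpha_stay = 0.15,
                            candidates = NULL) {
  if (alpha_enter <= 0 || alpha_enter >= 1 || alpha_stay <= 0 ||
      alpha_stay >= 1)
    stop("'alpha_enter' and 'alpha_stay' must lie in (0, 1)", call. = FALSE)
  X <- .as_pred_matrix(x)
  pool <- if (is.null(candidates)) colnames(X) else {
    miss <- setdiff(candidates, colnames(X))
    if (length(miss))
      stop("candidate predictor(s) not in x: ", paste(miss, collapse = ", "),
           call. = FALSE)
    candidates
  }
  current <- character(0)
  seen <- character(0)
  steps <- list()
  repeat {
    moved <- FALSE
    avail <- setdiff(pool, current)
    if (length(avail) && length(y) > length(current) + 2) {
      pv <- .entry_pvalues(y, X, current, avail)
      if (any(!is.na(pv)) && min(pv, na.rm = TRUE) <= alpha_enter) {
        j <- avail[which.min(pv)]
        current <- c(current, j)
        steps[[length(steps) + 1L]] <- list(action = "enter", term = j,
                                            p = min(pv, na.rm = TRUE))
        moved <- TRUE
      }
    }
    # backward elimination on the current set
    repeat {
      if (!length(current)) break
      m <- fit_ols(y, X[, current, drop = FALSE])
      tval <- m$coefficients[-1] / m$se[-1]
      pv <- 2 * pt(-abs(tval), m$df_residual)
      if (max(pv) > alpha_stay) {
        k <- current[which.max(pv)]
        current <- setdiff(current, k)
        steps[[length(steps) + 1L]] <- list(action = "remove", term = k,
                                            p = max(pv))
        moved <- TRUE
      } else break
    }
    state <- paste(sort(current), collapse = "+")
    if (!moved || state %in% seen) break
    seen <- c(seen, state)
  }
  if (!length(current)) {
    warning("no predictor met the entry criterion; intercept-only model",
            call. = FALSE)
    out <- fit_ols(y, NULL)
  } else {
    out <- fit_ols(y, X[, current, drop = FALSE])
  }
  attr(out, "steps") <- steps
  out
}

#' Exhaustive best-subset selection by AIC
#'
#' Enumerates every predictor subset of size at most `max_terms` and returns
#' the fit minimising AIC (ties broken toward fewer terms). Serves as the
#' independent oracle for [stepwise_select()].
#'
#' @param y numeric response vector.
#' @param x matrix or data frame of candidate predictors.
#' @param max_terms largest subset size to consider.
#' @return An `ne_model` with a `search` attribute listing every subset and
#'   its AIC.
#' @export
best_subset <- function(y, x, max_terms = NULL) {
  X <- .as_pred_matrix(x)
  p <- ncol(X)
  if (is.null(max_terms)) max_terms <- p
  max_terms <- min(max_terms, p, length(y) - 2)
  n_sub <- sum(choose(p, 0:max_terms))
  if (n_sub > 1e5)
    stop("more than 1e5 candidate subsets; restrict max_terms", call. = FALSE)
  subsets <- list(character(0))
  for (k in seq_len(max_terms))
    subsets <- c(subsets, combn(colnames(X), k, simplify = FALSE))
  aics <- vapply(subsets, function(s)
    fit_ols(y, if (length(s)) X[, s, drop = FALSE])$aic, numeric(1))
  sizes <- lengths(subsets)
  best <- order(aics, sizes)[1]
  out <- fit_ols(y, if (length(subsets[[best]]))
    X[, subsets[[best]], drop = FALSE])
  attr(out, "search") <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = sizes, aic = aics)
  out
}

#' Pairwise Pearson correlations with p-values
#'
#' Pearson correlation matrix across the given columns, with two-sided
#' p-values from the t distribution with n - 2 degrees of freedom.
#'
#' @param panel data frame of ingredient samples (e.g. composition and
#'   energy columns).
#' @param vars columns to correlate; defaults to all numeric columns.
#' @return A list of class `ne_cor` with matrices `r` and `p` and the sample
#'   size `n`.
#' @export
#' @examples
#' pearson_matrix(data.frame(x = 1:4, y = c(2, 4, 5, 9)))
pearson_matrix <- function(panel, vars = NULL) {
  df <- as.data.frame(panel)
  if (is.null(vars)) vars <- names(df)[vapply(df, is.numeric, logical(1))]
  X <- as.matrix(df[, vars, drop = FALSE])
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(vars[sds == 0], collapse = ", "),
         "; correlation undefined", call. = FALSE)
  r <- cor(X)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "ne_cor")
}

#' @export
print.ne_cor <- function(x, digits = 2, ...) {
  cat("Pearson correlations (n =", x$n, "); upper triangle: p-values\n")
  m <- x$r
  m[upper.tri(m)] <- x$p[upper.tri(m)]
  print(round(m, digits))
  invisible(x)
}

#' Apply a prediction equation to a sample
#'
#' Evaluates a linear NE prediction equation — a fitted `ne_model`, a subset
#' of the [ne_equations()] catalogue (columns `term`, `estimate`), or a named
#' numeric vector with an `"(intercept)"` or `"intercept"` element — on one
#' or more samples. Composition predictors are in % of DM and energy
#' predictors in MJ/kg DM, matching the equation catalogue.
#'
#' @param equation the equation in one of the three forms above.
#' @param sample a data frame (or named list) holding every predictor the
#'   equation needs; a missing field is an error naming it.
#' @return Predicted NE, MJ/kg DM.
#' @export
#' @examples
#' eq <- ne_equations()
#' apply_equation(eq[eq$equation == 2, ], data.frame(me = 14.04))
apply_equation <- function(equation, sample) {
  if (inherits(equation, "ne_model")) {
    coefs <- equation$coefficients
  } else if (is.data.frame(equation)) {
    check_columns(equation, c("term", "estimate"), "equation")
    coefs <- setNames(equation$estimate, equation$term)
  } else if (is.numeric(equation) && !is.null(names(equation))) {
    coefs <- equation
  } else {
    stop("'equation' must be an ne_model, a catalogue subset, or a named vector",
         call. = FALSE)
  }
  int_names <- c("(intercept)", "intercept", "(Intercept)")
  intercept <- sum(coefs[names(coefs) %in% int_names])
  slopes <- coefs[!names(coefs) %in% int_names]
  df <- as.data.frame(sample)
  miss <- setdiff(names(slopes), names(df))
  if (length(miss))
    stop("sample is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pred <- rep(intercept, nrow(df))
  for (nm in names(slopes)) pred <- pred + slopes[[nm]] * df[[nm]]
  pred
}

.family_chemical <- c("cp", "ee", "starch", "ndf", "adf", "cf", "ash")

#' Stepwise NE equations for the four candidate predictor families
#'
#' Runs [stepwise_select()] within each of the four candidate families used
#' for NE prediction equations — proximate chemical composition only, and
#' chemical composition plus one energy system (GE, DE or ME) — and ranks
#' the selected equations by greatest R2, then least RMSE, then least AIC.
#'
#' @param panel sample panel with lowercase composition columns (% of DM)
#'   and energy columns `ge`, `de`, `me`, `ne` (MJ/kg DM); see [rsm_panel()].
#' @param alpha_enter,alpha_stay stepwise thresholds, see [stepwise_select()].
#' @param response response column, default `"ne"`.
#' @return A list of class `ne_model_set`: `models` (one `ne_model` per
#'   family), `comparison` (metric table), and `best` (the top-ranked model).
#' @export
ne_equation_search <- function(panel, alpha_enter = 0.15, alpha_stay = 0.15,
                               response = "ne") {
  df <- as.data.frame(panel)
  chem <- intersect(.family_chemical, names(df))
  if (!length(chem)) stop("no chemical composition columns in panel",
                          call. = FALSE)
  fams <- list(chemical = chem)
  for (e in c("ge", "de", "me"))
    if (e %in% names(df)) fams[[e]] <- c(chem, e)
  y <- df[[response]]
  X <- df[, setdiff(unique(unlist(fams)), response), drop = FALSE]
  models <- lapply(fams, function(cand)
    suppressWarnings(
      stepwise_select(y, X, alpha_enter, alpha_stay, candidates = cand)))
  comparison <- data.frame(
    family = names(models),
    terms = vapply(models, function(m) paste(m$predictors, collapse = "+"),
                   character(1)),
    r2 = vapply(models, `[[`, numeric(1), "r2"),
    rmse = vapply(models, `[[`, numeric(1), "rmse"),
    aic = vapply(models, `[[`, numeric(1), "aic"),
    p = vapply(models, `[[`, numeric(1), "overall_p"))
  ord <- order(-comparison$r2, comparison$rmse, comparison$aic)
  structure(list(models = models, comparison = comparison[ord, ],
                 best = models[[ord[1]]]),
            class = "ne_model_set")
}

#' @export
print.ne_model_set <- function(x, ...) {
  cat("Stepwise NE equations by candidate family",
      "(ranked by R2, then RMSE, then AIC):\n\n")
  df <- x$comparison
  df$r2 <- round(df$r2, 3); df$rmse <- round(df$rmse, 3)
  df$aic <- round(df$aic, 2); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  cat("\nBest fit:\n")
  print(x$best)
  invisible(x)
}
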