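test_that("fit_ols reproduces closed-form simple regression", {
  exact <- fit_ols(2 * (1:5), data.frame(x = 1:5))
  expect_equal(unname(coef(exact)), c(0, 2), tolerance = 1e-10)
  expect_equal(exact$r2, 1)
  expect_equal(exact$rmse, 0)
  m <- fit_ols(c(1, 2, 2), data.frame(x = 1:3))
  expect_equal(unname(coef(m)), c(2 / 3, 0.5), tolerance = 1e-10)
  expect_equal(m$r2, 0.75, tolerance = 1e-10)
  expect_equal(m$rmse, 0.40824829, tolerance = 1e-7)
  expect_equal(m$aic, -4.67111527, tolerance = 1e-7)
  expect_error(fit_ols(1:3, data.frame(a = 1:3, b = 1:3)), "n > p")
})

test_that("fit_ols matches a hand-rolled normal-equations oracle", {
  set.seed(99)
  for (i in 1:20) {
    n <- 12
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- 1 + X %*% c(0.5, -2, 1) + rnorm(n)
    m <- fit_ols(as.numeric(y), X)
    M <- cbind(1, X)
    beta <- solve(t(M) %*% M, t(M) %*% y)
    expect_equal(unname(coef(m)), as.numeric(beta), tolerance = 1e-8)
    res <- y - M %*% beta
    expect_equal(m$rmse, sqrt(sum(res^2) / (n - 4)), tolerance = 1e-8)
    expect_equal(m$aic, n * log(sum(res^2) / n) + 2 * 4, tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are refused naming the collinear column", {
  X <- data.frame(a = 1:6, b = 2 * (1:6))
  expect_error(fit_ols(rnorm(6), X), "collinear.*b")
})

test_that("pearson_matrix matches exact cases and cor.test p-values", {
  x <- 1:6
  p1 <- pearson_matrix(data.frame(x = x, y = 2 * x + 1))
  expect_equal(p1$r["x", "y"], 1)
  p2 <- pearson_matrix(data.frame(x = x, y = -x))
  expect_equal(p2$r["x", "y"], -1)
  p3 <- pearson_matrix(data.frame(x = c(1, 2, 3), y = c(1, 3, 2)))
  expect_equal(p3$r["x", "y"], 0.5)
  set.seed(4)
  df <- data.frame(u = rnorm(8), v = rnorm(8))
  pm <- pearson_matrix(df)
  ct <- cor.test(df$u, df$v)
  expect_equal(pm$r["u", "v"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pm$p["u", "v"], ct$p.value, tolerance = 1e-12)
  expect_error(pearson_matrix(data.frame(a = rep(1, 5), b = rnorm(5))),
               "constant")
})

test_that("stepwise selection finds a planted predictor among noise", {
  set.seed(12)
  n <- 50
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 3 * X[, "x2"] + rnorm(n, sd = 0.5)
  m <- stepwise_select(y, X)
  expect_identical(m$predictors, "x2")
  # metrics agree with a direct fit on the selected set
  direct <- fit_ols(y, X[, "x2", drop = FALSE])
  expect_equal(m$aic, direct$aic)
  expect_equal(m$r2, direct$r2)
  # nothing qualifies: intercept-only with a warning
  ynull <- rnorm(20)
  Xn <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("a", "b")))
  set.seed(201)
  expect_warning(m0 <- stepwise_select(rnorm(20), Xn, alpha_enter = 1e-6,
                                       alpha_stay = 1e-6), "intercept-only")
  expect_length(m0$predictors, 0)
})

test_that("adding a predictor never decreases R-squared", {
  set.seed(31)
  for (i in 1:10) {
    n <- 20
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- X[, 1] + rnorm(n)
    r2 <- vapply(1:4, function(k)
      fit_ols(y, X[, 1:k, drop = FALSE])$r2, numeric(1))
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("best_subset minimises AIC over the enumerated models", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 2 * X[, "x1"] - 1.5 * X[, "x3"] + rnorm(n, sd = 0.8)
  bs <- best_subset(y, X)
  expect_setequal(bs$predictors, c("x1", "x3"))
  search <- attr(bs, "search")
  expect_true(all(bs$aic <= search$aic + 1e-12))
  # single predictor: identical to the direct fit
  one <- best_subset(y, X[, "x1", drop = FALSE])
  expect_equal(one$aic, min(fit_ols(y, X[, "x1", drop = FALSE])$aic,
                            fit_ols(y, NULL)$aic))
  expect_error(best_subset(rnorm(30), matrix(rnorm(30 * 20), 30, 20)),
               "1e5|subsets")
})

test_that("catalogue equations evaluate as printed linear combinations", {
  eq <- ne_equations()
  expect_setequal(unique(eq$equation), 1:4)
  expect_equal(apply_equation(ne_equations(1),
                              data.frame(de = 15.78, cp = 37.70)),
               10.0912, tolerance = 1e-10)
  expect_equal(apply_equation(ne_equations(2), data.frame(me = 14.04)),
               10.454, tolerance = 1e-10)
  # all-zero inputs return the intercept
  expect_equal(apply_equation(ne_equations(2), data.frame(me = 0)), -1.48)
  expect_error(apply_equation(ne_equations(1), data.frame(de = 15)), "cp")
  # fitted models predict through the same path
  m <- fit_ols(c(1, 2, 2, 4), data.frame(x = 1:4))
  expect_equal(predict(m, data.frame(x = 1:4)), m$fitted)
})

test_that("slope confidence intervals cover the truth at nominal rate", {
  set.seed(77)
  reps <- 1000
  hits_de <- hits_cp <- logical(reps)
  for (r in seq_len(reps)) {
    de <- runif(8, 11.5, 16)
    cp <- runif(8, 36, 43)
    y <- 1.14 * de + 0.46 * cp - 25.24 + rnorm(8, sd = 0.36)
    m <- fit_ols(y, data.frame(de = de, cp = cp))
    lo <- coef(m) - qt(0.975, m$df_residual) * m$se
    hi <- coef(m) + qt(0.975, m$df_residual) * m$se
    hits_de[r] <- lo["de"] <= 1.14 && 1.14 <= hi["de"]
    hits_cp[r] <- lo["cp"] <= 0.46 && 0.46 <= hi["cp"]
  }
  expect_gt(mean(hits_de), 0.925)
  expect_lt(mean(hits_de), 0.975)
  expect_gt(mean(hits_cp), 0.925)
  expect_lt(mean(hits_cp), 0.975)
})

test_that("equation families are searched and ranked by fit quality", {
  panel <- generate_ingredient_panel(30, seed = 14)
  search <- ne_equation_search(panel)
  expect_named(search$models, c("chemical", "ge", "de", "me"))
  expect_true(all(diff(search$comparison$r2) <= 1e-12))
  best <- search$best
  expect_equal(best$r2, max(search$comparison$r2))
})
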