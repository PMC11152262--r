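test_that("the design matrix applies listwise deletion and dummy coding", {
  tab <- make_fixture("paper_like_300")
  scores <- score_table(tab)
  coded <- collapse_levels(tab, scores)
  des <- build_design(coded, scores)
  expect_equal(nrow(des$X), 292)   # 300 minus 8 missing learn_elderly
  expect_equal(des$n_dropped, 8)
  expect_equal(colnames(des$X),
               c("(Intercept)", "learn_elderly", "class_total",
                 "places_total", "disability", "mobility", "health_good",
                 "family_good", "friends_good", "retired_yes", "female",
                 "married", "secondary_more", "no_children"))
  # the attitude dummy is 1 exactly for "keep learning" respondents
  kept <- match(des$respondent_id, coded$respondent_id)
  expect_equal(unname(des$X[, "learn_elderly"]),
               as.integer(coded$learn_elderly[kept] == "yes"))
  # no missing anywhere -> rows preserved exactly
  tab2 <- make_fixture("tiny8")
  s2 <- score_table(tab2)
  d2 <- build_design(collapse_levels(tab2, s2), s2)
  expect_equal(nrow(d2$X), 8)
  expect_error(
    build_design(coded[setdiff(names(coded), "learn_elderly")], scores),
    "learn_elderly")
})

test_that("an exact linear law is fitted exactly", {
  x <- 1:10
  X <- cbind(`(Intercept)` = 1, x = x)
  # an exact fit triggers the stock "essentially perfect fit" warning
  fit <- suppressWarnings(fit_ols_robust(X, 1 + 2 * x))
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("robust SEs equal the explicit sandwich formula on 6 points", {
  X <- cbind(`(Intercept)` = 1, x = c(0, 1, 2, 3, 4, 10))
  y <- c(1.2, 0.8, 3.1, 2.2, 5.5, 9.0)
  n <- 6; k <- 2
  # independent oracle: explicit summation
  XtX <- matrix(0, k, k); Xty <- numeric(k)
  for (i in 1:n) {
    XtX <- XtX + X[i, ] %o% X[i, ]
    Xty <- Xty + X[i, ] * y[i]
  }
  beta <- solve(XtX, Xty)
  meat <- matrix(0, k, k)
  for (i in 1:n) {
    u <- y[i] - sum(X[i, ] * beta)
    meat <- meat + u^2 * (X[i, ] %o% X[i, ])
  }
  V0 <- solve(XtX) %*% meat %*% solve(XtX)
  fit0 <- fit_ols_robust(X, y, variant = "HC0")
  expect_equal(unname(fit0$coefficients), unname(beta), tolerance = 1e-10)
  expect_equal(unname(fit0$se), unname(sqrt(diag(V0))), tolerance = 1e-10)
  fit1 <- fit_ols_robust(X, y, variant = "HC1")
  expect_equal(unname(fit1$se), unname(sqrt(diag(V0) * n / (n - k))),
               tolerance = 1e-10)
})

test_that("HC1 scales HC0 by sqrt(n/(n-k)) and leaves coefficients alone", {
  set.seed(6)
  n <- 60
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- 0.5 + X[, "a"] - X[, "b"] + rnorm(n) * (1 + X[, "b"])
  fits <- lapply(c("HC0", "HC1", "HC2", "HC3"), function(v)
    fit_ols_robust(X, y, variant = v))
  for (f in fits[-1])
    expect_equal(f$coefficients, fits[[1]]$coefficients)
  expect_equal(fits[[2]]$se,
               fits[[1]]$se * sqrt(n / (n - ncol(X))), tolerance = 1e-12)
})

test_that("rank deficiency is reported with the collinear column", {
  X <- cbind(`(Intercept)` = 1, a = 1:8, twice_a = 2 * (1:8))
  expect_error(fit_ols_robust(X, rnorm(8)), "twice_a|a")
})

test_that("significance stars follow the 1/5/10% thresholds", {
  set.seed(44)
  n <- 200
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  fit <- fit_ols_robust(X, 0.2 * X[, "x"] + rnorm(n))
  expected <- ifelse(fit$p < 0.01, "***",
                     ifelse(fit$p < 0.05, "**",
                            ifelse(fit$p < 0.1, "*", "")))
  expect_equal(fit$stars, expected)
})

test_that("the comparison table lays out three models side by side", {
  tab <- make_fixture("paper_like_300")
  scores <- score_table(tab)
  coded <- collapse_levels(tab, scores)
  regs <- fit_wellbeing_regressions(coded, scores)
  out <- table3_layout(regs)
  expect_equal(ncol(out), 3)
  # 14 coefficient rows (13 predictors + Constant), each with an SE line,
  # plus Observations and R-squared
  expect_equal(nrow(out), 14 * 2 + 2)
  expect_equal(unname(out["Observations", ]), rep("292", 3))
  expect_match(out["learn_elderly", "quality"], "^-?\\d\\.\\d{4}")
  expect_match(out[which(rownames(out) == "learn_elderly") + 1, 1],
               "^\\(\\d\\.\\d{4}\\)$")
  bad <- regs; bad$quality$coefficients <- bad$quality$coefficients[-2]
  expect_error(table3_layout(bad), "predictor set")
})
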