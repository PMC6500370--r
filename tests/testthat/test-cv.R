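test_that("noiseless linear signal gives CV R-squared 1 for all models", {
  set.seed(21)
  X <- cbind(rnorm(50), rnorm(50))
  y <- 3 * X[, 1]
  d <- design_from_xy(X, y)
  for (model in c("single", "multiple", "lasso")) {
    r <- cross_validate(d, model, repeats = 2, seed = 9)
    expect_equal(r$r2_cv, 1, tolerance = 1e-6)
  }
})

test_that("pooled single-probe CV reproduces a hand-run fold-by-fold fit", {
  set.seed(22)
  X <- matrix(rnorm(10), 10, 1)
  y <- 0.8 * X[, 1] + rnorm(10, 0, 0.5)
  d <- design_from_xy(X, y)
  r <- cross_validate(d, "single", folds = 5, repeats = 1, seed = 3)
  # oracle: same fold assignment, explicit per-fold least squares
  foldid <- methpred:::make_folds(10, 5, seed = 3 + 1)
  pred <- rep(NA_real_, 10)
  for (k in 1:5) {
    tr <- foldid != k
    b <- cov(X[tr, 1], y[tr]) / var(X[tr, 1])
    a <- mean(y[tr]) - b * mean(X[tr, 1])
    pred[!tr] <- a + b * X[!tr, 1]
  }
  expect_equal(r$per_repeat[1], cor(pred, y)^2, tolerance = 1e-12)
  expect_equal(r$r2_cv, mean(r$per_repeat))
})

test_that("null single-probe CV R-squared is small and shrinks with n", {
  # under independence the pooled out-of-fold R^2 is O(1/n); the exact
  # constant exceeds the plain-correlation 1/(n-1) because out-of-fold
  # predictions anti-correlate with the held-out response
  null_mean <- function(n, B) {
    set.seed(23)
    mean(replicate(B, {
      d <- design_from_xy(matrix(rnorm(n), n, 1), rnorm(n))
      cross_validate(d, "single", repeats = 2, seed = 1)$r2_cv
    }))
  }
  m100 <- null_mean(100, 120)
  m400 <- null_mean(400, 60)
  expect_gt(m100, 1 / 99)     # at least the null-correlation level
  expect_lt(m100, 8 / 99)     # but still a vanishing quantity
  expect_lt(m400, m100)       # and it decays with sample size
})

test_that("held-out folds never leak into their own predictions", {
  set.seed(24)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- X[, 1] + rnorm(40)
  d <- design_from_xy(X, y)
  foldid <- methpred:::make_folds(40, 5, seed = 2)
  for (model in c("single", "multiple", "lasso")) {
    p1 <- methpred:::cv_one_repeat(d, model, foldid, 5, inner_seed = 7,
                                   inner_folds = 10, single_rule = "refit",
                                   lambda_rule = "1se", pooled = TRUE,
                                   return_pred = TRUE)
    d2 <- d
    d2$y[foldid == 1] <- d2$y[foldid == 1] + 100  # corrupt held-out y only
    p2 <- methpred:::cv_one_repeat(d2, model, foldid, 5, inner_seed = 7,
                                   inner_folds = 10, single_rule = "refit",
                                   lambda_rule = "1se", pooled = TRUE,
                                   return_pred = TRUE)
    expect_equal(p1[foldid == 1], p2[foldid == 1], tolerance = 1e-12)
  }
})

test_that("per-repeat dispersion shrinks with sample size", {
  spread <- vapply(c(100, 500), function(n) {
    set.seed(25)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- X[, 1] + rnorm(n)
    r <- cross_validate(design_from_xy(X, y), "multiple", repeats = 10,
                        seed = 4)
    sd(r$per_repeat)
  }, 0)
  expect_lt(spread[2], spread[1])
})

test_that("both single-CpG CV readings run and the refit one is leakage-free", {
  set.seed(26)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- X[, 4] + rnorm(60)
  d <- design_from_xy(X, y)
  a <- cross_validate(d, "single", repeats = 3, seed = 1,
                      single_rule = "max_per_cpg")
  b <- cross_validate(d, "single", repeats = 3, seed = 1,
                      single_rule = "refit")
  expect_true(is.finite(a$r2_cv) && is.finite(b$r2_cv))
  # max-over-CpGs can only exceed the honest refit estimate on average
  expect_gte(a$r2_cv, b$r2_cv - 0.1)
})

test_that("per-fold averaging variant stays close to pooled on clean signal", {
  set.seed(27)
  X <- matrix(rnorm(80 * 2), 80, 2)
  y <- X[, 1] + rnorm(80, 0, 0.3)
  d <- design_from_xy(X, y)
  pooled <- cross_validate(d, "multiple", repeats = 3, seed = 5)
  perfold <- cross_validate(d, "multiple", repeats = 3, seed = 5,
                            pooled = FALSE)
  expect_equal(pooled$r2_cv, perfold$r2_cv, tolerance = 0.1)
})
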