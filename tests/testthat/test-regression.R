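make_paired_missing <- function(n = 100, miss2 = integer(), miss3 = integer()) {
  set.seed(1)
  meth <- matrix(runif(3 * n), 3, n,
                 dimnames = list(c("cg1", "cg2", "cg3"), paste0("S", 1:n)))
  meth["cg2", miss2] <- NA
  meth["cg3", miss3] <- NA
  expr <- matrix(rnorm(n), 1, n, dimnames = list("G1", paste0("S", 1:n)))
  paired_from_matrices(expr, meth)
}

test_that("design building deletes listwise over the gene's probes", {
  p <- make_paired_missing(miss2 = 1:3)
  expect_equal(build_design("G1", p, "cg2")$n_complete, 97L)
  expect_equal(build_design("G1", p, "cg1")$n_complete, 100L)
  # two probes missing in disjoint sets of 5: union drops 10
  p2 <- make_paired_missing(miss2 = 1:5, miss3 = 6:10)
  expect_equal(build_design("G1", p2, c("cg2", "cg3"))$n_complete, 90L)
})

test_that("ineligible genes raise classed skip conditions", {
  p <- make_paired_missing(miss2 = 1:95)
  expect_error(build_design("G1", p, "cg2"), class = "methpred_skip")
  pc <- make_paired_missing()
  pc$expression["G1", ] <- 5  # constant expression
  expect_error(build_design("G1", pc, "cg1"), class = "methpred_skip")
  pk <- make_paired_missing()
  pk$methylation["cg1", ] <- 0.5  # constant probe is dropped...
  d <- suppressMessages(build_design("G1", pk, c("cg1", "cg2")))
  expect_equal(d$probe_ids, "cg2")
  # ...and a gene with only constant probes is skipped
  expect_error(suppressMessages(build_design("G1", pk, "cg1")),
               class = "methpred_skip")
})

test_that("single-CpG R-squared is the squared Pearson correlation", {
  # hand-computed: r = 6.5 / sqrt(5 * 8.75), r^2 = 42.25 / 43.75
  d <- design_from_xy(cbind(c(1, 2, 3, 4)), c(1, 2, 3, 5))
  f <- fit_single_best(d)
  expect_equal(f$best_r2, 42.25 / 43.75, tolerance = 1e-12)
  # p-value matches the classical slope t-test (oracle: lm)
  lmfit <- lm(y ~ x, data.frame(x = d$X[, 1], y = d$y))
  expect_equal(unname(f$p[1]), summary(lmfit)$coefficients["x", 4],
               tolerance = 1e-10)
})

test_that("a perfectly collinear probe wins with R-squared 1; ties break by id", {
  set.seed(4)
  x <- rnorm(30)
  X <- cbind(cg_b = rnorm(30), cg_a = x, cg_c = x)  # duplicate signal columns
  d <- design_from_xy(X[, order(colnames(X))], 2 * x + 1)
  f <- fit_single_best(d)
  expect_equal(f$best_r2, 1, tolerance = 1e-12)
  expect_equal(f$best_probe, "cg_a")  # first of the tied pair by id order
})

test_that("multiple regression nests the single fit and handles saturation", {
  set.seed(5)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(40)
  d <- design_from_xy(X, y)
  m <- fit_multiple(d)
  s <- fit_single_best(d)
  expect_gte(m$fitting_r2, s$best_r2 - 1e-10)
  expect_false(m$rank_deficient)
  # p = 1 collapses to the single fit exactly
  d1 <- design_from_xy(X[, 2, drop = FALSE], y)
  expect_equal(fit_multiple(d1)$fitting_r2, fit_single_best(d1)$best_r2,
               tolerance = 1e-12)
  # saturated design interpolates: R^2 = 1, flagged, p-value missing
  Xs <- matrix(rnorm(6 * 8), 6, 8)
  ms <- fit_multiple(design_from_xy(Xs, rnorm(6)))
  expect_equal(ms$fitting_r2, 1, tolerance = 1e-8)
  expect_true(ms$rank_deficient)
  expect_true(is.na(ms$overall_p))
})

test_that("orthogonal predictors add their marginal variance shares", {
  # centered orthonormal x1, x2 and noise direction; shares 0.2 / 0.3 / 0.5
  n <- 6
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4] * sqrt(n - 1)
  y <- sqrt(0.2) * q[, 1] + sqrt(0.3) * q[, 2] + sqrt(0.5) * q[, 3]
  d <- design_from_xy(q[, 1:2], y)
  s <- fit_single_best(d)
  expect_equal(unname(s$r2), c(0.2, 0.3), tolerance = 1e-10)
  m <- fit_multiple(d)
  expect_equal(m$fitting_r2, 0.5, tolerance = 1e-10)
  # oracle: explicit normal-equations solve
  X1 <- cbind(1, d$X)
  bhat <- solve(crossprod(X1), crossprod(X1, y))
  expect_equal(squared_cor(as.numeric(X1 %*% bhat), y), m$fitting_r2,
               tolerance = 1e-12)
})

test_that("overall model F-test agrees with lm on random designs", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n) + X[, 1] * runif(1, 0, 1.5)
    m <- fit_multiple(design_from_xy(X, y))
    lf <- summary(lm(y ~ X))
    p_lm <- pf(lf$fstatistic[1], lf$fstatistic[2], lf$fstatistic[3],
               lower.tail = FALSE)
    expect_equal(m$overall_p, unname(p_lm), tolerance = 1e-9)
    expect_equal(m$fitting_r2, lf$r.squared, tolerance = 1e-9)
  }
})

test_that("multiple regression on all probes nests the methylation subset", {
  set.seed(8)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6)
  y <- X[, 1] + 0.5 * X[, 5] + rnorm(n)
  full <- fit_multiple(design_from_xy(X, y))
  subset <- fit_multiple(design_from_xy(X[, 1:4], y))
  expect_gte(full$fitting_r2, subset$fitting_r2 - 1e-10)
})
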