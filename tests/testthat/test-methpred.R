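fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- tiny_dataset(n = 60, G = 8, seed = 17)
      cache <<- list(ds = ds,
                     fit = suppressMessages(methpred(
                       paired = ds$paired, map = ds$map, repeats = 2,
                       seed = 17)))
    }
    cache
  }
})

test_that("per-gene fits respect least-squares nesting and R-squared bounds", {
  res <- fit_small()$fit$results
  wide <- reshape(res[, c("gene", "model", "fitting_r2")],
                  idvar = "gene", timevar = "model", direction = "wide")
  expect_true(all(wide$fitting_r2.multiple >= wide$fitting_r2.single - 1e-10,
                  na.rm = TRUE))
  # penalization only shrinks the in-sample fit
  expect_true(all(wide$fitting_r2.multiple >= wide$fitting_r2.lasso - 1e-10,
                  na.rm = TRUE))
  r2 <- c(res$fitting_r2, res$r2_cv)
  expect_true(all(r2[!is.na(r2)] >= 0 & r2[!is.na(r2)] <= 1))
})

test_that("fitting R-squared of unpenalized models is seed-invariant", {
  ds <- fit_small()$ds
  f1 <- fit_small()$fit
  f2 <- suppressMessages(methpred(paired = ds$paired, map = ds$map,
                                  repeats = 2, seed = 917))
  for (m in c("single", "multiple")) {
    a <- f1$results[f1$results$model == m, ]
    b <- f2$results[f2$results$model == m, ]
    expect_identical(a$fitting_r2, b$fitting_r2)
  }
  # CV estimates move with the seed
  expect_false(identical(f1$results$r2_cv, f2$results$r2_cv))
})

test_that("coef, predict, fitted and residuals are mutually consistent", {
  got <- fit_small()
  fit <- got$fit; ds <- got$ds
  g <- fit$results$gene[fit$results$model == "lasso" &
                          fit$results$valid %in% TRUE][1]
  cf <- coef(fit, g, "lasso")
  expect_equal(names(cf)[1], "(Intercept)")
  pred <- predict(fit, genes = g, model = "lasso")
  probes <- setdiff(names(cf), "(Intercept)")
  manual <- as.numeric(t(ds$paired$methylation[probes, , drop = FALSE]) %*%
                         cf[probes]) + cf["(Intercept)"]
  expect_equal(unname(pred[g, ]), unname(manual), tolerance = 1e-12)
  resid <- residuals(fit, model = "lasso")
  obs <- ds$paired$expression[rownames(resid), ]
  expect_equal(resid[g, ], obs[g, ] - pred[g, ], tolerance = 1e-12)
  # single-model prediction uses the best probe's univariate line
  cfs <- coef(fit, g, "single")
  expect_length(cfs, 2L)
  ps <- predict(fit, genes = g, model = "single")
  expect_equal(unname(ps[g, ]),
               unname(cfs[1] + cfs[2] * ds$paired$methylation[names(cfs)[2], ]),
               tolerance = 1e-12)
})

test_that("summary tallies are monotone and the object prints", {
  fit <- fit_small()$fit
  s <- summary(fit)
  for (tab in list(s$fit_counts, s$cv_counts)) {
    for (key in split(tab, interaction(tab$probe_set_mode, tab$model))) {
      expect_true(all(diff(key$count) <= 0))
    }
  }
  expect_output(print(fit), "expression-from-methylation")
  expect_output(print(s), "valid LASSO")
  pdf(NULL)
  qq <- plot(fit)
  dev.off()
  expect_s3_class(qq, "qq_compare")
})

test_that("pipeline runs from files, is deterministic, and validates config", {
  ds <- tiny_dataset(n = 40, G = 5, seed = 19)
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  cfg <- function(out) run_config(
    expression = file.path(dir, "expression.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    exclusion = file.path(dir, "exclusion.txt"),
    scale = "m", repeats = 2, seed = 19, out_dir = out)
  fit1 <- suppressMessages(run_pipeline(cfg(out1)))
  fit2 <- suppressMessages(run_pipeline(cfg(out2)))
  for (f in c("results.tsv", "cv_results.tsv", "summary_fit.tsv",
              "summary_cv.tsv")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_true(file.exists(file.path(out1, "run.log")))
  expect_true(startsWith(readLines(file.path(out1, "results.tsv"))[1],
                         "# methpred"))
  # summary counts in the written table are monotone per model
  s <- read.delim(file.path(out1, "summary_cv.tsv"), comment.char = "#")
  for (key in split(s, s$model)) expect_true(all(diff(key$count) <= 0))

  expect_error(run_config(preset = "lcl_like", models = character()),
               "at least one model")
  expect_error(run_config(expression = "nope.tsv", methylation = "nope2.tsv",
                          annotation = "nope3.tsv"), "not found")
})

test_that("skipped genes are reported with reasons, not dropped silently", {
  ds <- tiny_dataset(n = 40, G = 5, seed = 23)
  # make one gene constant in expression
  ds$paired$expression["GENE0002", ] <- 1
  fit <- suppressMessages(methpred(paired = ds$paired, map = ds$map,
                                   cv = FALSE, seed = 1))
  expect_true("GENE0002" %in% fit$skipped$gene)
  expect_match(fit$skipped$reason[fit$skipped$gene == "GENE0002"], "constant")
  expect_false("GENE0002" %in% fit$results$gene)
})
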