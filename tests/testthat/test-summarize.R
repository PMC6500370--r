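fake_results <- function(r2, valid = rep(TRUE, length(r2)),
                         model = "lasso", psm = "methylation") {
  data.frame(gene = sprintf("G%03d", seq_along(r2)),
             model = rep_len(model, length(r2)),
             probe_set_mode = rep_len(psm, length(r2)),
             region_mode = rep_len("all", length(r2)),
             fitting_r2 = r2, r2_cv = r2, valid = valid,
             stringsAsFactors = FALSE)
}

test_that("restricting to lasso-valid genes filters every model's rows", {
  lasso <- fake_results(runif(10), valid = c(rep(TRUE, 7), rep(FALSE, 3)))
  single <- fake_results(runif(10), model = "single", valid = NA)
  res <- rbind(lasso, single)
  out <- restrict_to_lasso_valid(res)
  expect_equal(sort(unique(out$gene)), sprintf("G%03d", 1:7))
  expect_equal(sum(out$model == "single"), 7L)
  # all valid: identity on the gene set
  all_ok <- rbind(fake_results(runif(4)), fake_results(runif(4), model = "m2"))
  expect_equal(nrow(restrict_to_lasso_valid(all_ok)), 8L)
  none <- fake_results(runif(3), valid = rep(FALSE, 3))
  expect_warning(out0 <- restrict_to_lasso_valid(none), "no genes")
  expect_equal(nrow(out0), 0L)
})

test_that("threshold counts are strict and monotone", {
  res <- fake_results(c(0.05, 0.15, 0.25, 0.35))
  tab <- count_exceeding(res, "cv")
  expect_equal(tab$count, c(3L, 2L, 1L))
  # a value exactly at the threshold does not count
  expect_equal(count_exceeding(fake_results(0.1), "cv")$count, c(0L, 0L, 0L))
  expect_equal(count_exceeding(fake_results(numeric(0)), "cv")$count,
               integer(0))
  # missing R-squared never counts
  res_na <- fake_results(c(0.5, NA))
  expect_equal(count_exceeding(res_na, "cv")$count, c(1L, 1L, 1L))
  # monotone in the threshold for arbitrary inputs
  set.seed(41)
  r <- count_exceeding(fake_results(runif(200)), "fit")
  expect_true(all(diff(r$count) <= 0))
})

test_that("percentages round to two decimals, half away from zero", {
  expect_identical(percent_of_modeled(827, 8040), 10.29)
  expect_identical(percent_of_modeled(42, 8040), 0.52)
  expect_identical(percent_of_modeled(0, 8040), 0)
  expect_identical(percent_of_modeled(1, 800), 0.13)  # 0.125 rounds up
  expect_error(percent_of_modeled(1, 0), "positive")
  expect_error(percent_of_modeled(5, 4))
})

test_that("significant-CpG gene counting uses the strict minimum p", {
  fits <- list(
    g1 = list(p = c(0.2, 0.03)),   # counted at 0.05
    g2 = list(p = c(0.05, 0.9)),   # exactly 0.05: not counted
    g3 = list(p = c(0.6, 0.7))
  )
  expect_equal(count_genes_with_significant_cpg(fits, 0.05), 1L)
  expect_equal(count_genes_with_significant_cpg(fits, 0.5), 2L)
  expect_equal(count_genes_with_significant_cpg(fits, 0), 0L)
  expect_equal(count_genes_with_significant_cpg(c(g1 = 0.01, g2 = 0.2), 0.05), 1L)
})

test_that("probe-set comparison flags CI departures and tolerates gaps", {
  meth <- fake_results(c(0.3, 0.2, 0.1))
  snp <- fake_results(c(0.25, NA, 0.05), valid = c(TRUE, NA, FALSE),
                      psm = "s_and_c")
  all_ <- fake_results(c(0.31, 0.6, 0.12), psm = "all")
  cmp <- compare_probe_sets(meth, snp, all_, n = 103)
  tab <- cmp$table
  # inside the CI of 0.3 at n=103: not flagged
  expect_false(tab$flag_outside_ci[tab$gene == "G001"])
  # 0.6 far above the CI of 0.2: flagged
  expect_true(tab$flag_outside_ci[tab$gene == "G002"])
  # invalid s_and_c model: value reported missing, row still present
  expect_true(is.na(tab$r2_s_and_c[tab$gene == "G003"]))
  expect_equal(nrow(tab), 3L)
})

test_that("variability correlation handles degenerate and perfect cases", {
  expect_warning(v <- variability_correlation(1:5, rep(0.3, 5)), "constant")
  expect_true(is.na(v$correlation))
  x <- runif(10)
  expect_equal(variability_correlation(x, x)$correlation, 1)
  expect_warning(variability_correlation(1:2, c(0.1, 0.2)), "fewer than 3")
  expect_error(variability_correlation(1:3, 1:4))
  set.seed(42)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(variability_correlation(a, b, "spearman")$correlation,
               cor(a, b, method = "spearman"))
})
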