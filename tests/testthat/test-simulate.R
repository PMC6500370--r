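test_that("generation is bit-identical under a fixed seed", {
  cfg <- generator_config(n_samples = 50, n_genes = 8, seed = 1,
                          probes_per_gene = c(3, 10), target_r2 = c(0, 0.5))
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$paired$methylation, b$paired$methylation)
  expect_identical(a$paired$expression, b$paired$expression)
  expect_identical(a$truth, b$truth)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_dataset(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("missingness hits the requested rate and only the methylation side", {
  ds <- generate_dataset(generator_config(
    n_samples = 200, n_genes = 20, probes_per_gene = c(8, 15),
    missing_rate = 0.01, target_r2 = 0.3, seed = 2))
  frac <- mean(is.na(ds$paired$methylation))
  expect_gt(frac, 0.008)
  expect_lt(frac, 0.012)
  expect_false(anyNA(ds$paired$expression))
})

test_that("scales behave: beta in [0,1], M unbounded, S&C probes trimodal", {
  dsb <- generate_dataset(generator_config(
    n_samples = 150, n_genes = 10, scale = "beta", fraction_s_and_c = 0.3,
    target_r2 = 0.2, seed = 3))
  v <- dsb$paired$methylation
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  dsm <- generate_dataset(generator_config(
    n_samples = 300, n_genes = 10, scale = "m", fraction_s_and_c = 0.3,
    maf_range = c(0.3, 0.5), jitter_sd = 0.1, target_r2 = 0.2, seed = 4))
  snp <- dsm$classification$probe_id[dsm$classification$class == "s_and_c"]
  # genotype-like probes: three clusters 2 latent units apart with small
  # jitter leave two wide gaps in the sorted values
  x <- dsm$paired$methylation[snp[1], ]
  gaps <- diff(sort(x))
  expect_gte(sum(gaps > 1), 2L)
})

test_that("planted variance explained matches its definition", {
  # single causal unit-variance probe with beta 1 and noise variance 1 -> 0.5
  ds <- generate_dataset(generator_config(
    n_samples = 400, n_genes = 5, probes_per_gene = c(4, 8),
    target_r2 = 0.5, n_causal = 1, seed = 5))
  expect_equal(ds$truth$planted_r2, rep(0.5, 5))
  expect_equal(planted_r2(ds$truth, "GENE0003"), 0.5)
  expect_error(planted_r2(ds$truth, "NOPE"), "not in truth")
  # the realized signal share reproduces the target (construction check)
  g <- "GENE0001"
  tr <- ds$truth[ds$truth$gene == g, ]
  cp <- strsplit(tr$causal_probes, ";")[[1]]
  eff <- as.numeric(strsplit(tr$effects, ";")[[1]])
  sig <- as.numeric(t(ds$paired$methylation[cp, , drop = FALSE]) %*% eff)
  y <- as.numeric(ds$paired$expression[g, ])
  expect_equal(var(sig) / var(y), 0.5, tolerance = 0.15)
  # zero effect genes carry planted 0
  ds0 <- generate_dataset(generator_config(n_samples = 50, n_genes = 3,
                                           target_r2 = 0, n_causal = 0,
                                           seed = 6))
  expect_equal(ds0$truth$planted_r2, rep(0, 3))
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(target_r2 = 0.5, n_causal = 0), "infeasible")
  expect_error(generator_config(target_r2 = 0.95), "0.9")
  expect_error(generator_config(probes_per_gene = c(3, 5), n_causal = 4),
               "n_causal")
})

test_that("null genes rarely earn a valid LASSO model at n = 200", {
  ds <- generate_dataset(generator_config(
    n_samples = 200, n_genes = 150, probes_per_gene = c(5, 12),
    scale = "m", target_r2 = 0, n_causal = 0, seed = 7))
  valid <- vapply(names(ds$map), function(g) {
    d <- build_design(g, ds$paired, probes_for_gene(g, ds$map, "all", "all"))
    fit_lasso(d, seed = match(g, names(ds$map)))$valid
  }, TRUE)
  expect_lt(mean(valid), 0.15)
})

test_that("written fixtures read back into an equivalent dataset", {
  ds <- tiny_dataset(n = 30, G = 4, seed = 8)
  dir <- tempfile("fixture")
  write_dataset(ds, dir)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  meth <- read_methylation_matrix(file.path(dir, "methylation.tsv"),
                                  scale = "m")
  expect_equal(unclass(expr)[, ], unclass(ds$paired$expression)[, ],
               tolerance = 1e-12)
  expect_equal(unclass(meth)[, ], unclass(ds$paired$methylation)[, ],
               tolerance = 1e-12)
  ann <- load_probe_annotation(file.path(dir, "annotation.tsv"))
  expect_setequal(ann$probe_id, ds$annotation$probe_id)
  excl <- read_exclusion_list(file.path(dir, "exclusion.txt"))
  expect_setequal(excl,
    ds$classification$probe_id[ds$classification$class == "s_and_c"])
})
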