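# methpred

Predicting a person's gene expression from the DNA methylation of the CpG
probes in each gene's region, across individuals in a population cohort.

Population studies often bank DNA (and hence methylation arrays) without
RNA. Whether a gene's methylation profile carries enough information to
stand in for its expression is an empirical question, and answering it per
gene needs care: CpGs within a gene are correlated, effects flip sign
between promoter and gene body, and probes that overlap SNPs or
cross-hybridize ("S&C probes") can smuggle genetic rather than epigenetic
signal into the prediction. `methpred` implements the full per-gene
comparison for Illumina 450K-style data:

* **single** — each CpG alone; the CpG with maximal R² represents the gene;
* **multiple** — ordinary least squares on all of the gene's CpGs (with a
  minimum-norm fit and a flag when the design is rank deficient);
* **lasso** — L1-penalized regression over the same CpGs, penalty chosen by
  inner 10-fold cross-validation (one-SE rule by default), a gene counting
  as *modelable* only when at least one coefficient survives.

Everywhere, R² is the squared Pearson correlation between predicted and
observed expression. Out-of-sample performance (`r2_cv`) is estimated by
5-fold cross-validation repeated 10 times, pooling out-of-fold predictions
within each repeat; the full penalty selection reruns inside every training
fold. Observed R² is judged against the Fisher-z null of a squared
correlation at sample size n — quantiles
`tanh(qnorm((1+q)/2)/sqrt(n-3))^2`, confidence intervals by transforming
`atanh(sqrt(R2)) ± z*/sqrt(n-3)` — via `null_r2_quantile()`,
`r2_confidence_interval()`, and `qq_compare()`.

The package also ships readers for plain-TSV and GEO series-matrix layouts,
450K-manifest annotation parsing (promoter = TSS1500/TSS200/5'UTR/1stExon,
body = Body), beta↔M conversion, probe classification from an exclusion
list, threshold-count summaries, probe-set comparisons, and a synthetic
cohort generator with exactly known per-gene variance explained, so the
whole pipeline is testable without any data download.

## Worked example

```r
library(methpred)

ds  <- generate_dataset(preset_config("pbmc_like", seed = 1))
fit <- methpred(paired = ds$paired, map = ds$map, seed = 1)
fit
#> per-gene expression-from-methylation fit
#>   200 genes x 100 samples; modes: methylation; models: single/multiple/lasso
#>   5-fold CV x 10 repeats (seed 1)
#>   139 lasso rows valid; 0 gene/mode skips
summary(fit)
#> genes: 200 total, 139 with a valid LASSO model
#> genes with a CpG significant at 0.05: 193; at 0.0001: 126
#>
#> model fitting R^2 (genes exceeding threshold):
#>  probe_set_mode    model >0.1 >0.2 >0.3
#>     methylation    lasso  139  121  102
#>     methylation multiple  139  136  133
#>     methylation   single  136   89   34
#>
#> cross-validation R^2 (genes exceeding threshold):
#>  probe_set_mode    model >0.1 >0.2 >0.3
#>     methylation    lasso  103   82   61
#>     methylation multiple  106   73   44
#>     methylation   single  135   74   23
```

Reading the output: of 200 simulated genes (planted variance explained
spread over [0, 0.6] at n = 100), 139 support a valid lasso model; all
model comparisons are restricted to those. In-sample, unpenalized multiple
regression always looks best — that is over-fitting, visible in how its
counts collapse from the fitting to the cross-validation columns
(133 → 44 genes above R² 0.3). Under cross-validation the lasso leads at
the 0.2 and 0.3 thresholds (the single-CpG column is inflated at the
lowest threshold because its default CV reading takes the maximum over
CpGs — see the methods vignette). `plot(fit)` draws the observed CV
R² against the Fisher-z null line; `coef(fit, "GENE0007")` and
`predict(fit, newdata)` expose per-gene models for downstream use.

Whole runs, from files or presets, go through the orchestrator:

```r
cfg <- run_config(expression = "expr.tsv", methylation = "meth.tsv",
                  annotation = "annot.tsv", exclusion = "snp_probes.txt",
                  scale = "beta", probe_set_modes = c("methylation", "all"),
                  seed = 1, out_dir = "run1")
fit <- run_pipeline(cfg)
```

which writes per-gene results, CV results (with per-repeat values),
threshold summaries, a QQ table, the probe-set comparison, skip reasons,
and a timestamped log, each TSV headed by a comment recording package
version, seed, and config hash.

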