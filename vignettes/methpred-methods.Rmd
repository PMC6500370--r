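---
title: "Predicting gene expression from DNA methylation: models, evaluation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene expression from DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpred)
```

## The problem

Across a human population cohort profiled on both an expression array and a
450K-style methylation array, how well does the DNA methylation of the CpG
probes in a gene's region predict that gene's expression across individuals?
`methpred` answers this per gene with three nested-in-spirit linear models:

* **single** — each CpG regressed on expression separately; the CpG with the
  largest R² represents the gene;
* **multiple** — ordinary least squares on all of the gene's CpGs at once;
* **lasso** — L1-penalized regression on all CpGs, with the penalty chosen
  by 10-fold cross-validation on mean squared error.

Throughout, R² means the **squared Pearson correlation between predicted and
observed expression**, not 1 − SSE/SST. In-sample the two coincide for OLS
with an intercept, but they differ out of sample and for shrunken fits, and
the squared correlation is the quantity that stays comparable across the
three models.

## Data model and probe handling

The unit of analysis is a *paired dataset*: a genes × samples expression
matrix (log-scale, normalized upstream — normalization is out of scope) and
a probes × samples methylation matrix on either the beta scale (proportions
in [0, 1]) or the M scale (log2 of the methylation odds,
`m = log2(beta/(1 - beta))`). The two scales are used as-is per dataset;
`beta_to_m()` is an opt-in utility, never applied automatically, because the
typical published matrices already commit to one scale. The clipping bound
for the logit is 1e−6.

Probes map to genes through a 450K-manifest-style annotation
(`UCSC_RefGene_Name` / `UCSC_RefGene_Group`, semicolon-joined and aligned).
A probe annotated to several genes counts for each of them. Region groups
use the manifest vocabulary; **promoter** is TSS1500 ∪ TSS200 ∪ 5'UTR ∪
1stExon and **body** is `Body`. The annotation never defines "promoter"
for us, so we adopt the platform's standard convention; 3'UTR probes belong
to neither region subset, which is the conservative reading.

Probes on a user-supplied exclusion list — those with potential SNP overlap
or cross-hybridization, the "S&C probes" — form the complement of the
methylation-probe set; "all probes" is their union. The package never
recomputes which probes are SNP-affected; it only consumes a list.

Missing methylation values are kept at load and handled per gene by
listwise deletion over that gene's probes — no imputation, because the
missingness mechanism in the source arrays is unknown and per-gene deletion
keeps every fitted model an honest function of observed data.
Expression rows sharing a gene symbol (multiple probesets per gene) are
collapsed by per-sample mean; the right collapse is genuinely open, and the
mean is the least-committal choice. Both events are reported.

## Eligibility and degenerate designs

A gene needs ≥ 10 complete samples and non-constant expression; the lasso
additionally needs ≥ 2 probes and ≥ 20 complete samples, since penalty
selection by inner 10-fold CV is meaningless below that. Constant probes
are dropped before every fit. A one-probe gene still gets single and
multiple fits (which then coincide exactly — a tested invariant).

Rank-deficient multiple regressions — including the saturated case
p ≥ n − 1 — are fitted by the minimum-norm least-squares solution and
*flagged*, not refused: over-fitting of the unpenalized model on
probe-rich genes is part of the phenomenon being measured, and refusing to
fit would hide it. The overall model F-test is reported missing when
saturated.

## The lasso engine

The penalty path has 100 values, log-spaced from the smallest penalty that
zeroes every coefficient down to 1/1000 of it; predictors (and effectively
the response) are standardized for fitting and coefficients are returned on
the original scale. The path depends only on the data — the seed moves fold
assignment and nothing else, so refitting with a new seed never changes the
candidate penalties (a tested invariant).

The solver is a small coordinate-descent routine (covariance updates,
active-set iteration, warm starts along the path) compiled via Rcpp; its
conventions are those of the standard coordinate-descent software, and the
test suite cross-checks its paths, coefficients, CV curves, and selected
penalties against glmnet on matched fold assignments. The in-package solver
exists because the evaluation design below reruns penalty selection inside
every training fold of every repeat — roughly fifty full inner
cross-validations per gene — and the package-level overhead of calling an
external CV routine tens of thousands of times dominates the actual
arithmetic.

**Penalty rule.** The inner 10-fold CV curve is summarized either by its
minimizer (`lambda_rule = "min"`) or by the sparsest penalty within one
standard error of it (`"1se"`, the conventional default extraction). The
package defaults to `"1se"`. The deciding observation: under the null
(no methylation signal), the minimizer keeps spurious coefficients in
roughly 40% of genes, while the one-SE rule keeps them in ~1–2% — only the
latter is consistent with the empirical fact that in population cohorts
only a sixth to a third of genes support a valid lasso model at all. A
*valid* model is one with ≥ 1 nonzero coefficient at the selected penalty;
model comparisons are restricted to lasso-valid genes so the three models
are compared on the same footing. Exact ties on the CV curve resolve to
the larger penalty (the sparser model).

## Cross-validated prediction R²

Out-of-sample performance is estimated by 5-fold cross-validation repeated
10 times. Per repeat, the folds are a fresh random partition; each fold is
predicted by a model fitted on the other four fifths; the pooled
out-of-fold predictions give **one** squared correlation with observed
expression per repeat, and `r2_cv` is the mean over repeats. Pooling before
correlating (rather than averaging five per-fold R² values) avoids the
instability of correlations on fifth-sized folds; the per-fold-average
variant is exposed via `pooled = FALSE` for sensitivity checks.

Everything estimated is re-estimated inside each training portion: the
lasso reruns its entire inner 10-fold penalty selection, and standardization
statistics come from training data only. A dedicated test corrupts a
held-out fold's responses and verifies its predictions do not move.

For the single-CpG model two estimands are offered and labelled:

* `single_rule = "max_per_cpg"` (default): every CpG is cross-validated
  separately and the per-repeat value is the maximum pooled R² over CpGs —
  the "representative CpG" reading, which matches how a best-CpG summary is
  usually reported, at the cost of a selection optimism;
* `single_rule = "refit"`: the best CpG is re-selected inside each training
  fold — strictly leakage-free, but it estimates the performance of the
  *selection procedure*, a different quantity.

Repeat r of a master seed s uses derived seed s + r for the outer
partition, and a further deterministic offset per fold for the inner fold
assignment, so whole runs are reproducible bit-for-bit from one integer.

## Chance levels: the Fisher-z null

Whether observed R² values beat chance is judged against the null
distribution of a squared correlation at sample size n: with
z = atanh(r) approximately Normal(0, 1/(n − 3)) under the null, the
q-quantile of R² is `tanh(qnorm((1+q)/2)/sqrt(n-3))^2`
(`null_r2_quantile()`), and a level-(1−α) confidence interval for an
observed R² maps `atanh(sqrt(r2)) ± qnorm(1−α/2)/sqrt(n−3)` back through
tanh and squaring, clipping the lower bound to 0 when the z-interval
crosses zero (`r2_confidence_interval()`). `qq_compare()` ranks observed
values against `q = (i − 0.5)/G` null quantiles and reports the maximum
observed-minus-expected departure. The analytic quantiles are used for
reference lines; simulation is kept as the test oracle (a 100,000-draw
Monte-Carlo null agrees to within 0.002 at the tested quantiles).

## What the generator emulates — and what it does not

`generate_dataset()` builds paired cohorts with known truth: per gene,
latent CpG levels are multivariate normal with AR(1) correlation between
adjacent probes (default ρ = 0.5, standing in for the correlation of
neighbouring CpGs); methylation is the logistic of the latent (beta scale)
or the latent itself (M scale). S&C probes are replaced by genotype-like
trimodal values — three clusters at Hardy–Weinberg frequencies for a drawn
MAF, separated by `delta` latent units with jitter — mimicking the
categorical appearance of SNP-affected probes. Expression is a linear
signal on `n_causal` probes plus Gaussian noise scaled so that
`var(Xβ)/var(y)` equals the gene's target R² *exactly in the generated
cohort*; causal promoter probes get negative signs and body probes positive
signs with probability 0.8 each, following the canonical directionality.
Missingness is completely at random (no mechanism is documented for the
real arrays). With `dual_effect_prob`, every gene independently receives a
methylation effect and/or a genotype effect, each with its own variance
share: because the two shares are drawn independently per gene, the
methylation-probe R² and S&C-probe R² are uncorrelated across genes by
construction, which is the property the probe-set comparison is designed
to detect. (Planting the two effect types in disjoint gene sets does
*not* reproduce this: two disjoint clusters of (high, low) and (low, high)
points are strongly anti-correlated, not uncorrelated.)

Realistic features deliberately not modelled: array normalization
artifacts, batch effects, twin relatedness, cell-type mixture, and any
dependence of missingness on signal. Passing tests on generated cohorts
therefore demonstrate that the *pipeline measures what it claims* under a
known truth — not that real tissues will show any particular prediction
power.

Named presets pin the study-shaped configurations: `adipose_like` (beta
scale with sparse missingness, n = 200), `pbmc_like` (M scale, n = 100),
`lcl_like` (M scale, n = 280), each with 200 genes and per-gene variance
explained spread over [0, 0.6]; `null_calibration` (n = 100, 1000 genes,
no signal; 3–15 probes per gene keeps the thousand-gene negative control
affordable) and `recovery` (n = 500, 50 genes, 20 probes, 3 causal,
target 0.5, ρ = 0.3). The probes-per-gene default of 3–60 is a stand-in
for the platform's implicit distribution.

## Numerical choices

* Coordinate-descent convergence: largest squared standardized-coefficient
  update below `1e-8 × var(y)`; path `lambda_min_ratio` 1e−3; 100
  penalties, with the largest nudged up by 1e−9 relative so the path head
  is exactly all-zero despite floating-point summation order.
* Single-CpG ties (identical R²) resolve to the lowest probe id; probes
  within a gene are always in ascending id order, so designs are
  reproducible regardless of annotation row order.
* Predictions with zero variance (an intercept-only lasso) score R² = 0:
  they carry no predictive signal, and leaving them undefined would
  silently drop exactly the genes the validity analysis is about.
* Percentages round half away from zero to two decimals, matching how such
  tables are conventionally printed.
* A CV repeat whose training response is constant is discarded and logged;
  a gene with all repeats discarded reports a missing CV R².

## Worked example

```{r example, eval = FALSE}
ds <- generate_dataset(preset_config("pbmc_like", seed = 1))
fit <- methpred(paired = ds$paired, map = ds$map,
                probe_set_modes = c("methylation", "all"),
                seed = 1)
summary(fit)
plot(fit)                    # QQ against the Fisher-z null
coef(fit, "GENE0001")        # lasso coefficients, original scale
```

The acceptance script (`scripts/acceptance.R`) re-runs the calibration,
recovery, Fisher-z, and independence computations from scratch at the
preset sizes above (1000 null genes at n = 100; 50 recovery genes at
n = 500; 200 independence genes at n = 200; a 100,000-draw Monte-Carlo
null) and writes the resulting quantities as JSON.

## Known limitations

* The minimum-norm convention for rank-deficient OLS is one of several
  defensible choices (software commonly drops aliased columns instead);
  fitted values agree, coefficients do not.
* The `max_per_cpg` single-CpG CV reading carries selection optimism by
  construction; use `refit` when an unbiased estimate of the procedure is
  wanted.
* Whether full-data standardization (a mild leak) was ever the intended
  protocol in comparable analyses is unknowable from the outside; this
  implementation standardizes within folds and documents the choice.
* The generator's AR(1) latent correlation is a convenience; real CpG
  correlation decays with genomic distance and clusters at islands.
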