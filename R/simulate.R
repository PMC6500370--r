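#' Configuration for the paired-data generator
#'
#' Describes a synthetic population cohort with paired methylation and
#' expression, structured like 450K-plus-expression-array studies: dozens of
#' correlated CpGs per gene, beta- or M-value scales, genotype-like
#' trimodal S&C probes, optional missing methylation values, and a known
#' per-gene variance explained.
#'
#' @param n_samples individuals in the cohort.
#' @param n_genes genes (each with its own probe set).
#' @param probes_per_gene integer `c(min, max)`; per-gene probe counts are
#'   drawn uniformly from this range (default 3--60).
#' @param cpg_correlation AR(1) correlation between adjacent CpGs on the
#'   latent scale (default 0.5; neighbouring CpG levels are correlated).
#' @param scale `"beta"` (logistic of the latent, in `[0,1]`) or `"m"`
#'   (latent taken as an M value).
#' @param fraction_s_and_c probability a probe is a genotype-affected /
#'   cross-hybridizing (S&C) probe.
#' @param maf_range minor-allele-frequency range for S&C probes.
#' @param target_r2 per-gene variance explained: a single number (point
#'   mass), a `c(min, max)` range (uniform), or a list
#'   `list(values=, weights=)` (finite mixture). All values in `[0, 0.9]`.
#' @param n_causal causal probes per gene (0 forced when the gene's target
#'   is 0).
#' @param effect_class class the causal probes are drawn from:
#'   `"methylation"` (default) or `"s_and_c"`.
#' @param genotype_effect_fraction fraction of genes whose causal probes are
#'   S&C (genotype-like) instead of `effect_class` — lets methylation-driven
#'   and genotype-driven genes be planted in disjoint sets.
#' @param dual_effect_prob when positive, overrides the single-effect
#'   machinery: each gene independently receives a methylation effect and a
#'   genotype (S&C) effect, each with its own variance share drawn from
#'   `target_r2`. A scalar is one probability for both; a length-2 vector
#'   gives `c(methylation, s_and_c)` probabilities separately — the design
#'   for studying whether epigenetic and genetic predictive signal are
#'   statistically independent across genes.
#' @param promoter_negative_prob probability a causal promoter probe gets a
#'   negative coefficient (default 0.8, the canonical direction).
#' @param body_positive_prob probability a causal Body probe gets a
#'   positive coefficient (default 0.8).
#' @param region_probs sampling weights over the six region groups.
#' @param missing_rate completely-at-random missingness in the methylation
#'   matrix.
#' @param delta latent separation between adjacent genotype clusters of S&C
#'   probes.
#' @param jitter_sd within-cluster latent noise of S&C probes.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_samples = 200, n_genes = 200,
                             probes_per_gene = c(3, 60),
                             cpg_correlation = 0.5,
                             scale = c("beta", "m"),
                             fraction_s_and_c = 0.2,
                             maf_range = c(0.05, 0.5),
                             target_r2 = c(0, 0.9),
                             n_causal = 2,
                             effect_class = c("methylation", "s_and_c"),
                             genotype_effect_fraction = 0,
                             dual_effect_prob = 0,
                             promoter_negative_prob = 0.8,
                             body_positive_prob = 0.8,
                             region_probs = c(TSS1500 = 0.16, TSS200 = 0.14,
                                              `5UTR` = 0.12, `1stExon` = 0.08,
                                              Body = 0.40, `3UTR` = 0.10),
                             missing_rate = 0,
                             delta = 2, jitter_sd = 0.25,
                             seed = 1) {
  scale <- match.arg(scale)
  effect_class <- match.arg(effect_class)
  stopifnot(n_samples >= 10, n_genes >= 1,
            length(probes_per_gene) == 2,
            probes_per_gene[1] >= 1,
            probes_per_gene[2] >= probes_per_gene[1],
            cpg_correlation >= 0, cpg_correlation < 1,
            fraction_s_and_c >= 0, fraction_s_and_c <= 1,
            genotype_effect_fraction >= 0, genotype_effect_fraction <= 1,
            all(dual_effect_prob >= 0), all(dual_effect_prob <= 1),
            length(dual_effect_prob) %in% 1:2,
            missing_rate >= 0, missing_rate < 1,
            all(maf_range > 0), all(maf_range <= 0.5))
  tvals <- if (is.list(target_r2)) target_r2$values else target_r2
  if (any(tvals < 0 | tvals > 0.9))
    stop("target_r2 values must lie in [0, 0.9]")
  if (n_causal < 0 || (n_causal == 0 && any(tvals > 0)))
    stop("infeasible config: positive target_r2 needs n_causal >= 1")
  if (n_causal > probes_per_gene[1])
    stop("n_causal exceeds the minimum probes per gene")
  if (any(dual_effect_prob > 0) && 2 * n_causal > probes_per_gene[1])
    stop("dual effects need probes_per_gene >= 2 * n_causal")
  stopifnot(identical(sort(names(region_probs)), sort(REGION_GROUPS)))
  rm(tvals)
  structure(as.list(environment()), class = "generator_config")
}

draw_target_r2 <- function(target_r2, n) {
  if (is.list(target_r2)) {
    sample(target_r2$values, n, replace = TRUE, prob = target_r2$weights)
  } else if (length(target_r2) == 1) {
    rep(target_r2, n)
  } else {
    runif(n, target_r2[1], target_r2[2])
  }
}

#' Generate a paired dataset with known ground truth
#'
#' Per gene, latent CpG levels are multivariate normal with AR(1)
#' correlation between adjacent probes, shifted by a per-probe baseline;
#' methylation is the logistic of the latent (beta scale) or the latent
#' itself (M scale). S&C probes are replaced by genotype-like values: three
#' clusters at Hardy-Weinberg frequencies for a drawn MAF, separated by
#' `delta` on the latent scale with jitter. Expression is
#' `y = X beta + eps`, with `beta` supported on the causal probes (signs
#' following the promoter-negative / body-positive convention) and the
#' noise scaled so that `var(X beta) / var(y)` equals the gene's target
#' R-squared exactly in the generated cohort. Missing methylation entries
#' are inserted completely at random.
#'
#' @param config a [generator_config()].
#' @return List with `paired` (a `paired_dataset`), `map`
#'   (`gene_probe_map`), `classification`, `annotation` (long data frame),
#'   `truth` (a `truth_set` data frame: gene, causal probes, effects,
#'   `planted_r2`), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n <- cfg$n_samples
  G <- cfg$n_genes
  rho <- cfg$cpg_correlation
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("GENE%04d", seq_len(G))
  p_g <- resample(seq(cfg$probes_per_gene[1], cfg$probes_per_gene[2]),
                  G, replace = TRUE)
  targets <- draw_target_r2(cfg$target_r2, G)
  geno_gene <- runif(G) < cfg$genotype_effect_fraction

  total_p <- sum(p_g)
  meth <- matrix(NA_real_, total_p, n)
  probe_ids <- sprintf("cg%07d", seq_len(total_p))
  rownames(meth) <- probe_ids
  colnames(meth) <- sample_ids
  expr <- matrix(NA_real_, G, n, dimnames = list(gene_ids, sample_ids))

  ann <- vector("list", G)
  truth <- vector("list", G)
  cls <- character(total_p)
  off <- 0L
  for (g in seq_len(G)) {
    p <- p_g[g]
    idx <- off + seq_len(p)
    ids <- probe_ids[idx]
    region <- sample(names(cfg$region_probs), p, replace = TRUE,
                     prob = cfg$region_probs)
    dual <- any(cfg$dual_effect_prob > 0)
    if (dual) {
      dp <- rep_len(cfg$dual_effect_prob, 2)
      has_m <- runif(1) < dp[1]
      has_g <- runif(1) < dp[2]
      nc <- cfg$n_causal
      need <- c(methylation = if (has_m) nc else 0L,
                s_and_c = if (has_g) nc else 0L)
    } else {
      want_class <- if (geno_gene[g]) "s_and_c" else cfg$effect_class
      nc <- if (targets[g] > 0) cfg$n_causal else 0L
      need <- c(methylation = 0L, s_and_c = 0L)
      if (nc > 0) need[want_class] <- nc
    }
    class_g <- ifelse(runif(p) < cfg$fraction_s_and_c, "s_and_c", "methylation")
    # each effect class must have enough probes to host its causal set
    for (cl in names(need)) {
      deficit <- need[[cl]] - sum(class_g == cl)
      if (need[[cl]] > 0 && deficit > 0)
        class_g[resample(which(class_g != cl), deficit)] <- cl
    }
    cls[idx] <- class_g

    # latent AR(1) chain with unit marginal variance, plus probe baselines
    z <- matrix(rnorm(n * p), n, p)
    if (p > 1 && rho > 0)
      for (j in 2:p) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    mu <- rnorm(p, 0, 1.5)
    lat <- sweep(z, 2, mu, `+`)
    # genotype-like probes: 3 clusters at HWE frequencies
    snp <- which(class_g == "s_and_c")
    if (length(snp) > 0) {
      maf <- runif(length(snp), cfg$maf_range[1], cfg$maf_range[2])
      for (s in seq_along(snp)) {
        gt <- rbinom(n, 2, maf[s])
        lat[, snp[s]] <- (gt - 2 * maf[s]) * cfg$delta +
          rnorm(n, 0, cfg$jitter_sd)
      }
    }
    Xg <- if (cfg$scale == "beta") plogis(lat) else lat
    meth[idx, ] <- t(Xg)

    # plant the expression signal
    draw_signs <- function(regions) vapply(regions, function(rg) {
      if (rg %in% PROMOTER_GROUPS)
        if (runif(1) < cfg$promoter_negative_prob) -1 else 1
      else if (rg == "Body")
        if (runif(1) < cfg$body_positive_prob) 1 else -1
      else resample(c(-1, 1), 1)
    }, 0)
    # unit-variance effect per causal probe of one class, rescaled so the
    # component's sample variance equals `share`
    component <- function(cl, share) {
      cs <- sort(resample(which(class_g == cl), nc))
      b <- numeric(p)
      sds <- apply(Xg[, cs, drop = FALSE], 2, sd)
      sds[sds == 0] <- 1
      b[cs] <- draw_signs(region[cs]) / sds
      s <- as.numeric(Xg %*% b)
      s <- s - mean(s)
      if (sd(s) == 0) return(list(b = numeric(p), s = s, cs = cs))
      sc <- sqrt(share) / sd(s)
      list(b = b * sc, s = s * sc, cs = cs)
    }
    beta <- numeric(p)
    causal <- integer(0)
    if (dual) {
      t_m <- if (has_m) draw_target_r2(cfg$target_r2, 1) else 0
      t_g <- if (has_g) draw_target_r2(cfg$target_r2, 1) else 0
      tot <- t_m + t_g
      if (tot > 0.85) {  # keep a noise floor when both effects are strong
        t_m <- t_m * 0.85 / tot; t_g <- t_g * 0.85 / tot; tot <- 0.85
      }
      s_all <- numeric(n)
      for (eff in list(list(cl = "methylation", t = t_m),
                       list(cl = "s_and_c", t = t_g))) {
        if (eff$t > 0) {
          cmp <- component(eff$cl, eff$t)
          beta <- beta + cmp$b
          s_all <- s_all + cmp$s
          causal <- c(causal, cmp$cs)
        }
      }
      ve <- max(1 - tot, 0.05)
      y <- s_all + rnorm(n, 0, sqrt(ve))
      vs <- if (tot > 0) var(s_all) else 0
      planted <- if (tot > 0) vs / (vs + ve) else 0
      planted_m <- t_m; planted_g <- t_g
      eff_class <- if (t_m > 0 && t_g > 0) "both"
                   else if (t_m > 0) "methylation"
                   else if (t_g > 0) "s_and_c" else NA_character_
    } else {
      if (nc > 0) {
        cmp <- component(want_class, 1)  # raw scale; noise set from target
        beta <- cmp$b; causal <- cmp$cs
        signal <- cmp$s
      } else signal <- numeric(n)
      vs <- if (nc > 0) var(signal) else 0
      ve <- if (targets[g] > 0 && vs > 0)
        vs * (1 - targets[g]) / targets[g] else 1
      y <- signal + rnorm(n, 0, sqrt(ve))
      planted <- if (nc > 0) vs / (vs + ve) else 0
      planted_m <- if (nc > 0 && want_class == "methylation") planted else 0
      planted_g <- if (nc > 0 && want_class == "s_and_c") planted else 0
      eff_class <- if (nc > 0) want_class else NA_character_
    }
    expr[g, ] <- y

    ann[[g]] <- data.frame(probe_id = ids, gene = gene_ids[g],
                           group = region, stringsAsFactors = FALSE)
    causal <- sort(unique(causal))
    truth[[g]] <- data.frame(
      gene = gene_ids[g],
      causal_probes = paste(ids[causal], collapse = ";"),
      effects = paste(format(beta[causal], digits = 8, trim = TRUE),
                      collapse = ";"),
      planted_r2 = planted,
      planted_r2_meth = planted_m,
      planted_r2_snp = planted_g,
      effect_class = eff_class,
      stringsAsFactors = FALSE)
    off <- off + p
  }

  if (cfg$missing_rate > 0) {
    drop <- runif(length(meth)) < cfg$missing_rate
    meth[drop] <- NA_real_
  }

  annotation <- do.call(rbind, ann)
  classification <- structure(
    data.frame(probe_id = probe_ids, class = cls, stringsAsFactors = FALSE),
    provenance = "synthetic", class = c("probe_classification", "data.frame"))
  meth <- structure(meth, scale = cfg$scale,
                    class = c("meth_matrix", class(meth)))
  expr <- structure(expr, class = c("expr_matrix", class(expr)))
  paired <- align_samples(expr, meth)
  map <- build_gene_probe_map(annotation, classification, probe_ids)
  truth <- do.call(rbind, truth)
  class(truth) <- c("truth_set", "data.frame")
  list(paired = paired, map = map, classification = classification,
       annotation = annotation, truth = truth, config = cfg)
}

#' Planted variance explained for a gene
#'
#' The population-style variance explained `var(X beta) / (var(X beta) +
#' var(eps))` recorded by the generator, not a sample re-estimate.
#'
#' @param truth the `truth` component of [generate_dataset()].
#' @param gene gene symbol.
#' @return The planted R-squared.
#' @export
planted_r2 <- function(truth, gene) {
  i <- match(gene, truth$gene)
  if (is.na(i)) stop(sprintf("gene '%s' not in truth set", gene))
  truth$planted_r2[i]
}

#' Named generator presets
#'
#' Small study-shaped configurations: `"adipose_like"` (beta values with
#' missing entries, n = 200), `"pbmc_like"` (M values, n = 100),
#' `"lcl_like"` (M values, n = 280), each with 200 genes and per-gene
#' variance explained spread over `[0, 0.6]`; plus three validation
#' designs: `"null_calibration"` (n = 100, 1000 genes, no signal),
#' `"recovery"` (n = 500, 50 genes, 20 probes, 3 causal, planted
#' R-squared 0.5, correlation 0.3), and `"independence"` (n = 200, 200
#' genes; every gene gets a genotype effect through its S&C probes and,
#' by an independent coin, a methylation effect, so the two predictive
#' signals are uncorrelated across genes by construction).
#'
#' @param name preset name.
#' @param seed seed stored in the returned config.
#' @return A `generator_config`.
#' @export
preset_config <- function(name = c("adipose_like", "pbmc_like", "lcl_like",
                                   "null_calibration", "recovery",
                                   "independence"),
                          seed = 1) {
  name <- match.arg(name)
  switch(name,
    adipose_like = generator_config(
      n_samples = 200, n_genes = 200, scale = "beta",
      target_r2 = c(0, 0.6), missing_rate = 2e-4, seed = seed),
    pbmc_like = generator_config(
      n_samples = 100, n_genes = 200, scale = "m",
      target_r2 = c(0, 0.6), seed = seed),
    lcl_like = generator_config(
      n_samples = 280, n_genes = 200, scale = "m",
      target_r2 = c(0, 0.6), seed = seed),
    null_calibration = generator_config(
      n_samples = 100, n_genes = 1000, probes_per_gene = c(3, 15),
      scale = "m", target_r2 = 0, n_causal = 0, seed = seed),
    recovery = generator_config(
      n_samples = 500, n_genes = 50, probes_per_gene = c(20, 20),
      cpg_correlation = 0.3, scale = "m", target_r2 = 0.5, n_causal = 3,
      fraction_s_and_c = 0, seed = seed),
    independence = generator_config(
      n_samples = 200, n_genes = 200, probes_per_gene = c(10, 20),
      # shares drawn on [0.15, 0.4]: the two effects can never sum past the
      # noise floor, so their shares stay exactly independent across genes
      # every gene gets a genotype effect; an independent coin adds a
      # methylation effect, so the S&C side never relies on spurious fits
      scale = "m", target_r2 = c(0.15, 0.4), n_causal = 2,
      fraction_s_and_c = 0.35, dual_effect_prob = c(0.5, 1), seed = seed)
  )
}

#' Write a generated dataset as the TSV formats the readers consume
#'
#' Emits `expression.tsv`, `methylation.tsv`, `annotation.tsv`
#' (manifest-style semicolon-joined columns), `exclusion.txt` (the S&C
#' probes), and `truth.tsv` into `dir`.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- ds$config$seed
  write_matrix_tsv(ds$paired$expression, file.path(dir, "expression.tsv"),
                   id_col = "gene", seed = seed)
  write_matrix_tsv(ds$paired$methylation, file.path(dir, "methylation.tsv"),
                   id_col = "probe_id", seed = seed)
  agg <- do.call(rbind, lapply(split(ds$annotation, ds$annotation$probe_id),
    function(d) data.frame(probe_id = d$probe_id[1],
                           UCSC_RefGene_Name = paste(d$gene, collapse = ";"),
                           UCSC_RefGene_Group = paste(d$group, collapse = ";"))))
  utils::write.table(agg, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  excl <- ds$classification$probe_id[ds$classification$class == "s_and_c"]
  writeLines(c("# synthetic S&C probe list", excl),
             file.path(dir, "exclusion.txt"))
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
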