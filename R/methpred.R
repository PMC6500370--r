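#' Fit per-gene expression-prediction models from DNA methylation
#'
#' The central fitting function. For every gene, the CpG probes mapped to
#' its region are used to predict its expression across individuals under
#' three models — best single CpG, all-CpG multiple regression, and LASSO
#' penalized regression — optionally followed by repeated five-fold
#' cross-validation of each model's out-of-sample R-squared. Probe sets can
#' be restricted by class (methylation vs S&C vs all) and by region
#' (promoter vs gene body).
#'
#' Eligibility per gene and mode: at least one usable probe for the
#' single-CpG model, at least two for multiple and LASSO regression, at
#' least 10 complete samples (20 for LASSO), and non-constant expression.
#' Ineligible genes are recorded in `$skipped` with reasons, never silently
#' dropped.
#'
#' @param expression genes x samples matrix (see
#'   [read_expression_matrix()]), or `NULL` if `paired` is given.
#' @param methylation probes x samples matrix, or `NULL` if `paired` is
#'   given.
#' @param paired a ready `paired_dataset`; overrides
#'   `expression`/`methylation`.
#' @param annotation probe annotation: a `probe_annotation` / long data
#'   frame with columns `probe_id`, `gene`, `group`. Ignored when `map` is
#'   given.
#' @param map a prebuilt `gene_probe_map`.
#' @param exclusion S&C probe ids (character vector or file path); empty
#'   means every probe is a methylation probe.
#' @param probe_set_modes subset of `c("methylation", "s_and_c", "all")`.
#' @param region_modes subset of `c("all", "promoter", "body")`.
#' @param models subset of `c("single", "multiple", "lasso")`.
#' @param cv run repeated cross-validation (default `TRUE`).
#' @param folds,repeats outer CV controls (defaults 5 and 10).
#' @param inner_folds lasso penalty-selection folds (default 10).
#' @param seed master seed; all per-gene fold assignments derive from it.
#' @param alpha overall-model significance level (default 1e-4).
#' @param lambda_rule,single_rule see [fit_lasso()] and [cross_validate()].
#' @param genes optional subset of genes to fit.
#' @param verbose print per-gene progress.
#' @return An object of class `methpred`: list with `results` (one row per
#'   gene x mode x model), `fits` (the fitted model objects), `skipped`,
#'   `paired`, `map`, and the call parameters. Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_samples = 60, n_genes = 5,
#'                                         probes_per_gene = c(3, 6),
#'                                         target_r2 = 0.5, seed = 7))
#' fit <- methpred(paired = ds$paired, map = ds$map, repeats = 2, seed = 7)
#' summary(fit)
methpred <- function(expression = NULL, methylation = NULL, paired = NULL,
                     annotation = NULL, map = NULL, exclusion = character(),
                     probe_set_modes = "methylation", region_modes = "all",
                     models = c("single", "multiple", "lasso"),
                     cv = TRUE, folds = 5, repeats = 10, inner_folds = 10,
                     seed = 1, alpha = 1e-4,
                     lambda_rule = c("1se", "min"),
                     single_rule = c("max_per_cpg", "refit"),
                     genes = NULL, verbose = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  single_rule <- match.arg(single_rule)
  models <- match.arg(models, several.ok = TRUE)
  probe_set_modes <- match.arg(probe_set_modes,
                               c("methylation", "s_and_c", "all"),
                               several.ok = TRUE)
  region_modes <- match.arg(region_modes, c("all", "promoter", "body"),
                            several.ok = TRUE)
  if (is.null(paired)) {
    if (is.null(expression) || is.null(methylation))
      stop("supply either `paired` or both `expression` and `methylation`")
    paired <- align_samples(expression, methylation)
  }
  if (is.null(map)) {
    if (is.null(annotation)) stop("supply either `map` or `annotation`")
    cls <- classify_probes(rownames(paired$methylation), exclusion)
    map <- build_gene_probe_map(annotation, cls, rownames(paired$methylation))
  }
  all_genes <- intersect(names(map), rownames(paired$expression))
  genes <- if (is.null(genes)) all_genes else intersect(genes, all_genes)
  if (length(genes) == 0) stop("no genes shared by the probe map and the expression matrix")

  res_rows <- list()
  fits <- list()
  skipped <- list()
  for (psm in probe_set_modes) for (rm_ in region_modes) {
    mode_key <- paste(psm, rm_, sep = ".")
    fits[[mode_key]] <- list()
    for (gene in genes) {
      gi <- match(gene, names(map))
      probes <- suppressWarnings(probes_for_gene(gene, map, psm, rm_))
      gene_seed <- seed + 1009L * gi
      out <- tryCatch(
        fit_gene_models(gene, paired, probes, models, cv, folds, repeats,
                        inner_folds, gene_seed, alpha, lambda_rule,
                        single_rule),
        methpred_skip = function(e)
          structure(list(reason = e$reason), class = "gene_skip")
      )
      if (inherits(out, "gene_skip")) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(gene = gene, probe_set_mode = psm, region_mode = rm_,
                     reason = out$reason, stringsAsFactors = FALSE)
        next
      }
      out$rows$probe_set_mode <- psm
      out$rows$region_mode <- rm_
      res_rows[[length(res_rows) + 1L]] <- out$rows
      fits[[mode_key]][[gene]] <- out$fits
      if (verbose) message(sprintf("fitted %s [%s/%s]", gene, psm, rm_))
    }
  }
  results <- if (length(res_rows) > 0) do.call(rbind, res_rows) else
    empty_results()
  rownames(results) <- NULL
  structure(
    list(results = results, fits = fits,
         skipped = if (length(skipped) > 0) do.call(rbind, skipped) else
           data.frame(gene = character(), probe_set_mode = character(),
                      region_mode = character(), reason = character()),
         paired = paired, map = map, models = models,
         probe_set_modes = probe_set_modes, region_modes = region_modes,
         cv = cv, folds = folds, repeats = repeats,
         inner_folds = inner_folds, seed = seed, alpha = alpha,
         lambda_rule = lambda_rule, single_rule = single_rule,
         call = match.call()),
    class = "methpred"
  )
}

empty_results <- function() {
  data.frame(gene = character(), model = character(),
             n_complete = integer(), p = integer(),
             fitting_r2 = numeric(), overall_p = numeric(),
             significant = logical(), rank_deficient = logical(),
             n_nonzero = integer(), valid = logical(),
             best_probe = character(), lambda = numeric(),
             r2_cv = numeric(), probe_set_mode = character(),
             region_mode = character(), stringsAsFactors = FALSE)
}

#' Fit the requested models (and their CV) for one gene
#'
#' Worker behind [methpred()], exported for single-gene use. Raises a
#' classed `methpred_skip` condition when the gene is ineligible.
#'
#' @inheritParams methpred
#' @param gene gene symbol.
#' @param probes probe ids to use as predictors.
#' @return List with `rows` (result data frame rows) and `fits` (model
#'   objects, including `cv_*` entries).
#' @export
fit_gene_models <- function(gene, paired, probes, models, cv, folds, repeats,
                            inner_folds, seed, alpha = 1e-4,
                            lambda_rule = "1se", single_rule = "max_per_cpg") {
  design <- build_design(gene, paired, probes)
  fits <- list(design_probes = design$probe_ids)
  rows <- list()
  add_row <- function(model, fitting_r2 = NA, overall_p = NA,
                      significant = NA, rank_deficient = NA, n_nonzero = NA,
                      valid = NA, best_probe = NA, lambda = NA, r2_cv = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, model = model, n_complete = design$n_complete,
      p = design$p, fitting_r2 = fitting_r2, overall_p = overall_p,
      significant = significant, rank_deficient = rank_deficient,
      n_nonzero = n_nonzero, valid = valid,
      best_probe = as.character(best_probe), lambda = lambda, r2_cv = r2_cv,
      stringsAsFactors = FALSE)
  }
  run_cv <- function(model) {
    if (!cv) return(NA_real_)
    r <- tryCatch(
      cross_validate(design, model, folds = folds, repeats = repeats,
                     seed = seed, inner_folds = inner_folds,
                     single_rule = single_rule, lambda_rule = lambda_rule),
      methpred_skip = function(e) NULL)
    if (is.null(r)) return(NA_real_)
    fits[[paste0("cv_", model)]] <<- r
    r$r2_cv
  }
  if ("single" %in% models) {
    f <- fit_single_best(design)
    fits$single <- f
    add_row("single", fitting_r2 = f$best_r2, best_probe = f$best_probe,
            overall_p = unname(f$p[f$best_probe]), r2_cv = run_cv("single"))
  }
  if ("multiple" %in% models && design$p >= 2) {
    f <- fit_multiple(design, alpha = alpha)
    fits$multiple <- f
    add_row("multiple", fitting_r2 = f$fitting_r2, overall_p = f$overall_p,
            significant = f$significant, rank_deficient = f$rank_deficient,
            r2_cv = run_cv("multiple"))
  }
  if ("lasso" %in% models && design$p >= 2 && design$n_complete >= 20) {
    f <- fit_lasso(design, inner_folds = inner_folds, seed = seed,
                   lambda_rule = lambda_rule)
    fits$lasso <- f
    add_row("lasso", fitting_r2 = f$fitting_r2, n_nonzero = f$n_nonzero,
            valid = f$valid, lambda = f$lambda_selected,
            r2_cv = run_cv("lasso"))
  }
  if (length(rows) == 0) skip_gene(gene, "no eligible model")
  list(rows = do.call(rbind, rows), fits = fits)
}

#' @export
print.methpred <- function(x, ...) {
  cat("per-gene expression-from-methylation fit\n")
  cat(sprintf("  %d genes x %d samples; modes: %s; models: %s\n",
              length(unique(x$results$gene)), x$paired$n,
              paste(x$probe_set_modes, collapse = "/"),
              paste(x$models, collapse = "/")))
  if (x$cv)
    cat(sprintf("  %d-fold CV x %d repeats (seed %d)\n",
                x$folds, x$repeats, x$seed))
  nl <- sum(x$results$model == "lasso" & x$results$valid %in% TRUE)
  cat(sprintf("  %d lasso rows valid; %d gene/mode skips\n",
              nl, nrow(x$skipped)))
  invisible(x)
}

#' Threshold-count summary of a methpred fit
#'
#' Restricts to genes with a valid LASSO model (per probe-set mode) and
#' tabulates, for each model, how many genes exceed R-squared thresholds in
#' model fitting and in cross-validation, plus nominal single-CpG
#' significance tallies.
#'
#' @param object a `methpred` fit.
#' @param thresholds R-squared thresholds (default 0.1, 0.2, 0.3).
#' @param ... unused.
#' @return A `summary.methpred` list with `fit_counts`, `cv_counts`,
#'   `n_lasso_valid`, `n_genes`, `n_sig_cpg_05`, `n_sig_cpg_alpha`.
#' @export
summary.methpred <- function(object, thresholds = c(0.1, 0.2, 0.3), ...) {
  res <- object$results
  restricted <- if (any(res$model == "lasso"))
    suppressWarnings(restrict_to_lasso_valid(res)) else res
  fit_counts <- count_exceeding(restricted, "fit", thresholds)
  cv_counts <- if (object$cv) count_exceeding(restricted, "cv", thresholds)
               else NULL
  # best-probe p equals the per-gene minimum CpG p (same n for all probes);
  # tallied in the primary mode only so multi-mode runs do not double-count
  single <- res[res$model == "single" &
                  res$probe_set_mode == object$probe_set_modes[1] &
                  res$region_mode == object$region_modes[1], , drop = FALSE]
  min_p <- stats::setNames(single$overall_p, single$gene)
  structure(
    list(fit_counts = fit_counts, cv_counts = cv_counts,
         n_lasso_valid = length(unique(restricted$gene)),
         n_genes = length(unique(res$gene)),
         n_sig_cpg_05 = count_genes_with_significant_cpg(min_p, 0.05),
         n_sig_cpg_alpha = count_genes_with_significant_cpg(min_p,
                                                            object$alpha),
         alpha = object$alpha, thresholds = thresholds),
    class = "summary.methpred"
  )
}

#' @export
print.summary.methpred <- function(x, ...) {
  cat(sprintf("genes: %d total, %d with a valid LASSO model\n",
              x$n_genes, x$n_lasso_valid))
  cat(sprintf("genes with a CpG significant at 0.05: %d; at %g: %d\n",
              x$n_sig_cpg_05, x$alpha, x$n_sig_cpg_alpha))
  show <- function(tab, label) {
    if (is.null(tab) || nrow(tab) == 0) return()
    cat(sprintf("\n%s R^2 (genes exceeding threshold):\n", label))
    wide <- stats::reshape(
      tab[c("probe_set_mode", "model", "threshold", "count")],
      idvar = c("probe_set_mode", "model"), timevar = "threshold",
      direction = "wide")
    names(wide) <- sub("^count\\.", ">", names(wide))
    print(wide, row.names = FALSE)
  }
  show(x$fit_counts, "model fitting")
  show(x$cv_counts, "cross-validation")
  invisible(x)
}

get_gene_fit <- function(object, gene, model, probe_set_mode, region_mode) {
  psm <- probe_set_mode %||% object$probe_set_modes[1]
  rm_ <- region_mode %||% object$region_modes[1]
  f <- object$fits[[paste(psm, rm_, sep = ".")]][[gene]]
  if (is.null(f)) stop(sprintf("no fit stored for gene '%s' in mode %s/%s",
                               gene, psm, rm_))
  if (is.null(f[[model]]))
    stop(sprintf("model '%s' was not fitted for gene '%s'", model, gene))
  f
}

#' Extract per-gene coefficients
#'
#' @param object a `methpred` fit.
#' @param gene gene symbol.
#' @param model which model's coefficients (default `"lasso"`).
#' @param probe_set_mode,region_mode mode to look in (defaults: first
#'   fitted).
#' @param ... unused.
#' @return Named coefficient vector (intercept first).
#' @export
coef.methpred <- function(object, gene, model = "lasso",
                          probe_set_mode = NULL, region_mode = NULL, ...) {
  f <- get_gene_fit(object, gene, model, probe_set_mode, region_mode)
  m <- f[[model]]
  switch(model,
    lasso = c("(Intercept)" = m$intercept, m$coefficients),
    multiple = m$coefficients,
    single = stats::setNames(c(m$intercept, m$slope),
                             c("(Intercept)", m$best_probe)))
}

#' Predict expression from new methylation data
#'
#' @param object a `methpred` fit.
#' @param newdata probes x samples methylation matrix on the same scale as
#'   the training data; defaults to the training methylation.
#' @param genes genes to predict (default: all fitted).
#' @param model `"lasso"` (default), `"multiple"`, or `"single"`.
#' @param probe_set_mode,region_mode mode to use.
#' @param ... unused.
#' @return Genes x samples matrix of predicted expression; samples with
#'   missing methylation at a needed probe predict `NA`.
#' @export
predict.methpred <- function(object, newdata = NULL, genes = NULL,
                             model = "lasso", probe_set_mode = NULL,
                             region_mode = NULL, ...) {
  newdata <- newdata %||% object$paired$methylation
  psm <- probe_set_mode %||% object$probe_set_modes[1]
  rm_ <- region_mode %||% object$region_modes[1]
  mode_fits <- object$fits[[paste(psm, rm_, sep = ".")]]
  genes <- genes %||% names(mode_fits)
  out <- matrix(NA_real_, length(genes), ncol(newdata),
                dimnames = list(genes, colnames(newdata)))
  for (gene in genes) {
    f <- mode_fits[[gene]]
    if (is.null(f) || is.null(f[[model]])) next
    cf <- coef(object, gene, model, psm, rm_)
    probes <- setdiff(names(cf), "(Intercept)")
    if (!all(probes %in% rownames(newdata)))
      stop(sprintf("newdata lacks probe(s) needed for gene '%s'", gene))
    X <- t(newdata[probes, , drop = FALSE])
    out[gene, ] <- as.numeric(X %*% cf[probes]) + cf["(Intercept)"]
  }
  out
}

#' @export
fitted.methpred <- function(object, ...) {
  predict(object, ...)
}

#' @export
residuals.methpred <- function(object, model = "lasso", ...) {
  pred <- predict(object, model = model, ...)
  obs <- object$paired$expression[rownames(pred), , drop = FALSE]
  obs - pred
}

#' QQ plot of observed prediction R-squared against the Fisher-z null
#'
#' @param x a `methpred` fit (with CV results).
#' @param model model whose R-squared to plot (default `"lasso"`).
#' @param metric `"cv"` (default) or `"fit"`.
#' @param ... passed to [plot()].
#' @return The underlying [qq_compare()] object, invisibly.
#' @export
plot.methpred <- function(x, model = "lasso", metric = c("cv", "fit"), ...) {
  metric <- match.arg(metric)
  col <- if (metric == "cv") "r2_cv" else "fitting_r2"
  vals <- x$results[[col]][x$results$model == model]
  qq <- qq_compare(vals, n = x$paired$n)
  plot(qq$table$expected, qq$table$observed,
       xlab = "expected null R-squared (Fisher z)",
       ylab = sprintf("observed %s R-squared (%s)", model, metric), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(qq)
}
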