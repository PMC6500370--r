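#' Build the per-gene regression design
#'
#' Extracts the gene's expression vector and the methylation values of the
#' listed probes, keeping only samples with complete methylation across all
#' of those probes (listwise deletion; missing values are handled per gene,
#' never imputed). Probes that are constant over the complete samples are
#' dropped with a message, since they carry no information for any of the
#' models.
#'
#' @param gene gene symbol (a row of the expression matrix).
#' @param paired a `paired_dataset` from [align_samples()].
#' @param probes probe ids to use as predictors (rows of the methylation
#'   matrix), e.g. from [probes_for_gene()].
#' @param min_samples minimum number of complete samples (default 10).
#' @return A `gene_design`: list with `gene`, `X` (n_complete x p matrix),
#'   `y`, `probe_ids`, `n_complete`, `p`, `dropped` (constant probes).
#'   Ineligible genes raise a classed `methpred_skip` condition carrying the
#'   reason; see [fit_gene_models()] for a caller that records skips.
#' @export
build_design <- function(gene, paired, probes, min_samples = 10) {
  if (length(probes) == 0) skip_gene(gene, "no probes")
  if (!gene %in% rownames(paired$expression)) skip_gene(gene, "no expression row")
  miss <- setdiff(probes, rownames(paired$methylation))
  if (length(miss) > 0)
    stop(sprintf("probe(s) not in methylation matrix: %s",
                 paste(utils::head(miss, 3), collapse = ", ")))
  X <- t(paired$methylation[probes, , drop = FALSE])
  y <- as.numeric(paired$expression[gene, ])
  complete <- stats::complete.cases(X) & is.finite(y)
  X <- X[complete, , drop = FALSE]
  y <- y[complete]
  if (length(y) < min_samples)
    skip_gene(gene, sprintf("only %d complete samples (< %d)",
                            length(y), min_samples))
  if (sd(y) == 0) skip_gene(gene, "constant expression")
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0) {
    message(sprintf("gene %s: dropped %d constant probe(s)", gene, length(dropped)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) skip_gene(gene, "all probes constant")
  structure(
    list(gene = gene, X = X, y = y, probe_ids = colnames(X),
         n_complete = nrow(X), p = ncol(X), dropped = dropped),
    class = "gene_design"
  )
}

#' Best single-CpG regression
#'
#' Models each CpG separately against expression. The per-probe R-squared is
#' the squared Pearson correlation of the probe with expression (identical
#' to the univariate least-squares fit R-squared); the per-probe p-value is
#' the two-sided t-test of the slope. The CpG with maximum R-squared
#' represents the gene; ties break by probe id order.
#'
#' @param design a `gene_design` from [build_design()].
#' @return A `single_fit`: list with `r2` and `p` (named per-probe vectors),
#'   `best_probe`, `best_r2`, `n`.
#' @export
fit_single_best <- function(design) {
  r <- as.numeric(cor(design$X, design$y))
  r2 <- r^2
  n <- design$n_complete
  tstat <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  names(r2) <- names(p) <- design$probe_ids
  best <- which.max(r2)  # first maximum = lowest probe id (columns sorted)
  uf <- univariate_fits(design$X[, best, drop = FALSE], design$y)
  structure(
    list(r2 = r2, p = p, best_probe = design$probe_ids[best],
         best_r2 = unname(r2[best]), slope = unname(uf$slope),
         intercept = unname(uf$intercept), n = n),
    class = "single_fit"
  )
}

# minimum-norm least squares with intercept; tol as in base qr
min_norm_ols <- function(X, y) {
  X1 <- cbind(`(Intercept)` = 1, X)
  sv <- svd(X1)
  tol <- max(dim(X1)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  rank <- sum(pos)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  coefs <- sv$v %*% (dinv * crossprod(sv$u, y))
  list(coefficients = stats::setNames(as.numeric(coefs), colnames(X1)),
       fitted = as.numeric(X1 %*% coefs), rank = rank)
}

#' All-CpG multiple regression
#'
#' Ordinary least squares of expression on every CpG of the gene, with
#' intercept. When the design is rank deficient (including the saturated
#' case p >= n - 1) the minimum-norm least-squares solution is used and the
#' fit is flagged rather than refused: such genes are exactly where the
#' over-fitting of unpenalized multiple regression shows. The overall
#' p-value is the model F-test (reported missing when saturated), and
#' `significant` flags `overall_p < alpha`.
#'
#' @param design a `gene_design`.
#' @param alpha significance level for the overall model F-test
#'   (default 1e-4).
#' @return A `multiple_fit`: list with `coefficients` (intercept first),
#'   `fitting_r2` (squared correlation of fitted vs observed),
#'   `overall_p`, `rank_deficient`, `significant`, `n`, `p`.
#' @export
fit_multiple <- function(design, alpha = 1e-4) {
  n <- design$n_complete
  if (n <= 2) skip_gene(design$gene, "too few samples for multiple regression")
  fit <- min_norm_ols(design$X, design$y)
  rank_deficient <- fit$rank < ncol(design$X) + 1
  r2 <- squared_cor(fit$fitted, design$y)
  sse <- sum((design$y - fit$fitted)^2)
  sst <- sum((design$y - mean(design$y))^2)
  df1 <- fit$rank - 1
  df2 <- n - fit$rank
  overall_p <- if (df2 <= 0 || df1 <= 0) NA_real_ else {
    r2c <- 1 - sse / sst
    pf((r2c / df1) / ((1 - r2c) / df2), df1, df2, lower.tail = FALSE)
  }
  structure(
    list(coefficients = fit$coefficients, fitting_r2 = r2,
         overall_p = overall_p, rank_deficient = rank_deficient,
         significant = isTRUE(overall_p < alpha), n = n, p = design$p),
    class = "multiple_fit"
  )
}

# penalty selection on an inner-CV curve; ties go to the larger penalty
# (lambda is descending, so the first qualifying index wins)
select_lambda <- function(lambda, cvm, cvsd, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  i_min <- which(cvm <= min(cvm))[1]
  i <- if (rule == "min") i_min
       else which(cvm <= cvm[i_min] + cvsd[i_min])[1]
  list(index = i, lambda = lambda[i])
}

#' LASSO penalized regression with inner-CV penalty selection
#'
#' Fits the lasso path (100 penalties, log-spaced from the smallest penalty
#' that zeroes every coefficient down to 1/1000 of it), with predictors and
#' response standardized for fitting and coefficients reported on the
#' original scale. The penalty is chosen by 10-fold cross-validation on the
#' mean squared error: `lambda_rule = "1se"` (default) takes the sparsest
#' penalty within one standard error of the minimum — the conventional
#' default extraction — while `"min"` takes the minimizer itself. A fit is
#' *valid* when the selected model keeps at least one nonzero coefficient;
#' genes where even minimal penalization selects nothing have no predictive
#' information in their methylation.
#'
#' @param design a `gene_design` with at least 2 probes and 20 complete
#'   samples.
#' @param inner_folds folds for penalty selection (default 10).
#' @param seed integer seed for fold assignment; the candidate penalty path
#'   depends only on the data, never on the seed.
#' @param nlambda,lambda_min_ratio penalty path controls.
#' @param lambda_rule `"1se"` or `"min"`.
#' @return A `lasso_fit`: list with `lambda_selected`, `coefficients`
#'   (named, original scale, no intercept), `intercept`, `n_nonzero`,
#'   `valid`, `fitting_r2`, `cvm`, `cvsd`, `lambda` (the full path), `n`.
#' @export
fit_lasso <- function(design, inner_folds = 10, seed = 1, nlambda = 100,
                      lambda_min_ratio = 1e-3,
                      lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  if (design$p < 2) skip_gene(design$gene, "lasso needs >= 2 probes")
  if (design$n_complete < 20)
    skip_gene(design$gene, "lasso needs >= 20 complete samples")
  if (sd(design$y) == 0) skip_gene(design$gene, "constant expression")
  foldid <- make_folds(design$n_complete, inner_folds, seed = seed)
  cvfit <- .lasso_cv_cpp(design$X, design$y, foldid,
                         nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio)
  sel <- select_lambda(cvfit$lambda, cvfit$cvm, cvfit$cvsd, lambda_rule)
  beta <- stats::setNames(cvfit$beta[, sel$index], design$probe_ids)
  a0 <- cvfit$a0[sel$index]
  n_nonzero <- sum(beta != 0)
  pred <- as.numeric(design$X %*% beta) + a0
  structure(
    list(lambda_selected = sel$lambda, coefficients = beta, intercept = a0,
         n_nonzero = n_nonzero, valid = n_nonzero >= 1,
         fitting_r2 = squared_cor(pred, design$y),
         cvm = cvfit$cvm, cvsd = cvfit$cvsd, lambda = cvfit$lambda,
         n = design$n_complete),
    class = "lasso_fit"
  )
}
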