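# slope/intercept of every univariate regression at once; returns a list of
# length-p vectors
univariate_fits <- function(X, y) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, y - ym))
  slope <- ifelse(sxx > 0, sxy / sxx, 0)
  list(slope = slope, intercept = ym - slope * xm)
}

#' Repeated k-fold cross-validation R-squared for one gene
#'
#' Estimates out-of-sample prediction R-squared by repeated random k-fold
#' cross-validation (default 5 folds, 10 repeats). Within each repeat the
#' samples are split into disjoint folds; each fold is predicted from a
#' model fitted on the remaining folds, the out-of-fold predictions are
#' pooled, and one squared correlation with the observed expression is
#' computed per repeat. The reported `r2_cv` is the mean over repeats.
#'
#' Everything that involves estimation reruns inside each training portion:
#' the lasso redoes its full inner 10-fold penalty selection, and
#' standardization uses training data only, so the held-out fold never
#' leaks into its own predictions.
#'
#' For the single-CpG model two readings are available. The default,
#' `single_rule = "max_per_cpg"`, cross-validates every CpG separately and
#' takes, per repeat, the maximum pooled R-squared over CpGs — the
#' representative-CpG reading. `single_rule = "refit"` re-selects the best
#' CpG inside each training fold (strictly leakage-free, but a different
#' estimand: the CV performance of the selection-plus-fit procedure).
#'
#' @param design a `gene_design` from [build_design()].
#' @param model `"single"`, `"multiple"`, or `"lasso"`.
#' @param folds outer folds (default 5).
#' @param repeats number of random re-partitions (default 10).
#' @param seed master seed; repeat r uses derived seed `seed + r`.
#' @param inner_folds lasso penalty-selection folds (default 10).
#' @param single_rule see above.
#' @param lambda_rule passed to the lasso; see [fit_lasso()].
#' @param pooled if `TRUE` (default) one R-squared per repeat from pooled
#'   out-of-fold predictions; if `FALSE`, the mean of per-fold R-squared
#'   values (sensitivity-check variant).
#' @return A `cv_result`: list with `r2_cv`, `per_repeat` (length
#'   `repeats`), `model`, `folds`, `repeats`, `seed`, `n_discarded`.
#' @export
cross_validate <- function(design, model = c("single", "multiple", "lasso"),
                           folds = 5, repeats = 10, seed = 1,
                           inner_folds = 10,
                           single_rule = c("max_per_cpg", "refit"),
                           lambda_rule = c("1se", "min"),
                           pooled = TRUE) {
  model <- match.arg(model)
  single_rule <- match.arg(single_rule)
  lambda_rule <- match.arg(lambda_rule)
  n <- design$n_complete
  if (n < 2 * folds)
    skip_gene(design$gene, sprintf("n=%d too small for %d-fold CV", n, folds))
  per_repeat <- rep(NA_real_, repeats)
  for (r in seq_len(repeats)) {
    foldid <- make_folds(n, folds, seed = seed + r)
    val <- tryCatch(
      cv_one_repeat(design, model, foldid, folds,
                    inner_seed = seed + 7919L * r,
                    inner_folds = inner_folds, single_rule = single_rule,
                    lambda_rule = lambda_rule, pooled = pooled),
      methpred_skip = function(e) NA_real_
    )
    per_repeat[r] <- val
  }
  n_discarded <- sum(is.na(per_repeat))
  if (n_discarded > 0)
    message(sprintf("gene %s: %d of %d CV repeats discarded",
                    design$gene, n_discarded, repeats))
  structure(
    list(r2_cv = if (all(is.na(per_repeat))) NA_real_
                 else mean(per_repeat, na.rm = TRUE),
         per_repeat = per_repeat, model = model, folds = folds,
         repeats = repeats, seed = seed, n_discarded = n_discarded),
    class = "cv_result"
  )
}

cv_one_repeat <- function(design, model, foldid, folds, inner_seed,
                          inner_folds, single_rule, lambda_rule, pooled,
                          return_pred = FALSE) {
  X <- design$X; y <- design$y; n <- length(y)
  if (model == "single" && single_rule == "max_per_cpg") {
    # pooled out-of-fold predictions per CpG, then max over CpGs
    preds <- matrix(NA_real_, n, ncol(X))
    for (k in seq_len(folds)) {
      test <- foldid == k
      if (sd(y[!test]) == 0) skip_gene(design$gene, "constant training y")
      uf <- univariate_fits(X[!test, , drop = FALSE], y[!test])
      preds[test, ] <- sweep(sweep(X[test, , drop = FALSE], 2, uf$slope, `*`),
                             2, uf$intercept, `+`)
    }
    if (pooled) {
      r2s <- apply(preds, 2, squared_cor, obs = y)
      return(max(r2s, na.rm = TRUE))
    }
    fold_max <- vapply(seq_len(folds), function(k) {
      test <- foldid == k
      max(apply(preds[test, , drop = FALSE], 2, squared_cor, obs = y[test]),
          na.rm = TRUE)
    }, 0)
    return(mean(fold_max))
  }
  pred <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    test <- foldid == k
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]
    if (sd(ytr) == 0) skip_gene(design$gene, "constant training y")
    pred[test] <- switch(
      model,
      single = {  # refit rule: best training CpG, fit on training only
        r2tr <- as.numeric(cor(Xtr, ytr))^2
        r2tr[is.na(r2tr)] <- -Inf
        j <- which.max(r2tr)
        uf <- univariate_fits(Xtr[, j, drop = FALSE], ytr)
        Xte[, j] * uf$slope + uf$intercept
      },
      multiple = {
        fit <- min_norm_ols(Xtr, ytr)
        as.numeric(cbind(1, Xte) %*% fit$coefficients)
      },
      lasso = {
        inner_id <- make_folds(nrow(Xtr), inner_folds,
                               seed = inner_seed + 104729L * k)
        cvfit <- .lasso_cv_cpp(Xtr, ytr, inner_id)
        sel <- select_lambda(cvfit$lambda, cvfit$cvm, cvfit$cvsd, lambda_rule)
        as.numeric(Xte %*% cvfit$beta[, sel$index]) + cvfit$a0[sel$index]
      }
    )
  }
  if (return_pred) return(pred)
  if (pooled) return(squared_cor(pred, y))
  mean(vapply(seq_len(folds), function(k)
    squared_cor(pred[foldid == k], y[foldid == k]), 0))
}

#' Null quantile of R-squared under the Fisher z-transformation
#'
#' Under the null of no correlation, `z = atanh(r)` is approximately normal
#' with mean 0 and variance `1/(n - 3)`. The q-quantile of the squared
#' correlation is therefore `tanh(qnorm((1 + q)/2) / sqrt(n - 3))^2`. Used
#' to draw the expected straight line in QQ comparisons of observed
#' prediction R-squared against chance.
#'
#' @param q probability (vectorized), strictly inside (0, 1).
#' @param n sample size, must exceed 3.
#' @return Expected null R-squared at each `q`.
#' @export
#' @examples
#' null_r2_quantile(0.5, 103)  # about 0.0045
null_r2_quantile <- function(q, n) {
  if (n <= 3) stop("n must exceed 3 for the Fisher z null")
  stopifnot(all(q > 0 & q < 1))
  tanh(qnorm((1 + q) / 2) / sqrt(n - 3))^2
}

#' Fisher-z confidence interval on the R-squared scale
#'
#' Takes `r = +sqrt(r2)`, forms `atanh(r) +/- qnorm(1 - (1-level)/2) /
#' sqrt(n - 3)`, and maps back through `tanh` and squaring. When the
#' z-interval crosses zero, the lower bound on the R-squared scale is 0.
#'
#' @param r2 squared correlation in `[0, 1)`.
#' @param n sample size, must exceed 3.
#' @param level confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' r2_confidence_interval(0.25, 103)  # about (0.115, 0.400)
r2_confidence_interval <- function(r2, n, level = 0.95) {
  if (n <= 3) stop("n must exceed 3 for the Fisher z interval")
  stopifnot(r2 >= 0, r2 < 1)
  z <- atanh(sqrt(r2))
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  lo <- if (z - hw < 0) 0 else tanh(z - hw)^2
  c(lower = lo, upper = tanh(z + hw)^2)
}

#' QQ comparison of observed R-squared against the Fisher-z null
#'
#' Ranks the observed values and pairs rank i of G with the null quantile at
#' `q = (i - 0.5) / G`. The departure summary is the maximum of
#' observed minus expected over ranks — positive when prediction exceeds
#' chance.
#'
#' @param observed_r2 numeric vector of R-squared values (NA dropped).
#' @param n sample size the values were computed at.
#' @return A `qq_compare`: list with `table` (data frame of `q`, `expected`,
#'   `observed`) and `max_departure`.
#' @export
qq_compare <- function(observed_r2, n) {
  obs <- sort(observed_r2[!is.na(observed_r2)])
  if (length(obs) == 0) stop("no observed values")
  G <- length(obs)
  q <- (seq_len(G) - 0.5) / G
  expected <- null_r2_quantile(q, n)
  structure(
    list(table = data.frame(q = q, expected = expected, observed = obs),
         max_departure = max(obs - expected), n = n),
    class = "qq_compare"
  )
}
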