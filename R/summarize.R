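#' Restrict results to genes with a valid LASSO model
#'
#' Model comparisons are made on a common footing: within each probe-set and
#' region mode, only genes whose LASSO fit is valid (at least one nonzero
#' coefficient at the selected penalty) are kept — for all three models.
#'
#' @param results a per-gene results data frame with at least columns
#'   `gene`, `model`, `probe_set_mode`, `region_mode`, `valid`.
#' @return The filtered data frame.
#' @export
restrict_to_lasso_valid <- function(results) {
  keep_parts <- lapply(
    split(results, interaction(results$probe_set_mode, results$region_mode,
                               drop = TRUE)),
    function(d) {
      ok <- d$gene[d$model == "lasso" & !is.na(d$valid) & d$valid]
      d[d$gene %in% ok, , drop = FALSE]
    }
  )
  out <- do.call(rbind, keep_parts)
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no genes with a valid LASSO model")
  out
}

#' Count genes exceeding R-squared thresholds
#'
#' The threshold-count summary: for each probe-set mode and model, the
#' number of genes whose R-squared strictly exceeds each threshold. Missing
#' R-squared values never count.
#'
#' @param results per-gene results, already restricted to lasso-valid genes
#'   (see [restrict_to_lasso_valid()]).
#' @param metric `"fit"` (model-fitting R-squared, column `fitting_r2`) or
#'   `"cv"` (cross-validation R-squared, column `r2_cv`).
#' @param thresholds numeric thresholds (default 0.1, 0.2, 0.3).
#' @return A `summary_table` data frame with columns `probe_set_mode`,
#'   `model`, `metric`, `threshold`, `count`, `n_modeled`, `percent`.
#' @export
count_exceeding <- function(results, metric = c("fit", "cv"),
                            thresholds = c(0.1, 0.2, 0.3)) {
  metric <- match.arg(metric)
  col <- if (metric == "fit") "fitting_r2" else "r2_cv"
  parts <- split(results, interaction(results$probe_set_mode, results$model,
                                      drop = TRUE))
  rows <- lapply(parts, function(d) {
    vals <- d[[col]]
    data.frame(probe_set_mode = d$probe_set_mode[1], model = d$model[1],
               metric = metric, threshold = thresholds,
               count = vapply(thresholds,
                              function(t) sum(vals > t, na.rm = TRUE), 0L),
               n_modeled = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probe_set_mode = character(), model = character(),
                      metric = character(), threshold = numeric(),
                      count = integer(), n_modeled = integer())
  out$percent <- ifelse(out$n_modeled > 0,
                        round_half_up(100 * out$count / pmax(out$n_modeled, 1), 2),
                        NA_real_)
  rownames(out) <- NULL
  structure(out, class = c("summary_table", "data.frame"))
}

#' Percentage of modeled genes, printed-style rounding
#'
#' `100 * count / n_models`, rounded to two decimals half away from zero —
#' the convention that reproduces printed percentages such as
#' 827/8040 = 10.29.
#'
#' @param count numerator (genes exceeding a threshold).
#' @param n_models denominator (genes with a valid model).
#' @return The rounded percentage.
#' @export
#' @examples
#' percent_of_modeled(827, 8040)  # 10.29
percent_of_modeled <- function(count, n_models) {
  if (any(n_models <= 0)) stop("n_models must be positive")
  stopifnot(all(count >= 0), all(count <= n_models))
  round_half_up(100 * count / n_models, 2)
}

#' Count genes with at least one nominally significant CpG
#'
#' Counts genes whose minimum per-CpG p-value (from single-CpG regressions)
#' is strictly below `alpha`. No multiple-testing correction: these are
#' nominal counts.
#'
#' @param single_fits a list of `single_fit` objects, or a named numeric
#'   vector of per-gene minimum p-values.
#' @param alpha significance level.
#' @return Integer count.
#' @export
count_genes_with_significant_cpg <- function(single_fits, alpha = 0.05) {
  min_p <- if (is.numeric(single_fits)) single_fits
           else vapply(single_fits, function(f) min(f$p), 0)
  sum(min_p < alpha, na.rm = TRUE)
}

#' Compare prediction from methylation, S&C, and all probes
#'
#' Lines up per-gene lasso R-squared across the three probe-set modes.
#' S&C values are reported only for genes with a valid S&C-mode model
#' (genes with too few genotype-affected probes have none); the comparison
#' row is still emitted with the field missing. `flag_outside_ci` marks
#' genes whose all-probe R-squared falls outside the Fisher-z confidence
#' interval of their methylation-probe R-squared — evidence that the extra
#' probes add (or remove) real signal. The returned correlation between
#' methylation and S&C R-squared across genes probes whether epigenetic and
#' genetic predictive signal coexist in the same genes.
#'
#' @param results_methylation,results_s_and_c,results_all data frames with
#'   columns `gene`, the metric column, and `valid` (lasso rows only).
#' @param n sample size used for the confidence interval.
#' @param metric column to compare (default `"r2_cv"`).
#' @param level confidence level for the interval.
#' @return A `probe_set_comparison`: list with `table` (per-gene) and
#'   `cross_mode_correlation` (Pearson, across genes with both values).
#' @export
compare_probe_sets <- function(results_methylation, results_s_and_c,
                               results_all, n, metric = "r2_cv",
                               level = 0.95) {
  val <- function(d, g, condition_valid = FALSE) {
    i <- match(g, d$gene)
    out <- d[[metric]][i]
    # only the S&C side is conditioned on model validity: genes without
    # enough genotype-affected probes to support a model report missing
    if (condition_valid && "valid" %in% names(d))
      out[!is.na(i) & !(d$valid[i] %in% TRUE)] <- NA
    out
  }
  genes <- sort(unique(c(results_methylation$gene, results_all$gene)))
  r2_meth <- val(results_methylation, genes)
  r2_snp <- val(results_s_and_c, genes, condition_valid = TRUE)
  r2_all <- val(results_all, genes)
  flag <- rep(NA, length(genes))
  for (i in seq_along(genes)) {
    if (is.na(r2_meth[i]) || is.na(r2_all[i])) next
    ci <- r2_confidence_interval(min(r2_meth[i], 1 - 1e-12), n, level)
    flag[i] <- r2_all[i] < ci["lower"] || r2_all[i] > ci["upper"]
  }
  both <- !is.na(r2_meth) & !is.na(r2_snp)
  cmc <- if (sum(both) >= 3 && sd(r2_meth[both]) > 0 && sd(r2_snp[both]) > 0)
    cor(r2_meth[both], r2_snp[both]) else NA_real_
  structure(
    list(table = data.frame(gene = genes, r2_methylation = r2_meth,
                            r2_s_and_c = r2_snp, r2_all = r2_all,
                            flag_outside_ci = flag,
                            stringsAsFactors = FALSE),
         cross_mode_correlation = cmc, n = n, metric = metric),
    class = "probe_set_comparison"
  )
}

#' Correlation between a variability measure and prediction R-squared
#'
#' Checks whether prediction power merely tracks how variable a gene's
#' expression (or its most predictive CpG) is across individuals: the
#' correlation across genes between a per-gene standard deviation and the
#' lasso cross-validation R-squared.
#'
#' @param per_gene_sd numeric vector (e.g. expression SD per gene, or the
#'   SD of the best single-regression CpG).
#' @param r2_cv numeric vector, same length and gene order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `correlation` (NA, with a warning, when undefined) and
#'   `table` (the scatter pairs).
#' @export
variability_correlation <- function(per_gene_sd, r2_cv,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(per_gene_sd) == length(r2_cv))
  ok <- is.finite(per_gene_sd) & is.finite(r2_cv)
  tab <- data.frame(sd = per_gene_sd[ok], r2_cv = r2_cv[ok])
  if (nrow(tab) < 3) {
    warning("fewer than 3 genes; correlation missing")
    return(list(correlation = NA_real_, table = tab))
  }
  if (sd(tab$sd) == 0 || sd(tab$r2_cv) == 0) {
    warning("constant input; correlation undefined")
    return(list(correlation = NA_real_, table = tab))
  }
  list(correlation = cor(tab$sd, tab$r2_cv, method = method), table = tab)
}
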