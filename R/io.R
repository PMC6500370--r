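#' Read an expression matrix (genes x samples)
#'
#' Reads a tab-separated matrix whose first column holds gene symbols and
#' whose header holds sample identifiers. Values are expected to be log-scale
#' normalized expression. Rows sharing a gene symbol (multiple array
#' probesets per gene) are collapsed by the per-sample mean; rows with no
#' finite value are dropped. Both events are reported via `message()`.
#'
#' @param path path to a TSV file.
#' @param dialect `"plain_tsv"` for a bare matrix, or `"series_matrix"` for
#'   the GEO series-matrix layout, in which lines starting with `"!"` are
#'   metadata, the data table sits between `!series_matrix_table_begin` /
#'   `!series_matrix_table_end`, and identifiers may be double-quoted.
#' @return A numeric matrix of class `expr_matrix` with gene symbols as row
#'   names and sample identifiers as column names.
#' @export
read_expression_matrix <- function(path, dialect = c("plain_tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  m <- read_matrix_tsv(path, dialect)
  if (anyDuplicated(rownames(m))) {
    n_dup <- sum(duplicated(rownames(m)))
    m <- rowsum(m, group = rownames(m), na.rm = TRUE) /
      as.vector(rowsum((!is.na(m)) + 0, group = rownames(m)))
    message(sprintf("collapsed %d duplicate gene rows by per-sample mean", n_dup))
  }
  all_na <- rowSums(is.finite(m)) == 0
  if (any(all_na)) {
    warning(sprintf("dropped %d expression rows with no finite value", sum(all_na)))
    m <- m[!all_na, , drop = FALSE]
  }
  structure(m, class = c("expr_matrix", class(m)))
}

#' Read a methylation matrix (CpG probes x samples)
#'
#' As [read_expression_matrix()], for probe-level methylation. Missing cells
#' (empty or `NA`) are kept as `NA` and their count is reported. When
#' `scale = "beta"` every non-missing value must lie in `[0, 1]`; a value
#' outside that range raises an error naming the probe and sample.
#'
#' @inheritParams read_expression_matrix
#' @param scale `"beta"` (methylation proportions in `[0, 1]`) or `"m"`
#'   (unbounded log2 ratios).
#' @return A numeric matrix of class `meth_matrix` with a `scale` attribute.
#' @export
read_methylation_matrix <- function(path, scale = c("beta", "m"),
                                    dialect = c("plain_tsv", "series_matrix")) {
  scale <- match.arg(scale)
  dialect <- match.arg(dialect)
  m <- read_matrix_tsv(path, dialect)
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicate probe id '%s' in %s",
                 rownames(m)[duplicated(rownames(m))][1], path))
  n_missing <- sum(is.na(m))
  if (n_missing > 0)
    message(sprintf("%d missing methylation values retained as NA", n_missing))
  if (scale == "beta") {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("beta value %g out of [0,1] at probe %s, sample %s",
                   m[bad[1, 1], bad[1, 2]],
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  structure(m, scale = scale, class = c("meth_matrix", class(m)))
}

# shared TSV reader for both dialects
read_matrix_tsv <- function(path, dialect) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (dialect == "series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) == 1 && length(end) == 1 && end > beg) {
      lines <- lines[(beg + 1):(end - 1)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
  }
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop(sprintf("no data rows in %s", path))
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  sample_ids <- header[-1]
  if (length(sample_ids) == 0)
    stop(sprintf("malformed header at line 1 of %s: no sample columns", path))
  if (anyDuplicated(sample_ids))
    stop(sprintf("duplicate sample id '%s' in %s",
                 sample_ids[duplicated(sample_ids)][1], path))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop(sprintf("parse error at line %d of %s: %d fields, expected %d",
                 which(nf != length(header))[1] + 1, path,
                 nf[nf != length(header)][1], length(header)))
  ids <- unquote(vapply(body, `[`, "", 1L))
  vals <- vapply(body, function(r) {
    r <- r[-1]
    r[r %in% c("", "NA", "NaN", "null")] <- NA
    as.numeric(r)
  }, numeric(length(sample_ids)))
  m <- if (is.null(dim(vals))) matrix(vals, nrow = length(ids)) else t(vals)
  dimnames(m) <- list(ids, sample_ids)
  m
}

#' Write a matrix as TSV with a provenance header comment
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @param id_col name for the row-identifier column.
#' @param seed optional seed recorded in the header comment.
#' @param hash optional config hash recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_col = "id", seed = NULL, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_comment(seed, hash), con)
  writeLines(paste(c(id_col, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r) paste(ifelse(is.na(r), "NA", format(r, digits = 17, trim = TRUE, scientific = FALSE)), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

tsv_comment <- function(seed = NULL, hash = NULL) {
  paste0("# methpred ", as.character(packageVersion("methpred")),
         if (!is.null(seed)) paste0(" seed=", seed),
         if (!is.null(hash)) paste0(" config=", hash))
}

#' Convert between methylation beta and M values
#'
#' The standard logit2 link between the two methylation scales:
#' `m = log2(beta / (1 - beta))` and its inverse
#' `beta = 2^m / (1 + 2^m)`. Beta values are clipped to
#' `[eps, 1 - eps]` before the transform; clipping is reported.
#'
#' @param beta,m numeric vector or matrix.
#' @param eps clipping bound keeping the logit finite.
#' @return The transformed vector or matrix.
#' @export
#' @examples
#' beta_to_m(0.8)  # log2(4) = 2
#' m_to_beta(0)    # 0.5
beta_to_m <- function(beta, eps = 1e-6) {
  n_clip <- sum(!is.na(beta) & (beta < eps | beta > 1 - eps))
  if (n_clip > 0)
    message(sprintf("clipped %d beta values to [%g, %g]", n_clip, eps, 1 - eps))
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Pair expression and methylation matrices on shared samples
#'
#' Restricts both matrices to the intersection of their sample identifiers,
#' ordered as in the expression matrix (population cohorts often profile
#' different subsets on the two platforms). At least 10 shared samples are
#' required for cross-validation to be feasible.
#'
#' @param expr matrix from [read_expression_matrix()].
#' @param meth matrix from [read_methylation_matrix()].
#' @return A `paired_dataset`: list with `expression`, `methylation`,
#'   `sample_ids`, and `n`.
#' @export
align_samples <- function(expr, meth) {
  common <- intersect(colnames(expr), colnames(meth))
  if (length(common) == 0) stop("expression and methylation share no samples")
  if (length(common) < 10)
    stop(sprintf("only %d shared samples; at least 10 required", length(common)))
  structure(
    list(expression = expr[, common, drop = FALSE],
         methylation = meth[, common, drop = FALSE],
         sample_ids = common,
         n = length(common)),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("paired dataset: %d genes x %d CpG probes x %d samples (%s scale)\n",
              nrow(x$expression), nrow(x$methylation), x$n,
              attr(x$methylation, "scale") %||% "unknown"))
  nm <- sum(is.na(x$methylation))
  if (nm > 0) cat(sprintf("  %d missing methylation values\n", nm))
  invisible(x)
}
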