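#' @useDynLib methpred, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor fitted pf plogis predict pt qnorm quantile
#'   residuals rbinom rnorm runif sd var
#' @importFrom utils packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so seeded
#' internals (fold assignment, simulation) never disturb the user's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# sample() without the scalar-x pitfall
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# near-balanced random assignment of n items to k folds
make_folds <- function(n, k, seed = NULL) {
  stopifnot(n >= k)
  if (is.null(seed)) sample(rep_len(seq_len(k), n))
  else with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Squared Pearson correlation between predictions and observations
#'
#' The R-squared used throughout: the squared correlation between predicted
#' and observed values (not 1 - SSE/SST; the two differ out of sample and for
#' shrunken fits). Predictions with zero variance (e.g. an intercept-only
#' penalized model) carry no predictive signal and score 0.
#'
#' @param pred,obs numeric vectors of equal length.
#' @return A scalar in `[0, 1]`, or `NA` if `obs` is constant.
#' @export
#' @examples
#' squared_cor(c(1, 2, 3), c(1.1, 1.9, 3.2))
squared_cor <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  keep <- is.finite(pred) & is.finite(obs)
  pred <- pred[keep]; obs <- obs[keep]
  if (length(obs) < 3L || sd(obs) == 0) return(NA_real_)
  if (sd(pred) == 0) return(0)
  min(cor(pred, obs)^2, 1)
}

# round half away from zero (matches how the printed percentages round)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# classed condition for genes that cannot be fitted (too few complete
# samples, constant response, no usable predictors); callers decide whether
# to stop or to record the reason and move on
skip_gene <- function(gene, reason) {
  stop(structure(
    class = c("methpred_skip", "error", "condition"),
    list(message = sprintf("gene %s skipped: %s", gene, reason),
         call = NULL, gene = gene, reason = reason)
  ))
}

is_skip <- function(x) inherits(x, "methpred_skip")

# tiny rolling hash for tagging output files with their config
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
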