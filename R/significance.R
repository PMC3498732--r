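#' Configuration for the growth-rate significance test
#'
#' @param df_full degrees of freedom of the natural cubic spline in the
#'   full model (default 3).
#' @param covariate `"log10_mu"` (log10 of the specific growth rate, the
#'   natural scale when rates span several orders of magnitude) or
#'   `"time"` (retentostat day, for a pure time course).
#' @param n_permutations number of label permutations for the null
#'   (default 1000; at least 100).
#' @param seed RNG seed for the permutation set.
#' @param p_threshold permutation p-value cut-off for calling a gene
#'   significant (default 0.01).
#' @param q_threshold q-value reported alongside for reference (the
#'   mapping from p to q is dataset-specific).
#' @return a `test_config` list.
#' @export
test_config <- function(df_full = 3, covariate = c("log10_mu", "time"),
                        n_permutations = 1000, seed = 1,
                        p_threshold = 0.01, q_threshold = 0.000188) {
  covariate <- match.arg(covariate)
  if (df_full < 1) stop("df_full must be >= 1")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  structure(list(df_full = df_full, covariate = covariate,
                 n_permutations = n_permutations, seed = seed,
                 p_threshold = p_threshold, q_threshold = q_threshold),
            class = "test_config")
}

spline_design <- function(covariate, df) {
  # natural cubic spline with knots at covariate quantiles, plus intercept
  basis <- splines::ns(covariate, df = df)
  X <- cbind(1, basis)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    warning("rank-deficient spline basis; fitting with ", qr_x$rank,
            " effective degrees of freedom")
  qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
}

fstat_from_Q <- function(Y, Q) {
  n <- ncol(Y)
  d1 <- ncol(Q)
  tot <- rowSums(Y * Y)
  rss0 <- tot - n * rowMeans(Y)^2
  YQ <- Y %*% Q
  rss1 <- pmax(tot - rowSums(YQ * YQ), 0)
  num <- (rss0 - rss1) / (d1 - 1)
  den <- rss1 / (n - d1)
  f <- num / den
  f[rss1 <= 1e-12 * rss0 & rss0 > 0] <- Inf   # model fits exactly
  f[rss0 <= .Machine$double.eps * pmax(tot, 1)] <- 0  # constant gene
  f
}

#' Spline F-statistic for association with a covariate
#'
#' For each gene, compares an intercept-only model against a natural
#' cubic spline in the covariate with `df_full` basis functions (plus
#' intercept), both fitted by least squares:
#' F = ((RSS0 - RSS1)/(d1 - d0)) / (RSS1/(n - d1)).
#' A constant gene gives F = 0; a gene fitted exactly by the spline gives
#' an `Inf` sentinel. The statistic is invariant to affine
#' transformations of the gene's profile.
#'
#' @param Y genes x samples matrix (or a single profile vector).
#' @param covariate per-sample covariate values.
#' @param df_full spline degrees of freedom (default 3).
#' @return numeric vector of F statistics, one per gene.
#' @export
fit_spline_fstat <- function(Y, covariate, df_full = 3) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  n <- ncol(Y)
  if (length(covariate) != n)
    stop("covariate length must match the number of samples")
  if (n <= df_full + 2)
    stop("need more samples than spline df + intercept + 1")
  Q <- spline_design(covariate, df_full)
  fstat_from_Q(Y, Q)
}

#' Permutation p-values for the spline F-test
#'
#' Permutes the sample labels (whole columns, so gene-gene correlation is
#' preserved), recomputes F for every gene under each permutation, and
#' estimates p with the add-one estimator
#' p = (1 + #\{F_perm >= F_obs\}) / (B + 1), whose smallest attainable
#' value is 1/(B+1). The same permutation set is used for all genes.
#'
#' @param Y genes x samples matrix.
#' @param covariate per-sample covariate values.
#' @param config a [test_config()].
#' @param perms optional B x n integer matrix of explicit permutations
#'   (rows are sample orderings); overrides `n_permutations`/`seed`.
#'   Useful for exhaustive enumeration at small n.
#' @return data.frame `gene_id`, `F`, `p`.
#' @export
permutation_pvalues <- function(Y, covariate, config = test_config(),
                                perms = NULL) {
  stopifnot(is.matrix(Y))
  n <- ncol(Y)
  f_obs <- fit_spline_fstat(Y, covariate, config$df_full)
  if (is.null(perms)) {
    set.seed(config$seed)
    perms <- t(replicate(config$n_permutations, sample.int(n)))
  }
  B <- nrow(perms)
  exceed <- integer(nrow(Y))
  for (b in seq_len(B)) {
    Qb <- spline_design(covariate[perms[b, ]], config$df_full)
    fb <- fstat_from_Q(Y, Qb)
    exceed <- exceed + (fb >= f_obs)
  }
  p <- (1 + exceed) / (B + 1)
  data.frame(gene_id = rownames(Y), F = f_obs, p = p,
             stringsAsFactors = FALSE)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.90 (step
#' 0.05) via pi0(lambda) = #\{p > lambda\}/(m (1 - lambda)), smooths the
#' estimates with a cubic polynomial and evaluates it at the largest
#' lambda, clamping to (0, 1]. Then q_i = min over p_j >= p_i of
#' pi0 * m * p_j / rank(p_j). If the smoother is unstable (non-finite or
#' non-positive pi0), pi0 falls back to 1, which reduces the estimate to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p p-values in (0, 1].
#' @param pi0 optionally force pi0 (e.g. 1 for plain BH).
#' @return numeric vector of q-values in the order of `p`; the pi0 used
#'   is attached as attribute `"pi0"`.
#' @export
estimate_qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.90, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- try(stats::lm(pi0_l ~ poly(lambda, 3)), silent = TRUE)
    pi0 <- if (inherits(fit, "try-error")) 1 else
      stats::predict(fit, data.frame(lambda = max(lambda)))
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
    pi0 <- min(pi0, 1)
  }
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  q <- pmin(q, 1)
  q[o] <- cummin(q[o])
  attr(q, "pi0") <- pi0
  q
}

#' Run the growth-rate differential-expression test
#'
#' Builds the covariate from the sample metadata (log10 growth rate by
#' default), computes spline F-statistics, permutation p-values and
#' Storey q-values, and flags significant genes at the configured
#' p-value threshold.
#'
#' @param mat preprocessed genes x samples matrix.
#' @param meta sample metadata (`sample_id`, `growth_rate`, `mode`, ...).
#' @param config a [test_config()].
#' @return data.frame `gene_id`, `F`, `p`, `q`, `significant`, ordered as
#'   the input matrix; attribute `"pi0"` carries the pi0 estimate.
#' @export
run_significance <- function(mat, meta, config = test_config()) {
  check_expression_matrix(mat)
  check_sample_metadata(meta, mat)
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  cov <- switch(config$covariate,
                log10_mu = log10(meta$growth_rate),
                time = {
                  if (is.null(meta$time_d))
                    stop("time covariate requested but metadata has no time_d")
                  meta$time_d
                })
  res <- permutation_pvalues(mat, cov, config)
  q <- estimate_qvalues(res$p)
  res$q <- as.numeric(q)
  res$significant <- res$p < config$p_threshold
  attr(res, "pi0") <- attr(q, "pi0")
  res
}

#' Significant genes at the configured threshold
#'
#' @param results a [run_significance()] result.
#' @param config a [test_config()].
#' @return the significant subset, ordered deterministically by
#'   (p, gene_id).
#' @export
call_significant <- function(results, config = test_config()) {
  out <- results[results$p < config$p_threshold, , drop = FALSE]
  out[order(out$p, out$gene_id), , drop = FALSE]
}
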