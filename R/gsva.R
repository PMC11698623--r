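# Per-sample gene-set variation scores: a rank-based Kolmogorov-Smirnov-like
# random walk over genes ordered by their sample-wise deviation from the
# cohort, summarizing the coordinated expression level of a gene set in each
# sample.

#' Per-sample gene-set variation scores
#'
#' For each gene a cross-sample expression-level CDF is estimated
#' (Gaussian kernel with per-gene bandwidth `sd/4`, or the empirical
#' CDF). Within each sample, genes are ordered by decreasing CDF value
#' and the symmetric rank statistic `|rank - (p + 1)/2|` weights a random
#' walk that accumulates `|r|^tau` inside the gene set against a uniform
#' penalty outside it. The default score is the sum of the maximum
#' positive and maximum negative deviation of the walk
#' (`score_type = "signed"`); `"max"` returns the single deviation of
#' largest magnitude.
#'
#' Ties in the sample-wise ordering are broken by gene identifier
#' (byte order), so scores are deterministic and invariant to the row
#' order of the input matrix.
#'
#' @param expr Normalized expression matrix (genes x samples), at least
#'   3 samples.
#' @param gene_set Character vector of gene ids; at least 2 must be
#'   present in `expr`.
#' @param tau Weight exponent on the rank statistic (default 1).
#' @param method `"kernel"` (default) or `"ecdf"`.
#' @param score_type `"signed"` (default) or `"max"`.
#' @return Named numeric vector of per-sample scores in \[-1, 1\].
#' @export
gsva_scores <- function(expr, gene_set, tau = 1,
                        method = c("kernel", "ecdf"),
                        score_type = c("signed", "max")) {
  check_expression_matrix(expr)
  method <- match.arg(method)
  score_type <- match.arg(score_type)
  if (ncol(expr) < 3L) stopf("gene-set scoring needs at least 3 samples")
  in_set <- rownames(expr) %in% gene_set
  if (sum(in_set) < 2L)
    stopf("gene set has fewer than 2 measured genes")

  z <- gene_level_cdf(expr, method)
  p <- nrow(expr)
  mid <- (p + 1) / 2
  n_out <- p - sum(in_set)
  tie_rank <- match(rownames(expr), sort(rownames(expr), method = "radix"))

  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-z[, j], tie_rank)           # ties broken by gene id
    rank_stat <- abs(seq_len(p) - mid)^tau
    inside <- in_set[ord]
    num <- cumsum(ifelse(inside, rank_stat, 0))
    denom_in <- num[p]
    walk <- num / denom_in - cumsum(!inside) / n_out
    max_pos <- max(c(0, walk[walk > 0]))
    max_neg <- min(c(0, walk[walk < 0]))
    if (score_type == "signed") max_pos + max_neg else
      if (max_pos >= -max_neg) max_pos else max_neg
  }, 0)
  names(scores) <- colnames(expr)
  scores
}

# Cross-sample expression-level CDF per gene, evaluated at each sample.
gene_level_cdf <- function(expr, method) {
  n <- ncol(expr)
  if (method == "ecdf") {
    t(apply(expr, 1L, function(x) rank(x, ties.method = "max") / n))
  } else {
    t(apply(expr, 1L, function(x) {
      h <- sd(x) / 4
      if (h == 0) return(rep(0.5, n))
      rowMeans(pnorm(outer(x, x, "-") / h))
    }))
  }
}

#' Score several gene sets at once
#'
#' @param expr Normalized expression matrix (genes x samples).
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param ... Passed to [gsva_scores()].
#' @return Matrix (sets x samples) of scores.
#' @export
gsva_score_matrix <- function(expr, sets, ...) {
  if (!length(sets)) stopf("no gene sets supplied")
  out <- t(vapply(sets, function(s) gsva_scores(expr, s, ...),
                  numeric(ncol(expr))))
  rownames(out) <- names(sets)
  out
}

#' Correlate gene-set scores with tumor stage
#'
#' Pearson correlation between the per-sample score vector and the
#' ordinal stage code, with a two-sided t-based p-value.
#'
#' @param scores Named per-sample score vector from [gsva_scores()].
#' @param traits Trait matrix from [encode_traits()] containing a
#'   `stage` column.
#' @return List with `r`, `p` and the sample count `n`.
#' @export
correlate_scores_stage <- function(scores, traits) {
  shared <- intersect(names(scores), rownames(traits))
  if (length(shared) < 4L)
    stopf("need at least 4 shared samples, got %d", length(shared))
  s <- scores[shared]
  if (var(s) == 0) stopf("scores are constant")
  stage <- traits[shared, "stage"]
  if (var(stage) == 0) stopf("stage is constant")
  r <- cor(s, stage)
  list(r = r, p = cor_pvalue(r, length(shared)), n = length(shared))
}
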