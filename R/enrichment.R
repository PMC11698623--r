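# miRNA target enrichment: hypergeometric upper-tail over-representation of
# each miRNA's targets in each important module, Benjamini-Hochberg FDR
# control across the record family, and the negative miRNA-eigengene
# correlation filter.

#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `z` module genes among `n` targets
#' drawn without replacement from a universe of `N` genes of which `x`
#' belong to the module:
#' `P = sum_{k=z}^{min(x,n)} C(x,k) C(N-x,n-k) / C(N,n)`,
#' evaluated in log space via [stats::phyper()].
#'
#' @param x Module size (genes in the module).
#' @param n Number of targets of the miRNA within the universe.
#' @param z Observed overlap between module and target set.
#' @param N Universe size (all network genes).
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper <- function(x, n, z, N) {
  if (any(c(x, n, z, N) < 0) || x > N || n > N || z > min(x, n))
    stopf("infeasible hypergeometric arguments: x=%s n=%s z=%s N=%s",
          x, n, z, N)
  phyper(z - 1, m = x, n = N - x, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: after sorting ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return FDR-adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric target enrichment of miRNAs in important modules
#'
#' One record per (miRNA, important module): `x` is the module size
#' (unassigned genes never count towards a module, but they do count in
#' the universe `N`), `n` the miRNA's target count within the universe,
#' `z` the overlap, and `p` the upper-tail probability from
#' [hypergeom_upper()].
#'
#' @param targets A `target_map` whose universe equals the partition's
#'   gene set.
#' @param partition Named gene -> module label vector.
#' @param important Character vector of module labels to test.
#' @return Data frame with columns `mirna`, `module`, `x`, `n`, `z`, `N`,
#'   `p`.
#' @export
enrich_mirnas <- function(targets, partition, important) {
  stopifnot(inherits(targets, "target_map"))
  missing_mod <- setdiff(important, unique(partition))
  if (length(missing_mod))
    stopf("important module(s) absent from partition: %s",
          paste(missing_mod, collapse = ", "))
  if (!setequal(names(partition), targets$universe))
    stopf("partition genes and target-map universe differ")
  N <- length(partition)
  records <- expand.grid(mirna = names(targets$map), module = important,
                         stringsAsFactors = FALSE)
  module_genes <- lapply(important,
                         function(mod) names(partition)[partition == mod])
  names(module_genes) <- important
  records$x <- vapply(records$module,
                      function(mod) length(module_genes[[mod]]), 0L)
  records$n <- lengths(targets$map)[records$mirna]
  records$z <- mapply(function(mir, mod) {
    length(intersect(targets$map[[mir]], module_genes[[mod]]))
  }, records$mirna, records$module)
  records$N <- N
  records$p <- mapply(hypergeom_upper, records$x, records$n, records$z,
                      MoreArgs = list(N = N))
  rownames(records) <- NULL
  records
}

#' Correlation between miRNA expression and module eigengenes
#'
#' Pearson correlation of every miRNA profile with every eigengene over
#' the shared samples. A constant miRNA profile yields `NA` (the record
#' is unevaluable and can never be selected).
#'
#' @param mirna_expr Normalized miRNA matrix (miRNAs x samples).
#' @param eigengenes Eigengene matrix (modules x samples).
#' @return Matrix (miRNAs x modules) of correlations.
#' @export
mirna_module_correlation <- function(mirna_expr, eigengenes) {
  shared <- intersect(colnames(mirna_expr), colnames(eigengenes))
  if (length(shared) < 4L)
    stopf("need at least 4 shared samples, got %d", length(shared))
  x <- mirna_expr[, shared, drop = FALSE]
  constant <- apply(x, 1L, function(v) var(v) == 0)
  r <- suppressWarnings(
    cor(t(x), t(eigengenes[, shared, drop = FALSE])))
  r[constant, ] <- NA_real_
  r
}

#' Apply the dual FDR and anticorrelation selection
#'
#' A record is selected when its FDR is strictly below `fdr_thr` and its
#' miRNA-eigengene correlation is strictly below `cor_thr` (negative).
#' Records with missing correlation are never selected.
#'
#' @param records Enrichment data frame carrying `fdr` and `r_me`.
#' @param fdr_thr FDR threshold (default 0.05).
#' @param cor_thr Correlation threshold (default -0.3).
#' @return `records` with a logical `selected` column.
#' @export
select_significant <- function(records, fdr_thr = 0.05, cor_thr = -0.3) {
  if (!all(c("fdr", "r_me") %in% names(records)))
    stopf("records must carry 'fdr' and 'r_me' columns")
  records$selected <- !is.na(records$r_me) &
    records$fdr < fdr_thr & records$r_me < cor_thr
  records
}

#' Full miRNA regulator screen
#'
#' Convenience wrapper chaining [enrich_mirnas()], [bh_adjust()],
#' [mirna_module_correlation()] and [select_significant()]. Only miRNAs
#' present in both the target map and the expression matrix are tested.
#' By default the BH family is the full (miRNA x important module)
#' record set; `fdr_family = "per_module"` adjusts within each module
#' instead.
#'
#' @param mirna_expr Normalized miRNA matrix (miRNAs x samples).
#' @param targets A `target_map` restricted to the network universe.
#' @param partition Named gene -> module label vector.
#' @param eigengenes Eigengene matrix (modules x samples).
#' @param important Module labels to test.
#' @param fdr_thr,cor_thr Selection thresholds (defaults 0.05 and -0.3).
#' @param fdr_family `"joint"` (default) or `"per_module"`.
#' @return Enrichment data frame with columns `mirna`, `module`, `x`,
#'   `n`, `z`, `N`, `p`, `fdr`, `r_me`, `selected`.
#' @export
screen_regulators <- function(mirna_expr, targets, partition, eigengenes,
                              important, fdr_thr = 0.05, cor_thr = -0.3,
                              fdr_family = c("joint", "per_module")) {
  fdr_family <- match.arg(fdr_family)
  tested <- intersect(names(targets$map), rownames(mirna_expr))
  if (!length(tested))
    stopf("no miRNA appears in both expression matrix and target map")
  tm <- targets
  tm$map <- tm$map[tested]
  records <- enrich_mirnas(tm, partition, important)
  records$fdr <- if (fdr_family == "joint") bh_adjust(records$p) else
    stats::ave(records$p, records$module, FUN = bh_adjust)
  rme <- mirna_module_correlation(mirna_expr[tested, , drop = FALSE],
                                  eigengenes)
  records$r_me <- rme[cbind(records$mirna, records$module)]
  select_significant(records, fdr_thr = fdr_thr, cor_thr = cor_thr)
}
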