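# Sample and feature filtering, library-size normalization, target-database
# merging and universe restriction. These steps mirror the standard
# treatment-naive tumor workflow: keep samples with both assays, no recorded
# therapy and known stage; drop low-count features; normalize to
# counts-per-million and log2-transform; intersect the expression genes with
# the merged target-database universe.

#' Select analysis samples
#'
#' Keeps samples that have both expression assays, no recorded
#' pharmaceutical or radiation therapy, and non-missing stage. Order is
#' stable by clinical-table order.
#'
#' @param clinical Clinical data frame (see [read_clinical_tsv()]).
#' @param gene_samples Character vector of sample ids with mRNA data.
#' @param mirna_samples Character vector of sample ids with miRNA data.
#' @param exclude_unknown_treatment Treat `"unknown"` therapy flags as
#'   treated (excluded)? Default `TRUE`, the conservative reading of
#'   "treatment-naive".
#' @return Character vector of retained sample ids.
#' @export
select_samples <- function(clinical, gene_samples, mirna_samples,
                           exclude_unknown_treatment = TRUE) {
  check_clinical(clinical)
  untreated_levels <- if (exclude_unknown_treatment) "no" else
    c("no", "unknown")
  keep <- clinical$sample_id %in% gene_samples &
    clinical$sample_id %in% mirna_samples &
    clinical$pharmaceutical_treatment %in% untreated_levels &
    clinical$radiation_treatment %in% untreated_levels &
    !is.na(clinical$stage) & nzchar(clinical$stage)
  out <- clinical$sample_id[keep]
  if (!length(out)) stopf("no samples survive filters")
  out
}

#' Remove low-count features
#'
#' Drops features whose total count across all samples is below
#' `min_total` (strictly less than; a feature with exactly `min_total`
#' counts is kept). The sample set is unchanged.
#'
#' @param matrix Raw count matrix (features x samples).
#' @param min_total Minimum total count to keep a feature.
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(matrix, min_total) {
  check_counts(matrix)
  matrix[rowSums(matrix) >= min_total, , drop = FALSE]
}

#' Normalize to counts-per-million and log2-transform
#'
#' Per-sample library-size scaling to counts-per-million followed by
#' `log2(cpm + 1)`; zero counts map to zero and doubling every count in a
#' sample leaves its normalized values unchanged.
#'
#' @param matrix Raw count matrix (features x samples).
#' @return Numeric matrix of log2-CPM values, same dimensions.
#' @export
normalize_log2 <- function(matrix) {
  check_counts(matrix)
  lib <- colSums(matrix)
  zero <- which(lib == 0)
  if (length(zero))
    stopf("sample(s) with zero total counts: %s",
          paste(colnames(matrix)[zero], collapse = ", "))
  log2(sweep(matrix, 2L, lib, "/") * 1e6 + 1)
}

#' Merge miRNA-target maps from several databases
#'
#' Pair-level union with deduplication; the merged universe is the union
#' of the input universes.
#'
#' @param maps List of `target_map` objects (at least one).
#' @return A single merged `target_map`.
#' @export
merge_target_maps <- function(maps) {
  if (!length(maps)) stopf("need at least one target map")
  stopifnot(all(vapply(maps, inherits, TRUE, "target_map")))
  pairs <- do.call(rbind, lapply(maps, function(tm) data.frame(
    mirna = rep(names(tm$map), lengths(tm$map)),
    gene = unlist(tm$map, use.names = FALSE),
    stringsAsFactors = FALSE)))
  universe <- sort(unique(unlist(lapply(maps, `[[`, "universe"))))
  target_map(pairs, universe = universe)
}

#' Total number of (miRNA, gene) pairs in a target map
#'
#' @param targets A `target_map`.
#' @return Integer pair count.
#' @export
n_target_pairs <- function(targets) {
  stopifnot(inherits(targets, "target_map"))
  sum(lengths(targets$map))
}

#' Restrict expression and target map to their common gene universe
#'
#' Keeps expression rows present in the target-map universe and target
#' genes present in the expression matrix. The resulting gene count is the
#' universe size N used by every enrichment test. The operation is
#' idempotent.
#'
#' @param expr Expression matrix (genes x samples).
#' @param targets A `target_map`.
#' @return List with elements `expr` and `targets`, both restricted.
#' @export
restrict_universe <- function(expr, targets) {
  check_expression_matrix(expr)
  stopifnot(inherits(targets, "target_map"))
  common <- intersect(rownames(expr), targets$universe)
  if (!length(common))
    stopf("expression genes and target-map universe do not intersect")
  expr2 <- expr[rownames(expr) %in% common, , drop = FALSE]
  map2 <- lapply(targets$map, function(g) g[g %in% common])
  map2 <- map2[lengths(map2) > 0]
  pairs <- data.frame(mirna = rep(names(map2), lengths(map2)),
                      gene = unlist(map2, use.names = FALSE),
                      stringsAsFactors = FALSE)
  list(expr = expr2, targets = target_map(pairs, universe = sort(common)))
}

#' Sample quality control by hierarchical clustering
#'
#' Average-linkage hierarchical clustering of samples on Euclidean
#' distance over normalized expression. With a height threshold, samples
#' outside the largest cluster at that cut are flagged as outliers; with
#' the threshold unset no sample is flagged.
#'
#' @param expr Expression matrix (genes x samples), at least 3 samples.
#' @param height_threshold Optional dendrogram cut height.
#' @return List with `hclust` (the sample dendrogram) and `flagged`
#'   (character vector of outlier sample ids).
#' @export
sample_qc_dendrogram <- function(expr, height_threshold = NULL) {
  check_expression_matrix(expr)
  if (ncol(expr) < 3L) stopf("sample QC needs at least 3 samples")
  hc <- hclust(dist(t(expr)), method = "average")
  flagged <- character(0)
  if (!is.null(height_threshold)) {
    cl <- cutree(hc, h = height_threshold)
    main <- names(which.max(table(cl)))
    flagged <- colnames(expr)[cl != as.integer(main)]
  }
  list(hclust = hc, flagged = flagged)
}
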