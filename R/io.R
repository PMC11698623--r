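# Readers and writers for the pipeline's plain-text interchange formats:
# features-by-samples TSV matrices, clinical tables, miRNA-target pair
# tables, GMT gene sets, and confidence-weighted edge lists.

#' Read a features-by-samples expression matrix from TSV
#'
#' The file must have a header row of sample identifiers and feature
#' identifiers in the first column.
#'
#' @param path Path to a tab-delimited file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  check_expression_matrix(m, sprintf("matrix in '%s'", path))
  m
}

#' Write a features-by-samples expression matrix to TSV
#'
#' @param matrix Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  check_expression_matrix(matrix)
  df <- data.frame(feature = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Expects columns `sample_id`, `stage`, `t`, `n`, `m`,
#' `pharmaceutical_treatment`, `radiation_treatment`, `age`. Treatment
#' flags are tri-state (`"yes"`, `"no"`, `"unknown"`); empty stage fields
#' are read as missing.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A data frame, one row per sample.
#' @export
read_clinical_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  check_clinical(df)
}

check_clinical <- function(df) {
  needed <- c("sample_id", "stage", "t", "n", "m",
              "pharmaceutical_treatment", "radiation_treatment", "age")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stopf("clinical table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("clinical table has duplicated sample_id values")
  df
}

#' Write a clinical table to TSV
#'
#' @param clinical Data frame as returned by [read_clinical_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_tsv <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Construct a miRNA-to-target map
#'
#' A target map stores, for each miRNA, the set of annotated target genes,
#' together with the gene universe against which enrichment is tested.
#' Duplicate (miRNA, gene) pairs are collapsed; every target must lie in
#' the universe.
#'
#' @param pairs Data frame with columns `mirna` and `gene`, one
#'   interaction per row.
#' @param universe Character vector of gene identifiers; defaults to the
#'   union of all target genes in `pairs`.
#' @return An object of class `target_map`: a list with elements `map`
#'   (named list of character vectors) and `universe`.
#' @export
target_map <- function(pairs, universe = NULL) {
  if (!all(c("mirna", "gene") %in% names(pairs)))
    stopf("pairs must have columns 'mirna' and 'gene'")
  pairs <- unique(pairs[, c("mirna", "gene")])
  if (is.null(universe)) universe <- sort(unique(pairs$gene))
  bad <- setdiff(pairs$gene, universe)
  if (length(bad))
    stopf("%d target gene(s) not in universe (e.g. %s)",
          length(bad), bad[1L])
  map <- split(pairs$gene, pairs$mirna)
  map <- lapply(map, function(g) sort(unique(g)))
  structure(list(map = map, universe = sort(unique(universe))),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d miRNAs, %d interactions, universe of %d genes\n",
              length(x$map), sum(lengths(x$map)), length(x$universe)))
  invisible(x)
}

#' Read a miRNA-target pair table from TSV
#'
#' Expects two tab-separated columns (miRNA, gene), one pair per row, with
#' a header row.
#'
#' @param path Path to the pair table.
#' @param universe Optional gene universe passed to [target_map()].
#' @return A `target_map`.
#' @export
read_target_map_tsv <- function(path, universe = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("mirna", "gene")
  target_map(df, universe = universe)
}

#' Write a target map as a miRNA-target pair table
#'
#' @param targets A `target_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_map_tsv <- function(targets, path) {
  df <- data.frame(
    mirna = rep(names(targets$map), lengths(targets$map)),
    gene = unlist(targets$map, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stopf("GMT line with fewer than 3 fields")
    f[-(1:2)]
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction edge list from TSV
#'
#' Expects a header row and at least two columns (node A, node B); an
#' optional third column holds edge confidence in \[0, 1\]. Duplicate
#' edges and self-loops are dropped.
#'
#' @param path Path to the edge list.
#' @return An undirected [igraph::graph] with an edge attribute
#'   `confidence` when present in the file.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("edge list needs at least two columns")
  edges <- data.frame(from = as.character(df[[1L]]),
                      to = as.character(df[[2L]]),
                      stringsAsFactors = FALSE)
  if (ncol(df) >= 3L) edges$confidence <- as.numeric(df[[3L]])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "max")
}
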