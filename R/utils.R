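# Internal validation and shared helpers.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Reserved module label for unassigned genes
#'
#' Genes that do not belong to any detected module carry the label
#' `"grey"`, following the colour convention of weighted co-expression
#' analysis. The grey "module" is excluded from eigengene computation,
#' trait screening and enrichment module sizes, but its genes still count
#' towards the enrichment universe.
#'
#' @return The character scalar `"grey"`.
#' @export
unassigned_label <- function() "grey"

# Colour labels assigned to modules in decreasing size order, echoing the
# field's convention; overflow falls back to "module<k>".
module_palette <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen",
           "darkturquoise", "darkgrey", "orange", "darkorange", "white",
           "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
           "darkolivegreen", "darkmagenta", "sienna3", "yellowgreen",
           "skyblue3", "plum1", "orangered4", "mediumpurple3")
  if (n <= length(pal)) pal[seq_len(n)] else
    c(pal, paste0("module", seq.int(length(pal) + 1L, n)))
}

check_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix (features x samples)", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("%s must have feature rownames and sample colnames", what)
  if (anyNA(x)) stopf("%s contains missing values", what)
  invisible(x)
}

check_counts <- function(x, what = "count matrix") {
  check_expression_matrix(x, what)
  if (any(x < 0)) stopf("%s contains negative counts", what)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to compare detected module partitions against planted truth.
#'
#' @param a,b Vectors of labels of equal length.
#' @return Numeric scalar in \[-1, 1\]; 1 means identical partitions up to
#'   label renaming.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Jaccard index between two sets
#'
#' @param a,b Vectors treated as sets.
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard_index <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Pearson correlation p-value from the t statistic with n-2 df (two-sided).
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tval), df = n - 2)
}
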