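# Signed weighted co-expression network: Pearson correlation, signed
# adjacency ((1+r)/2)^beta, soft-threshold selection by scale-free topology
# fit, topological overlap, dendrogram-based module detection, module
# eigengenes, eigengene-based module merging and kME membership filters.

#' Gene-gene Pearson correlation matrix
#'
#' @param expr Expression matrix (genes x samples), at least 3 samples,
#'   no zero-variance gene.
#' @return Symmetric genes-x-genes correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(expr) {
  check_expression_matrix(expr)
  if (ncol(expr) < 3L) stopf("correlation needs at least 3 samples")
  v <- apply(expr, 1L, var)
  if (any(v == 0))
    stopf("zero-variance gene(s): %s",
          paste(head(rownames(expr)[v == 0], 5L), collapse = ", "))
  cor(t(expr))
}

#' Signed adjacency from a correlation matrix
#'
#' Computes `a_ij = ((1 + cor_ij) / 2)^beta`, mapping correlation into
#' \[0, 1\] so that strong negative correlations approach 0 and the
#' soft-threshold power `beta` suppresses weak correlations.
#'
#' @param cor_matrix Symmetric correlation matrix.
#' @param beta Soft-threshold power, `>= 1`.
#' @return Adjacency matrix with unit diagonal and entries in \[0, 1\],
#'   with attribute `beta`.
#' @export
signed_adjacency <- function(cor_matrix, beta) {
  if (beta < 1) stopf("beta must be >= 1")
  adj <- ((1 + cor_matrix) / 2)^beta
  diag(adj) <- 1
  attr(adj, "beta") <- beta
  adj
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the signed network's connectivities
#' `k_i = sum_j a_ij` are binned (equal-occupancy bins on log10 k) and
#' log10(frequency) is regressed on log10(mean bin connectivity). The fit
#' index is R^2 multiplied by the negative sign of the slope, so a
#' network whose connectivity distribution *increases* cannot pass. The
#' chosen power is the smallest candidate whose fit exceeds `target_r2`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param powers Candidate powers; default 1-10 then even values to 20.
#' @param target_r2 Scale-free fit target, default 0.9.
#' @param n_bins Number of equal-occupancy connectivity bins.
#' @param cor_matrix Optional precomputed correlation matrix.
#' @return List with `report` (data frame: power, fit, mean_connectivity),
#'   `power` (chosen power, `NA` with a warning when none passes) and
#'   `target_r2`.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, seq(12L, 20L, 2L)),
                                target_r2 = 0.9, n_bins = 10L,
                                cor_matrix = NULL) {
  if (!length(powers)) stopf("powers must be non-empty")
  if (is.null(cor_matrix)) cor_matrix <- pearson_matrix(expr)
  powers <- sort(powers)
  rows <- lapply(powers, function(p) {
    adj <- signed_adjacency(cor_matrix, p)
    k <- rowSums(adj) - 1
    data.frame(power = p, fit = scale_free_fit(k, n_bins),
               mean_connectivity = mean(k))
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  passing <- report$power[!is.na(report$fit) & report$fit > target_r2]
  if (length(passing)) {
    chosen <- min(passing)
  } else {
    chosen <- NA_real_
    warning(sprintf("no candidate power reaches scale-free fit > %g",
                    target_r2), call. = FALSE)
  }
  list(report = report, power = chosen, target_r2 = target_r2)
}

# Signed scale-free topology fit index for a connectivity vector.
# Equal-width bins on k (the reference convention): equal-occupancy bins
# would make the per-bin frequency constant and the regression vacuous.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (!length(k)) stopf("all connectivities are zero")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  if (length(unique(breaks)) < 3L) return(NA_real_)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  freq <- tabulate(bin, nbins = length(breaks) - 1L)
  mean_k <- vapply(seq_along(freq),
                   function(b) mean(k[bin == b]), 0)
  ok <- freq > 0 & mean_k > 0
  if (sum(ok) < 3L) return(NA_real_)
  lf <- log10(freq[ok]); lk <- log10(mean_k[ok])
  r <- cor(lf, lk)
  if (is.na(r)) return(NA_real_)
  -sign(r) * r^2
}

#' Topological overlap similarity
#'
#' Standard unsigned topological overlap on a (signed) adjacency matrix:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` with `k_i = sum_{u != i} a_iu`, and unit diagonal. An isolated
#' pair (zero denominator) gets `TOM_ij = a_ij`.
#'
#' @param adj Adjacency matrix from [signed_adjacency()].
#' @return Symmetric TOM matrix with entries in \[0, 1\].
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- ifelse(denom > 0, num / denom, a)
  tom <- (tom + t(tom)) / 2
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# Largest-gap heuristic: the widest jump in the sorted merge heights
# separates tight branches (which complete low) from the loose joins
# above them. Incidental jumps among the earliest merges can be wide yet
# structurally meaningless (cutting there shatters the tree into
# singletons), so candidate gaps are visited in decreasing width and the
# first whose cut isolates at least one branch of `min_branch` leaves is
# chosen. Returns NULL when no positive gap qualifies.
best_gap_cut <- function(hc, min_branch = 8L, max_candidates = 50L) {
  h <- sort(hc$height)
  m <- length(h)
  if (m < 2L) return(NULL)
  gaps <- diff(h)
  ord <- order(gaps, decreasing = TRUE)
  ord <- ord[gaps[ord] > 0]
  rng <- h[m] - h[1L]
  for (i in head(ord, max_candidates)) {
    cut <- h[i] + gaps[i] / 2
    cl <- cutree(hc, h = cut)
    if (max(tabulate(cl)) >= min_branch)
      return(list(cut = cut, labels = cl, width = gaps[i],
                  prominence = if (rng > 0) gaps[i] / rng else 0))
  }
  NULL
}

# Widest sufficiently prominent gap whose cut separates a cluster into at
# least two sub-branches of module size; NULL when no such gap exists.
best_split_cut <- function(hc, min_module_size, prominence,
                           max_candidates = 50L) {
  h <- sort(hc$height)
  m <- length(h)
  if (m < 2L) return(NULL)
  rng <- h[m] - h[1L]
  if (rng <= 0) return(NULL)
  gaps <- diff(h)
  ord <- order(gaps, decreasing = TRUE)
  ord <- ord[gaps[ord] / rng >= prominence]
  for (i in head(ord, max_candidates)) {
    cl <- cutree(hc, h = h[i] + gaps[i] / 2)
    if (sum(tabulate(cl) >= min_module_size) >= 2L) return(cl)
  }
  NULL
}

# Recursively split one cluster when its dendrogram shows a prominent gap
# and at least two sub-branches meet the minimum module size.
split_cluster <- function(diss, items, min_module_size, prominence) {
  n <- length(items)
  if (n < 2L * min_module_size) return(list(items))
  hc <- hclust(as.dist(diss[items, items, drop = FALSE]), method = "average")
  cl <- best_split_cut(hc, min_module_size, prominence)
  if (is.null(cl)) return(list(items))
  out <- list()
  for (g in unique(cl)) {
    sub <- items[cl == g]
    if (length(sub) >= min_module_size) {
      out <- c(out, split_cluster(diss, sub, min_module_size, prominence))
    } else {
      out <- c(out, list(sub))  # undersized leftovers -> unassigned later
    }
  }
  out
}

#' Detect modules on the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut by a tree-shape criterion: by default at the widest gap in the
#' sorted merge heights whose cut isolates at least one real branch
#' (configurable to a fixed height or a height quantile). With
#' `deep_split >= 2` each cluster is recursively
#' re-examined and split where its own dendrogram shows a sufficiently
#' prominent gap and both sub-branches meet `min_module_size`; larger
#' `deep_split` lowers the required prominence (more, smaller modules).
#' Clusters below `min_module_size` are assigned the reserved label from
#' [unassigned_label()]. Modules are labelled by decreasing size.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size Minimum genes per module (default 30).
#' @param deep_split Split sensitivity 0-4 (default 2); 0 or 1 disables
#'   recursive sub-splitting.
#' @param cut_method `"gap"` (default), `"quantile"` or `"fixed"`.
#' @param cut_height Height for `cut_method = "fixed"`.
#' @param cut_quantile Merge-height quantile for `cut_method = "quantile"`.
#' @return Named character vector: gene id -> module label.
#' @export
detect_modules <- function(tom, min_module_size = 30L, deep_split = 2L,
                           cut_method = c("gap", "quantile", "fixed"),
                           cut_height = NULL, cut_quantile = 0.99) {
  cut_method <- match.arg(cut_method)
  if (min_module_size < 2L) stopf("min_module_size must be >= 2")
  genes <- rownames(tom)
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  cl <- switch(cut_method,
               gap = {
                 bc <- best_gap_cut(hc)
                 if (is.null(bc)) rep(1L, length(genes)) else bc$labels
               },
               quantile = cutree(hc, h = quantile(hc$height, cut_quantile)),
               fixed = {
                 if (is.null(cut_height)) stopf("cut_height required")
                 cutree(hc, h = cut_height)
               })
  clusters <- split(seq_along(genes), cl)

  prominence_by_split <- c(Inf, Inf, 0.45, 0.30, 0.20)
  prominence <- prominence_by_split[min(max(deep_split, 0L), 4L) + 1L]
  if (is.finite(prominence)) {
    clusters <- unlist(lapply(clusters, function(items) {
      split_cluster(diss, items, min_module_size, prominence)
    }), recursive = FALSE)
  }

  labels <- rep(unassigned_label(), length(genes))
  keep <- clusters[lengths(clusters) >= min_module_size]
  if (length(keep)) {
    keep <- keep[order(-lengths(keep))]
    pal <- module_palette(length(keep))
    for (i in seq_along(keep)) labels[keep[[i]]] <- pal[i]
  }
  names(labels) <- genes
  labels
}

#' Module eigengenes
#'
#' For each module the member genes are standardized across samples and
#' the first principal component score per sample is extracted,
#' standardized, and oriented so that it correlates positively with the
#' module's mean standardized profile.
#'
#' @param expr Expression matrix (genes x samples).
#' @param partition Named gene -> module label vector; the reserved
#'   unassigned label is skipped.
#' @return Matrix (modules x samples) of unit-variance eigengene profiles.
#' @export
module_eigengenes <- function(expr, partition) {
  check_expression_matrix(expr)
  modules <- setdiff(unique(partition), unassigned_label())
  if (!length(modules)) stopf("partition contains no modules")
  me <- matrix(NA_real_, length(modules), ncol(expr),
               dimnames = list(modules, colnames(expr)))
  for (mod in modules) {
    genes <- names(partition)[partition == mod]
    genes <- intersect(genes, rownames(expr))
    if (length(genes) < 2L)
      stopf("module '%s' has fewer than 2 genes in the expression matrix",
            mod)
    x <- expr[genes, , drop = FALSE]
    v <- apply(x, 1L, var)
    if (any(v == 0))
      stopf("module '%s' contains zero-variance gene '%s'",
            mod, genes[which(v == 0)[1L]])
    xs <- t(scale(t(x)))  # genes standardized across samples
    pc <- svd(xs, nu = 0L, nv = 1L)$v[, 1L]
    pc <- as.numeric(scale(pc))
    if (cor(pc, colMeans(xs)) < 0) pc <- -pc
    me[mod, ] <- pc
  }
  me
}

# kME: correlation of each gene with the eigengene of a given module.
module_kme <- function(expr, eigengene) {
  as.numeric(cor(t(expr), eigengene))
}

#' Merge modules with correlated eigengenes
#'
#' Clusters eigengenes on the dissimilarity `1 - cor` and merges, closest
#' pair first, any pair of modules closer than `cut_height`; eigengenes
#' are recomputed after each merge and the process iterates to a fixed
#' point. The merged module keeps the label of the larger member.
#'
#' @param expr Expression matrix (genes x samples).
#' @param partition Named gene -> module label vector.
#' @param cut_height Eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. eigengene correlation above 0.75).
#' @return The merged partition (named character vector).
#' @export
merge_close_modules <- function(expr, partition, cut_height = 0.25) {
  if (cut_height <= 0) return(partition)
  repeat {
    modules <- setdiff(unique(partition), unassigned_label())
    if (length(modules) < 2L) return(partition)
    me <- module_eigengenes(expr, partition)
    diss <- 1 - cor(t(me))
    diag(diss) <- Inf
    i <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    if (diss[i[1L], i[2L]] >= cut_height) return(partition)
    a <- rownames(me)[i[1L]]; b <- rownames(me)[i[2L]]
    sizes <- table(partition)
    keep_label <- if (sizes[[a]] >= sizes[[b]]) a else b
    drop_label <- setdiff(c(a, b), keep_label)
    partition[partition == drop_label] <- keep_label
  }
}

#' Module-membership (kME) filters
#'
#' Gene level: members whose correlation with their own module eigengene
#' falls below `min_kme_to_stay` are reassigned to the unassigned label.
#' Module level: modules lacking at least `min_core_size` members with
#' kME `>= min_core_kme` are dissolved entirely.
#'
#' @param expr Expression matrix (genes x samples).
#' @param partition Named gene -> module label vector.
#' @param eigengenes Eigengene matrix for `partition`
#'   (from [module_eigengenes()]); recomputed when `NULL`.
#' @param min_kme_to_stay Gene-level membership threshold (default 0.3).
#' @param min_core_kme Core membership threshold (default 0.5).
#' @param min_core_size Required number of core members (default 10).
#' @return The filtered partition (named character vector).
#' @export
apply_kme_filters <- function(expr, partition, eigengenes = NULL,
                              min_kme_to_stay = 0.3, min_core_kme = 0.5,
                              min_core_size = 10L) {
  if (is.null(eigengenes)) eigengenes <- module_eigengenes(expr, partition)
  out <- partition
  for (mod in setdiff(unique(partition), unassigned_label())) {
    genes <- names(partition)[partition == mod]
    kme <- module_kme(expr[genes, , drop = FALSE], eigengenes[mod, ])
    if (sum(kme >= min_core_kme) < min_core_size) {
      out[genes] <- unassigned_label()       # module dissolved
    } else {
      out[genes[kme < min_kme_to_stay]] <- unassigned_label()
    }
  }
  out
}
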