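# Fixture builders and independent oracles shared across test files.

# Expression matrix whose sample correlation matrix is exactly
# cor_ij = l_i * l_j (single factor with loadings l), built from
# orthonormalized centered noise. Deterministic given the seed.
make_factor_expr <- function(p, n, loadings, seed = 42L) {
  stopifnot(p + 1L <= n - 1L, length(loadings) == p)
  set.seed(seed)
  M <- scale(matrix(rnorm(n * (p + 1L)), n), scale = FALSE)
  Q <- qr.Q(qr(M))
  f <- Q[, 1L]
  E <- Q[, -1L, drop = FALSE]
  X <- vapply(seq_len(p), function(i) {
    loadings[i] * f + sqrt(1 - loadings[i]^2) * E[, i]
  }, numeric(n))
  m <- t(X)
  dimnames(m) <- list(sprintf("g%03d", seq_len(p)),
                      sprintf("s%03d", seq_len(n)))
  m
}

# Small clinical table builder with sensible defaults.
make_clinical <- function(sample_id,
                          stage = rep("II", length(sample_id)),
                          t = rep("T2", length(sample_id)),
                          n = rep("N0", length(sample_id)),
                          m = rep("M0", length(sample_id)),
                          pharm = rep("no", length(sample_id)),
                          radio = rep("no", length(sample_id)),
                          age = rep(60, length(sample_id))) {
  data.frame(sample_id = sample_id, stage = stage, t = t, n = n, m = m,
             pharmaceutical_treatment = pharm, radiation_treatment = radio,
             age = age, stringsAsFactors = FALSE)
}

# Exact hypergeometric upper tail by direct combinatorial summation.
# choose() is exact in double precision throughout the N <= 30 range.
hyper_oracle <- function(x, n, z, N) {
  ks <- z:min(x, n)
  ks <- ks[ks >= 0 & (n - ks) <= (N - x)]
  if (!length(ks)) return(0)
  sum(choose(x, ks) * choose(N - x, n - ks)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up, written as the textbook loop.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  pmin(q, 1)
}

# Naive step-by-step enumeration of the gene-set variation random walk
# for the ecdf method, independent of the package implementation.
gsva_ecdf_oracle <- function(expr, gene_set, tau = 1) {
  p <- nrow(expr); n <- ncol(expr)
  scores <- numeric(n)
  for (j in seq_len(n)) {
    z <- numeric(p)
    for (g in seq_len(p)) z[g] <- sum(expr[g, ] <= expr[g, j]) / n
    ord <- order(-z, match(rownames(expr),
                           sort(rownames(expr), method = "radix")))
    walk <- 0; pos <- 0; neg <- 0
    in_set <- rownames(expr) %in% gene_set
    total_in <- 0
    for (i in seq_len(p)) {
      if (in_set[ord[i]]) total_in <- total_in + abs(i - (p + 1) / 2)^tau
    }
    n_out <- p - sum(in_set)
    acc_in <- 0; acc_out <- 0
    for (i in seq_len(p)) {
      if (in_set[ord[i]]) acc_in <- acc_in + abs(i - (p + 1) / 2)^tau
      else acc_out <- acc_out + 1
      walk <- acc_in / total_in - acc_out / n_out
      if (walk > pos) pos <- walk
      if (walk < neg) neg <- walk
    }
    scores[j] <- pos + neg
  }
  names(scores) <- colnames(expr)
  scores
}

# Simulation configs used by the planted-structure acceptance checks.
recovery_config <- function(seed) {
  sim_config(seed = seed, n_samples = 100L, module_sizes = rep(50L, 5L),
             background_genes = 100L, module_cor = 0.8, n_mirnas = 10L,
             regulators = list(), trait_modules = list(),
             n_treated = 0L, n_unstaged = 0L)
}

regulator_config <- function(seed) {
  sim_config(seed = seed, n_samples = 100L,
             module_sizes = c(100L, 100L), background_genes = 1800L,
             module_cor = 0.8,
             trait_modules = list(c(1, 1, 0.5), c(2, 1, 0.5)),
             n_mirnas = 200L,
             regulators = list(c(1, 1, 0.6, 0.7), c(2, 2, 0.6, 0.7),
                               c(3, 1, 0.6, 0.7)),
             n_treated = 0L, n_unstaged = 0L)
}

# Detection chain shared by recovery tests: normalize, auto soft threshold
# (signed-network fallback 12), TOM, detect, merge, kME filters.
detect_chain <- function(expr) {
  cm <- pearson_matrix(expr)
  st <- suppressWarnings(pick_soft_threshold(expr, cor_matrix = cm))
  beta <- if (is.na(st$power)) 12 else st$power
  tom <- tom_similarity(signed_adjacency(cm, beta))
  p <- detect_modules(tom)
  p <- merge_close_modules(expr, p)
  apply_kme_filters(expr, p)
}
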