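# Network construction: correlation, signed adjacency, soft threshold,
# topological overlap, module detection, eigengenes, merging, kME filters.

test_that("pearson matrix matches the direct formula", {
  expr <- matrix(c(1, 2, 3, 4,
                   2, 1, 4, 3,
                   5, 3, 1, 2), 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  pm <- pearson_matrix(expr)
  hand <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(pm["g1", "g2"], hand(expr[1, ], expr[2, ]), tolerance = 1e-12)
  expect_equal(pm["g1", "g3"], hand(expr[1, ], expr[3, ]), tolerance = 1e-12)
  expect_equal(diag(pm), c(g1 = 1, g2 = 1, g3 = 1))

  dup <- rbind(expr, g4 = expr[1, ], g5 = -expr[1, ])
  pm2 <- pearson_matrix(dup)
  expect_equal(pm2["g1", "g4"], 1)
  expect_equal(pm2["g1", "g5"], -1)

  flat <- rbind(expr, g0 = c(2, 2, 2, 2))
  expect_error(pearson_matrix(flat), "g0")
})

test_that("signed adjacency follows ((1 + r)/2)^beta", {
  cm <- matrix(c(1, 1, 0, -1,
                 1, 1, 0, 0,
                 0, 0, 1, 0,
                 -1, 0, 0, 1), 4)
  for (beta in c(1, 6, 16)) {
    adj <- signed_adjacency(cm, beta)
    expect_equal(adj[1, 2], 1)
    expect_equal(adj[1, 4], 0)
    expect_equal(adj[1, 3], 0.5^beta)
  }
  expect_equal(signed_adjacency(cm, 16)[1, 3], 1.52587890625e-05)
  expect_error(signed_adjacency(cm, 0.5), "beta")
})

test_that("adjacency and TOM stay symmetric in [0, 1] on random inputs", {
  set.seed(9)
  for (i in 1:10) {
    expr <- matrix(rnorm(30 * 12), 30,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
    adj <- signed_adjacency(pearson_matrix(expr), sample(c(2, 6, 12), 1))
    tom <- tom_similarity(adj)
    for (m in list(adj, tom)) {
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(m, t(m))
      expect_equal(unname(diag(m)), rep(1, 30))
    }
  }
})

test_that("large beta makes adjacency an indicator of perfect correlation", {
  set.seed(10)
  expr <- matrix(rnorm(10 * 8), 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  expr <- rbind(expr, g11 = expr[1, ])
  adj <- signed_adjacency(pearson_matrix(expr), 64)
  target <- (abs(pearson_matrix(expr) - 1) < 1e-12) * 1
  expect_equal(adj, target, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("TOM matches closed forms", {
  # zero off-diagonal adjacency -> identity pattern
  a0 <- diag(4)
  expect_equal(tom_similarity(a0), diag(4))

  # complete graph: all off-diagonal TOM = 1
  m <- 5
  a1 <- matrix(1, m, m)
  t1 <- tom_similarity(a1)
  expect_equal(t1, matrix(1, m, m))

  # 3-node worked case
  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 0.8
  a[1, 3] <- a[3, 1] <- 0.4
  a[2, 3] <- a[3, 2] <- 0.2
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], (0.4 * 0.2 + 0.8) / (min(1.2, 1.0) + 1 - 0.8),
               tolerance = 1e-12)
  expect_equal(tom[1, 2], 0.88 / 1.2, tolerance = 1e-12)
})

test_that("soft threshold picks the smallest passing power", {
  p <- 100
  loadings <- 0.95 * (seq_len(p) / p)^3
  expr <- make_factor_expr(p, 120, loadings, seed = 42)
  st <- suppressWarnings(pick_soft_threshold(expr, powers = 1:10))
  expect_equal(st$power, 6)
  expect_gt(st$report$fit[st$report$power == 6], 0.9)
  expect_true(all(st$report$fit[st$report$power < 6] <= 0.9))

  # vacuous criterion selects the smallest candidate
  st0 <- suppressWarnings(pick_soft_threshold(expr, powers = c(3, 5, 9),
                                              target_r2 = 0))
  expect_equal(st0$power, 3)

  # mean connectivity strictly decreases with power
  expect_true(all(diff(st$report$mean_connectivity) < 0))
})

test_that("module detection recovers two planted blocks exactly", {
  set.seed(21)
  block <- function(p, n, l) {
    f <- rnorm(n)
    t(vapply(seq_len(p), function(i) l * f + sqrt(1 - l^2) * rnorm(n),
             numeric(n)))
  }
  expr <- rbind(block(50, 60, 0.9), block(50, 60, 0.9))
  dimnames(expr) <- list(paste0("g", 1:100), paste0("s", 1:60))
  truth <- rep(c("b1", "b2"), each = 50)
  tom <- tom_similarity(signed_adjacency(pearson_matrix(expr), 6))
  part <- detect_modules(tom, min_module_size = 30)
  expect_equal(adjusted_rand_index(part, truth), 1)

  # oversized minimum module size leaves everything unassigned
  part_all <- detect_modules(tom, min_module_size = 60)
  expect_true(all(part_all == unassigned_label()))

  # permuting gene order permutes labels but not the partition
  perm <- sample(100)
  part_perm <- detect_modules(tom[perm, perm], min_module_size = 30)
  expect_equal(adjusted_rand_index(part_perm[rownames(tom)], part), 1)

  # degenerate TOM neither crashes nor invents structure
  flat <- matrix(0.5, 40, 40,
                 dimnames = list(paste0("g", 1:40), paste0("g", 1:40)))
  diag(flat) <- 1
  part_flat <- detect_modules(flat, min_module_size = 5)
  expect_lte(length(setdiff(unique(part_flat), unassigned_label())), 1L)
})

test_that("eigengenes capture the planted factor and orientation", {
  # module of identical profiles: eigengene is that profile
  prof <- rnorm(20)
  expr <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(expr) <- paste0("s", 1:20)
  me <- module_eigengenes(expr, c(g1 = "m", g2 = "m", g3 = "m"))
  expect_equal(abs(cor(me["m", ], prof)), 1, tolerance = 1e-12)
  expect_gt(cor(me["m", ], prof), 0)  # orientation convention

  # planted single-factor module, loading 0.9, n = 100
  set.seed(42)
  f <- rnorm(100)
  mod <- t(vapply(1:40, function(i) 0.9 * f + sqrt(1 - 0.81) * rnorm(100),
                  numeric(100)))
  dimnames(mod) <- list(paste0("g", 1:40), paste0("s", 1:100))
  me2 <- module_eigengenes(mod, setNames(rep("m", 40), rownames(mod)))
  expect_gte(cor(me2["m", ], f), 0.95)

  # sign flip of the eigengene leaves |cor| with members unchanged
  expect_equal(abs(cor(-me2["m", ], mod["g1", ])),
               abs(cor(me2["m", ], mod["g1", ])))

  expr_zv <- rbind(expr, g4 = rep(1, 20))
  expect_error(
    module_eigengenes(expr_zv, setNames(rep("m", 4), rownames(expr_zv))),
    "zero-variance")
})

test_that("modules from a shared factor merge; orthogonal ones do not", {
  set.seed(33)
  n <- 80
  f_shared <- rnorm(n); f_other <- rnorm(n)
  gene <- function(f, l = 0.9) l * f + sqrt(1 - l^2) * rnorm(n)
  expr <- rbind(
    t(vapply(1:20, function(i) gene(f_shared), numeric(n))),
    t(vapply(1:20, function(i) gene(f_shared), numeric(n))),
    t(vapply(1:20, function(i) gene(f_other), numeric(n))))
  dimnames(expr) <- list(paste0("g", 1:60), paste0("s", 1:n))
  part <- setNames(rep(c("a", "b", "c"), each = 20), rownames(expr))

  merged <- merge_close_modules(expr, part, cut_height = 0.25)
  expect_length(setdiff(unique(merged), unassigned_label()), 2L)
  expect_length(unique(merged[1:40]), 1L)           # a and b merged
  expect_length(intersect(merged[1:40], merged[41:60]), 0L)

  expect_equal(merge_close_modules(expr, part, cut_height = 0), part)
})

test_that("kME filters drop weak members and dissolve coreless modules", {
  set.seed(44)
  n <- 60
  f <- rnorm(n)
  strong <- t(vapply(1:12, function(i) 0.9 * f + 0.44 * rnorm(n),
                     numeric(n)))
  weak <- matrix(rnorm(3 * n), 3)  # kME near zero
  expr <- rbind(strong, weak)
  dimnames(expr) <- list(paste0("g", 1:15), paste0("s", 1:n))
  part <- setNames(rep("m", 15), rownames(expr))

  filtered <- apply_kme_filters(expr, part)
  expect_true(all(filtered[1:12] == "m"))
  expect_true(all(filtered[13:15] == unassigned_label()))

  # all strong members: partition unchanged
  dimnames(strong) <- list(paste0("g", 1:12), paste0("s", 1:n))
  part_s <- setNames(rep("m", 12), rownames(strong))
  expect_equal(apply_kme_filters(strong, part_s), part_s)

  # module lacking 10 core members at kME >= 0.5 dissolves entirely
  small <- strong[1:9, ]
  mixed <- rbind(small, matrix(rnorm(6 * n), 6))
  dimnames(mixed) <- list(paste0("g", 1:15), paste0("s", 1:n))
  part_m <- setNames(rep("m", 15), rownames(mixed))
  dissolved <- apply_kme_filters(mixed, part_m, min_core_kme = 0.5,
                                 min_core_size = 10)
  expect_true(all(dissolved == unassigned_label()))
})
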