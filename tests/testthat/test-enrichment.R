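# Hypergeometric over-representation, BH adjustment, miRNA-eigengene
# correlation and dual-threshold selection.

test_that("hypergeometric upper tail matches closed forms", {
  expect_equal(hypergeom_upper(5, 3, 0, 12), 1)
  expect_equal(hypergeom_upper(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  # non-increasing in z
  ps <- vapply(0:5, function(z) hypergeom_upper(8, 5, z, 20), 0)
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_upper(5, 3, 4, 12), "infeasible")
  expect_error(hypergeom_upper(15, 3, 1, 12), "infeasible")
})

test_that("hypergeometric tail equals exact enumeration on a small grid", {
  for (N in c(6, 11, 15)) {
    for (x in seq(0, N, by = 2)) {
      for (n in seq(1, N, by = 3)) {
        for (z in 0:min(x, n)) {
          expect_equal(hypergeom_upper(x, n, z, N),
                       hyper_oracle(x, n, z, N),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("hypergeometric pmf sums to one over its support", {
  for (N in c(8, 13, 20)) {
    for (x in c(0, 3, N %/% 2, N)) {
      for (n in c(1, N %/% 3 + 1, N)) {
        lo <- max(0, n - (N - x))
        hi <- min(x, n)
        pmf_sum <- sum(vapply(lo:hi, function(k) {
          choose(x, k) * choose(N - x, n - k) / choose(N, n)
        }, 0))
        expect_equal(pmf_sum, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03, 1)),
               c(0.02, 0.053333333333333, 0.053333333333333, 1),
               tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.5, 0.01)), c(0.5, 0.02))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("BH is order-invariant and monotone over random vectors", {
  set.seed(77)
  for (i in 1:1000) {
    p <- runif(sample(2:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
})

test_that("enrichment records cover the miRNA x module grid", {
  genes <- paste0("g", 1:40)
  partition <- setNames(rep(c("mA", "mB", unassigned_label()),
                            c(10, 10, 20)), genes)
  tm <- target_map(
    data.frame(mirna = rep(c("mir1", "mir2"), c(8, 5)),
               gene = c(paste0("g", 1:8), paste0("g", 21:25))),
    universe = genes)
  rec <- enrich_mirnas(tm, partition, c("mA", "mB"))
  expect_equal(nrow(rec), 4L)  # 2 miRNAs x 2 modules
  expect_equal(unique(rec$N), 40L)  # unassigned genes count in N
  expect_equal(unique(rec$x[rec$module == "mA"]), 10L)

  r1 <- rec[rec$mirna == "mir1" & rec$module == "mA", ]
  expect_equal(r1$z, 8L)
  expect_equal(r1$p, hyper_oracle(10, 8, 8, 40), tolerance = 1e-12)

  # all-background target set: z = 0 against both modules, p = 1
  r2 <- rec[rec$mirna == "mir2" & rec$module == "mA", ]
  expect_equal(r2$z, 0L)
  expect_equal(r2$p, 1)

  expect_error(enrich_mirnas(tm, partition, "missing"), "absent")
})

test_that("miRNA-eigengene correlation flags constant profiles", {
  n <- 20
  set.seed(5)
  me <- rbind(mA = rnorm(n), mB = rnorm(n))
  colnames(me) <- paste0("s", 1:n)
  mir <- rbind(mir1 = -me["mA", ], mir2 = rep(3, n), mir3 = rnorm(n))
  colnames(mir) <- colnames(me)
  r <- mirna_module_correlation(mir, me)
  expect_equal(r["mir1", "mA"], -1, tolerance = 1e-12)
  expect_true(all(is.na(r["mir2", ])))

  rec <- data.frame(fdr = c(0.01, 0.01), r_me = c(NA, -0.9))
  expect_equal(select_significant(rec)$selected, c(FALSE, TRUE))
})

test_that("selection requires both FDR and anticorrelation, strictly", {
  rec <- data.frame(
    fdr = c(0.01, 0.01, 0.2, 0.05, 0.01),
    r_me = c(-0.5, 0.4, -0.9, -0.5, -0.3))
  sel <- select_significant(rec, fdr_thr = 0.05, cor_thr = -0.3)$selected
  expect_equal(sel, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("decoy miRNAs are selected at no more than the nominal FDR", {
  hits <- 0; screens <- 0
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_samples = 60,
                      module_sizes = c(60L, 60L), background_genes = 380L,
                      module_cor = 0.8,
                      trait_modules = list(c(1, 1, 0.5), c(2, 1, 0.5)),
                      n_mirnas = 200L, regulators = list(),
                      n_treated = 0L, n_unstaged = 0L)
    d <- simulate_dataset(cfg)
    g <- normalize_log2(filter_low_counts(d$gene_counts, 50))
    mi <- normalize_log2(filter_low_counts(d$mirna_counts, 10))
    partition <- d$truth$modules[rownames(g)]
    me <- module_eigengenes(g, partition)
    rec <- screen_regulators(mi, d$targets, partition, me,
                             c("module_1", "module_2"))
    hits <- hits + length(unique(rec$mirna[rec$selected]))
    screens <- screens + 1
  }
  expect_lte(hits / (screens * 200), 0.05)
})
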