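# Sample selection, count filtering, CPM/log2 normalization, target-map
# merging and universe restriction.

test_that("sample selection requires both assays, no therapy and stage", {
  clin <- make_clinical(c("s1", "s2", "s3", "s4", "s5"),
                        stage = c("II", "II", "II", NA, "III"),
                        pharm = c("no", "no", "no", "no", "no"),
                        radio = c("yes", "no", "no", "no", "no"))
  gene_samples <- c("s1", "s2", "s4", "s5")
  mirna_samples <- c("s1", "s2", "s3", "s4", "s5")
  kept <- select_samples(clin, gene_samples, mirna_samples)
  expect_false("s1" %in% kept)  # radiation therapy recorded
  expect_false("s3" %in% kept)  # mRNA assay missing
  expect_false("s4" %in% kept)  # stage missing
  expect_equal(kept, c("s2", "s5"))
})

test_that("unknown therapy status is excluded by default, kept on request", {
  clin <- make_clinical(c("s1", "s2"), pharm = c("unknown", "no"))
  expect_equal(select_samples(clin, clin$sample_id, clin$sample_id), "s2")
  expect_equal(
    select_samples(clin, clin$sample_id, clin$sample_id,
                   exclude_unknown_treatment = FALSE),
    c("s1", "s2"))
})

test_that("empty selection is an explicit error", {
  clin <- make_clinical("s1", radio = "yes")
  expect_error(select_samples(clin, "s1", "s1"), "no samples survive")
})

test_that("low-count filter keeps features at or above the threshold", {
  m <- rbind(a = c(24, 25), b = c(25, 25), c = c(26, 25), d = c(0, 0))
  colnames(m) <- c("s1", "s2")
  expect_equal(rownames(filter_low_counts(m, 50)), c("b", "c"))
  expect_equal(rownames(filter_low_counts(m, 1)), c("a", "b", "c"))
  expect_equal(filter_low_counts(m, 0), m)
  m2 <- m; m2[1, 1] <- -1
  expect_error(filter_low_counts(m2, 50), "negative")
})

test_that("normalization is CPM + log2(x + 1)", {
  m <- matrix(c(999, 1e6 - 999, 10, 90), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- normalize_log2(m)
  expect_equal(norm["g1", "s1"], log2(1000), tolerance = 1e-12)
  expect_equal(norm["g1", "s1"], 9.9658, tolerance = 1e-4)

  m0 <- matrix(c(0, 50, 10, 90), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(normalize_log2(m0)["g1", "s1"], 0)

  doubled <- m; doubled[, 1] <- 2 * m[, 1]
  expect_equal(normalize_log2(doubled)[, 1], normalize_log2(m)[, 1])

  mz <- m; mz[, 2] <- 0
  expect_error(normalize_log2(mz), "s2")
})

test_that("target-map merging is a deduplicated pair union", {
  tm1 <- target_map(data.frame(mirna = c("m1", "m1", "m2"),
                               gene = c("a", "b", "c")))
  tm2 <- target_map(data.frame(mirna = c("m2", "m3", "m3", "m3"),
                               gene = c("d", "a", "b", "d")))
  merged <- merge_target_maps(list(tm1, tm2))
  expect_equal(n_target_pairs(merged), 7L)
  expect_equal(merge_target_maps(list(tm1, tm1))$map, tm1$map)

  # maps sharing 2 pairs, sizes 5 and 4 -> 7 by inclusion-exclusion
  tm3 <- target_map(data.frame(mirna = c("m1", "m1", "m1", "m2", "m2"),
                               gene = c("a", "b", "c", "a", "b")))
  tm4 <- target_map(data.frame(mirna = c("m1", "m1", "m2", "m2"),
                               gene = c("a", "b", "c", "d")))
  expect_equal(n_target_pairs(merge_target_maps(list(tm3, tm4))), 7L)
})

test_that("universe restriction intersects genes and is idempotent", {
  expr <- matrix(rnorm(12), 3, dimnames = list(c("A", "B", "C"),
                                               paste0("s", 1:4)))
  tm <- target_map(data.frame(mirna = "m1", gene = c("B", "C", "D")),
                   universe = c("B", "C", "D"))
  r <- restrict_universe(expr, tm)
  expect_equal(sort(rownames(r$expr)), c("B", "C"))
  expect_equal(r$targets$universe, c("B", "C"))

  r2 <- restrict_universe(r$expr, r$targets)
  expect_equal(r2$expr, r$expr)
  expect_equal(r2$targets, r$targets)

  # universe superset of expression genes: expression unchanged
  tm_all <- target_map(data.frame(mirna = "m1", gene = "A"),
                       universe = c("A", "B", "C", "Z"))
  expect_equal(restrict_universe(expr, tm_all)$expr, expr)

  tm_disjoint <- target_map(data.frame(mirna = "m1", gene = "X"),
                            universe = c("X", "Y"))
  expect_error(restrict_universe(expr, tm_disjoint), "intersect")
})

test_that("filters commute with row and column permutations", {
  set.seed(1)
  m <- matrix(rpois(60, 30), 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  pr <- sample(6); pc <- sample(10)
  f1 <- filter_low_counts(m, 250)[, pc]
  f2 <- filter_low_counts(m[pr, pc], 250)
  expect_equal(f1[sort(rownames(f1)), ], f2[sort(rownames(f2)), ])
  expect_equal(normalize_log2(m)[pr, pc], normalize_log2(m[pr, pc]))
})

test_that("sample QC flags a grossly offset sample only when asked", {
  set.seed(2)
  expr <- matrix(rnorm(50 * 10), 50,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  expr[, "s10"] <- expr[, "s10"] + 50
  qc <- sample_qc_dendrogram(expr)
  expect_equal(qc$flagged, character(0))
  qc2 <- sample_qc_dendrogram(expr, height_threshold = 100)
  expect_equal(qc2$flagged, "s10")
  expect_error(sample_qc_dendrogram(expr[, 1:2]), "3 samples")

  # duplicated profiles merge at height zero
  dup <- cbind(expr[, c(1, 1)], expr[, 2:4])
  colnames(dup) <- paste0("d", 1:5)
  hc <- sample_qc_dendrogram(dup)$hclust
  expect_equal(min(hc$height), 0)
})
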