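make_dataset <- function(mat, phenotype) {
  expression_dataset(mat, phenotype)
}

test_that("signal-to-noise ranking applies the variance floor and tie-breaks", {
  # case (4,4,4) vs ctrl (2,2,2): sd floored at 0.2*|mu| -> 2/(0.8+0.4)
  mat <- rbind(GA = c(4, 4, 4, 2, 2, 2),
               GB = c(1, 1, 1, 1, 1, 1),
               GC = c(4, 4, 4, 2, 2, 2))
  ds <- make_dataset(mat, c(rep("case", 3), rep("control", 3)))
  rl <- rank_genes(ds, metric = "signal2noise")
  expect_equal(rl$scores[rl$genes == "GA"], 2 / (0.8 + 0.4),
               tolerance = 1e-12)
  # equal group means -> score 0
  expect_equal(rl$scores[rl$genes == "GB"], 0, tolerance = 1e-12)
  # identical scores -> lexicographic order
  expect_identical(rl$genes, c("GA", "GC", "GB"))
})

test_that("ranking falls back to log2fc below 3 samples per group", {
  mat <- matrix(c(5, 3, 1, 1), nrow = 2,
                dimnames = list(c("G1", "G2"), c("s1", "s2")))
  ds <- make_dataset(mat, c("case", "control"))
  rl <- rank_genes(ds, metric = "signal2noise")
  expect_identical(rl$metric, "log2fc")
  expect_equal(rl$scores, c(4, 2))
})

test_that("enrichment score matches hand computation and hits its bounds", {
  rl <- ranked_list(paste0("G", 1:10), as.numeric(10:1))
  # set {g1, g10}: hit weights 10/11 and 1/11, miss step -1/8
  es <- enrichment_score(rl, c("G1", "G10"), min_set_size = 1)
  expect_equal(es$ES, 10 / 11, tolerance = 1e-12)
  expect_identical(es$peak_index, 0L)
  # full set: no miss steps, ES exactly 1
  es_full <- enrichment_score(rl, paste0("G", 1:10), min_set_size = 1)
  expect_equal(es_full$ES, 1, tolerance = 1e-12)
  # bottom-concentrated set: negative ES
  es_neg <- enrichment_score(rl, c("G9", "G10"), min_set_size = 1)
  expect_lt(es_neg$ES, 0)
  expect_error(enrichment_score(rl, c("ZZ"), min_set_size = 1),
               "not represented")
  expect_error(enrichment_score(rl, c("G1", "G2"), min_set_size = 5),
               "min_set_size")
})

test_that("enrichment score equals the brute-force running sum", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    genes <- sprintf("G%03d", 1:n)
    scores <- sort(stats::rnorm(n, sd = 2), decreasing = TRUE)
    rl <- ranked_list(genes, scores)
    members <- sample(genes, sample(2:min(30, n - 1), 1))
    es <- enrichment_score(rl, members, min_set_size = 1)
    oracle <- oracle_es(scores, genes %in% members)
    expect_equal(es$ES, oracle$ES, tolerance = 1e-12)
    expect_identical(es$peak_index, oracle$peak_index)
    expect_true(es$ES >= -1 && es$ES <= 1)
  }
})

test_that("reversing a tie-free ranking negates the enrichment score", {
  set.seed(22)
  for (i in 1:20) {
    n <- 50
    genes <- sprintf("G%03d", 1:n)
    scores <- sort(stats::rnorm(n), decreasing = TRUE)
    members <- sample(genes, 8)
    es_fwd <- enrichment_score(ranked_list(genes, scores), members,
                               min_set_size = 1)
    es_rev <- enrichment_score(ranked_list(rev(genes), rev(-scores)),
                               members, min_set_size = 1)
    expect_equal(es_rev$ES, -es_fwd$ES, tolerance = 1e-12)
  }
})

test_that("permutation null is reproducible and handles degenerate sets", {
  sim <- simulate_expression(100, 5, 5, 10, 1, 1, seed = 23)
  rl <- rank_genes(sim$dataset)
  a <- permutation_null(sim$dataset, sim$truth$planted_set, rl,
                        mode = "gene_set", n_perm = 100, seed = 5)
  b <- permutation_null(sim$dataset, sim$truth$planted_set, rl,
                        mode = "gene_set", n_perm = 100, seed = 5)
  expect_identical(a, b)
  p <- permutation_null(sim$dataset, sim$truth$planted_set, rl,
                        mode = "phenotype", n_perm = 100, seed = 5)
  expect_identical(p, permutation_null(sim$dataset, sim$truth$planted_set,
                                       rl, mode = "phenotype", n_perm = 100,
                                       seed = 5))
  # gene_set mode with the whole ranked universe: every null ES is 1
  expect_warning(
    full <- permutation_null(sim$dataset, rl$genes, rl, mode = "gene_set",
                             n_perm = 20, seed = 6),
    "coarse")
  expect_equal(full, rep(1, 20), tolerance = 1e-12)
  expect_error(permutation_null(sim$dataset, sim$truth$planted_set, rl,
                                mode = "gene_set", n_perm = 5, seed = 1),
               "null")
})

test_that("normalization, permutation p and FDR follow their definitions", {
  # ES equal to the mean null magnitude -> NES = 1
  null_es <- c(0.2, 0.3, 0.4, -0.1, -0.2)
  res <- normalize_and_test(0.3, null_es)
  expect_equal(res$NES, 1, tolerance = 1e-12)
  # ES above every null value with 999 permutations -> p = 1/1000
  big_null <- seq(0.001, 0.999, length.out = 999)
  res2 <- normalize_and_test(1, big_null)
  expect_equal(res2$p_perm, 1 / 1000, tolerance = 1e-12)
  # hand computation on a 10-value null: 3 of 10 at least as extreme
  null10 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  res3 <- normalize_and_test(0.8, null10)
  expect_equal(res3$p_perm, (1 + 3) / 11, tolerance = 1e-12)
  expect_equal(res3$NES, 0.8 / mean(null10), tolerance = 1e-12)
  expect_true(res3$fdr >= 0 && res3$fdr <= 1)
  # no same-sign null: flagged, not silent NaN
  res4 <- normalize_and_test(0.5, c(-0.1, -0.2))
  expect_true(res4$flagged)
  expect_true(is.na(res4$NES))
})

test_that("leading edge extracts the members driving the peak", {
  rl <- ranked_list(paste0("G", 1:10), as.numeric(10:1))
  es <- enrichment_score(rl, c("G1", "G10"), min_set_size = 1)
  expect_identical(leading_edge(rl, c("G1", "G10"), es$ES, es$peak_index),
                   "G1")
  # set entirely above the peak -> whole set
  es2 <- enrichment_score(rl, c("G1", "G2", "G3"), min_set_size = 1)
  le2 <- leading_edge(rl, c("G1", "G2", "G3"), es2$ES, es2$peak_index)
  expect_setequal(le2, c("G1", "G2", "G3"))
  # mirrored ranking: leading edge of the sign-flipped result is identical
  rl_rev <- ranked_list(rev(rl$genes), rev(-rl$scores))
  es_rev <- enrichment_score(rl_rev, c("G1", "G10"), min_set_size = 1)
  expect_identical(
    leading_edge(rl_rev, c("G1", "G10"), es_rev$ES, es_rev$peak_index),
    "G1")
  expect_error(leading_edge(rl, c("G1"), 0, 0), "undefined")
})

test_that("regulation calls follow the NES/FDR thresholds", {
  th <- gsea_thresholds()
  expect_identical(classify_regulation(1.5, 0.01, th), "up")
  expect_identical(classify_regulation(1.5, 0.2, th), "ns")
  expect_identical(classify_regulation(-1.6, 0.01, th), "down")
  expect_identical(classify_regulation(1.2, 0.01, th), "ns")
  expect_identical(classify_regulation(NA_real_, 0.01, th), "ns")
  expect_error(gsea_thresholds(nes_up_min = -1), "nes_up_min")
})

test_that("run_gsea recovers a strongly planted set and reports its members", {
  sim <- simulate_expression(400, 10, 10, 30, 2, 1, seed = 31)
  gs <- list(PLANTED = gene_set("PLANTED", sim$truth$planted_set),
             RANDOM = gene_set("RANDOM",
                               sample(rownames(sim$dataset$values), 30)))
  res <- run_gsea(sim$dataset, gs, n_perm = 200, seed = 32)
  planted_row <- res[res$set == "PLANTED", ]
  expect_identical(planted_row$direction, "up")
  le <- strsplit(planted_row$leading_edge, ",")[[1]]
  expect_true(all(le %in% sim$truth$planted_set))
  expect_gt(length(le), 0)
  # leading edge members sit at or before the running-sum peak
  ranked <- attr(res, "ranked")
  expect_true(all(match(le, ranked$genes) <= planted_row$peak_index + 1L))
})
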