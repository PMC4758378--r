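star_edges <- data.frame(
  geneA = c("SEED1", "SEED1", "SEED1", "SEED1", "SEED1"),
  geneB = paste0("N", 1:5),
  stringsAsFactors = FALSE)

test_that("interactome is the 1-hop closure of the seeds", {
  net <- build_interactome(star_edges, "SEED1")
  expect_identical(length(net$nodes), 6L)
  expect_identical(as.integer(igraph::ecount(net$graph)), 5L)
  expect_error(build_interactome(star_edges, "ABSENT"), "no seed present")
  expect_error(build_interactome(star_edges, character()), "non-empty")

  # toy graph with 2 seeds: node set equals a brute-force depth-1 BFS
  set.seed(81)
  nodes <- sprintf("V%02d", 1:20)
  edges <- data.frame(geneA = sample(nodes, 40, replace = TRUE),
                      geneB = sample(nodes, 40, replace = TRUE),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$geneA != edges$geneB, ]
  seeds <- c("V01", "V02")
  net <- build_interactome(edges, seeds)
  closure <- unique(c(seeds,
                      edges$geneB[edges$geneA %in% seeds],
                      edges$geneA[edges$geneB %in% seeds]))
  expect_setequal(net$nodes, intersect(closure,
                                       c(edges$geneA, edges$geneB)))
})

test_that("rebuilding from exported edges reproduces the network", {
  set.seed(82)
  sim <- simulate_network(80, 200, planted_apoptosis_overlap = 10,
                          planted_htt_overlap = 3, seed = 83)
  net <- build_interactome(sim$edges, sim$seeds)
  sif <- withr::local_tempfile(fileext = ".sif")
  edges_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, sif_path = sif, edges_path = edges_tsv)
  rebuilt <- build_interactome(utils::read.delim(edges_tsv), net$seeds)
  expect_setequal(rebuilt$nodes, net$nodes)
  expect_identical(igraph::ecount(rebuilt$graph), igraph::ecount(net$graph))
  # SIF rows mirror the edge list
  expect_identical(length(readLines(sif)),
                   as.integer(igraph::ecount(net$graph)))
})

test_that("annotation overlays equal brute-force set intersections", {
  net <- build_interactome(star_edges, "SEED1")
  expect_identical(overlay_annotation(net, c("X", "Y"))$count, 0L)
  expect_identical(overlay_annotation(net, net$nodes)$count, 6L)
  set.seed(84)
  for (i in 1:20) {
    ann <- sample(c(net$nodes, sprintf("Z%02d", 1:10)), 8)
    expect_identical(overlay_annotation(net, ann)$count,
                     length(intersect(net$nodes, ann)))
  }
})

test_that("cross-annotation carries interaction types and planted counts", {
  sim <- simulate_network(250, 1500, planted_apoptosis_overlap = 40,
                          planted_htt_overlap = 6, seed = 85)
  net <- build_interactome(sim$edges, sim$seeds)
  expect_identical(overlay_annotation(net, sim$apoptosis)$count, 40L)
  cross <- cross_annotation(net, sim$apoptosis, sim$htt_interactors)
  expect_identical(nrow(cross), 6L)
  expect_identical(unname(attr(cross, "type_counts")[["direct"]]), 2L)
  # empty first annotation -> empty result
  empty <- cross_annotation(net, character(), sim$htt_interactors)
  expect_identical(nrow(empty), 0L)
  # all-direct typing propagates
  all_direct <- data.frame(gene = net$nodes[1:3], type = "direct")
  res <- cross_annotation(net, net$nodes, all_direct)
  expect_true(all(res$type == "direct"))
  conflict <- data.frame(gene = c("N1", "N1"),
                         type = c("direct", "indirect"))
  expect_error(cross_annotation(net, net$nodes, conflict), "conflicting")
})

test_that("tri-set prioritization emits one record per three-way member", {
  expect_identical(nrow(triset_prioritize(
    c("A", "B"), c("C", "D"),
    data.frame(gene = c("E", "F"), type = "direct"))), 0L)
  res <- triset_prioritize(c("A", "B", "C"), c("B", "C", "D"),
                           data.frame(gene = c("C", "E"),
                                      type = c("indirect", "direct")))
  expect_identical(res$gene, "C")
  expect_identical(res$htt_interaction, "indirect")
  # adding one gene to all three lists adds exactly one record
  res2 <- triset_prioritize(c("A", "B", "C", "Z"), c("B", "C", "D", "Z"),
                            data.frame(gene = c("C", "E", "Z"),
                                       type = c("indirect", "direct",
                                                "direct")))
  expect_identical(nrow(res2), nrow(res) + 1L)
  expect_true(all(res2$gene %in% c("A", "B", "C", "Z")))
})

test_that("fixture join reproduces the printed prioritization row counts", {
  t3 <- read_prioritization_table()
  # membership lists derived from the fixture's own columns
  diff_upr <- t3$gene
  hdtt <- t3$gene
  htt_int <- data.frame(gene = t3$gene,
                        type = t3$interaction_type,
                        stringsAsFactors = FALSE)
  motif_tab <- data.frame(gene = t3$gene, UPRE = t3$upre,
                          `ERSE-I` = t3$erse1, `ERSE-II` = t3$erse2,
                          check.names = FALSE)
  corr <- data.frame(gene = t3$gene, rho = t3$rho,
                     fdr_pos = ifelse(t3$rho >= 0, t3$fdr_cor, 1),
                     fdr_neg = ifelse(t3$rho < 0, t3$fdr_cor, 1),
                     stringsAsFactors = FALSE)
  res <- triset_prioritize(diff_upr, hdtt, htt_int,
                           motif_table = motif_tab, corr_records = corr)
  expect_identical(nrow(res), 13L)
  expect_identical(sum(res$htt_interaction == "direct"), 2L)
  expect_identical(sum(res$upre | res$erse1 | res$erse2), 8L)
  expect_identical(sum(res$fdr_cor < 0.01), 9L)
  # sorted by correlation significance, then gene
  expect_true(all(diff(res$fdr_cor) >= -1e-12))
})
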