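test_that("consensus patterns compile to the documented widths and matches", {
  pats <- upr_motifs()
  expect_identical(pats$UPRE$width, 8L)
  expect_identical(pats$`ERSE-I`$width, 19L)
  expect_identical(pats$`ERSE-II`$width, 11L)
  # UPRE accepts the G and A variants, rejects others
  expect_identical(nrow(scan_promoter("TGACGTGG", pats$UPRE,
                                      strands = "forward",
                                      window = c(0, 8))), 1L)
  expect_identical(nrow(scan_promoter("TGACGTGA", pats$UPRE,
                                      strands = "forward",
                                      window = c(0, 8))), 1L)
  expect_identical(nrow(scan_promoter("TGACGTGC", pats$UPRE,
                                      strands = "forward",
                                      window = c(0, 8))), 0L)
  # ERSE-I: CCAAT + any 9 nt + CCACG
  seq1 <- paste0("CCAAT", "ACGTACGTA", "CCACG")
  expect_identical(nrow(scan_promoter(seq1, pats$`ERSE-I`,
                                      strands = "forward",
                                      window = c(0, 19))), 1L)
  expect_error(compile_pattern("TGAXGTG"), "unknown consensus symbol")
})

test_that("promoter scanning honours strand, offsets and masked bases", {
  pats <- upr_motifs()
  h <- scan_promoter("AATGACGTGGCC", pats$UPRE, window = c(0, 12))
  expect_identical(h$offset, 2L)
  expect_identical(h$strand, "+")
  expect_identical(h$match, "TGACGTGG")
  # reverse-complement spelling is found only with strands = both,
  # reported at the forward coordinate of the match start
  rc <- scan_promoter("CCACGTCATT", pats$UPRE, strands = "both",
                      window = c(0, 10))
  expect_identical(nrow(rc), 1L)
  expect_identical(rc$strand, "-")
  expect_identical(rc$offset, 0L)
  expect_identical(nrow(scan_promoter("CCACGTCATT", pats$UPRE,
                                      strands = "forward",
                                      window = c(0, 10))), 0L)
  # sequence letter N never matches, even against the degenerate position
  expect_identical(nrow(scan_promoter("AATGACGTGNCC", pats$UPRE,
                                      window = c(0, 12))), 0L)
  # offsets are TSS-relative in the default window
  h2 <- scan_promoter(paste0(strrep("A", 1000), "TGACGTGG",
                             strrep("A", 492)), pats$UPRE)
  expect_identical(h2$offset[h2$strand == "+"], 0L)
})

test_that("scanner equals the naive position-by-position oracle", {
  set.seed(51)
  pats <- upr_motifs()
  for (i in 1:100) {
    pat <- pats[[sample(3, 1)]]
    # short sequences seeded with occasional planted instances and Ns
    seq <- random_dna(sample(40:80, 1))
    if (stats::runif(1) < 0.5) {
      inst <- gsub("R", sample(c("G", "A"), 1),
                   gsub("N", "C", pat$expanded))
      pos <- sample(nchar(seq) - pat$width + 1L, 1)
      substr(seq, pos, pos + pat$width - 1L) <- inst
    }
    if (stats::runif(1) < 0.3) {
      pos <- sample(nchar(seq), 1)
      substr(seq, pos, pos) <- "N"
    }
    got <- scan_promoter(seq, pat, strands = "both",
                         window = c(0, nchar(seq)))
    want <- oracle_scan(seq, pat$expanded, both_strands = TRUE)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      got_key <- sort(paste(got$offset + 1L, got$strand))
      want_key <- sort(paste(want$start, want$strand))
      expect_identical(got_key, want_key)
    }
  }
})

test_that("total hit count is invariant under reverse complementation", {
  set.seed(52)
  pats <- upr_motifs()
  for (i in 1:20) {
    seq <- random_dna(60)
    inst <- gsub("R", "G", gsub("N", "T", pats$UPRE$expanded))
    substr(seq, 10, 17) <- inst
    n_fwd <- nrow(scan_promoter(seq, pats$UPRE, strands = "both",
                                window = c(0, 60)))
    n_rc <- nrow(scan_promoter(revcomp(seq), pats$UPRE, strands = "both",
                               window = c(0, 60)))
    expect_identical(n_fwd, n_rc)
  }
})

test_that("presence semantics count each gene once per pattern", {
  pr <- simulate_promoters(15, motif_rates = c(UPRE = 1), seed = 53)
  tab <- presence_table(pr$sequences, window = pr$window)
  expect_true(all(tab$UPRE))
  expect_true(all(tab$UPRE_count >= 1L))
  dup <- stats::setNames(pr$sequences[c(1, 1)], c("PA", "PA"))
  expect_error(presence_table(dup), "unique")
})

test_that("shipped prioritization fixture reproduces the printed motif tallies", {
  t3 <- read_prioritization_table()
  expect_identical(nrow(t3), 13L)
  # eight genes carry at least one stress-response element
  expect_identical(sum(t3$upre | t3$erse1 | t3$erse2), 8L)
  # six genes carry both UPRE and ERSE-I
  both <- t3$gene[t3$upre & t3$erse1]
  expect_setequal(both, c("RAB5A", "HMGB1", "DNM1", "TCP1", "TUBB",
                          "TSG101"))
})

test_that("combination counts use at-least-these semantics", {
  tab <- data.frame(gene = c("A", "B", "C"),
                    UPRE = c(TRUE, FALSE, TRUE),
                    `ERSE-I` = c(TRUE, TRUE, TRUE),
                    `ERSE-II` = c(FALSE, FALSE, TRUE),
                    check.names = FALSE)
  cc <- combination_counts(tab, patterns = c("UPRE", "ERSE-I", "ERSE-II"))
  expect_identical(unname(cc[["UPRE&ERSE-I"]]), 2L)
  expect_identical(unname(cc[["UPRE&ERSE-I&ERSE-II"]]), 1L)
  expect_identical(unname(cc[["any"]]), 3L)
  expect_identical(unname(cc[["none"]]), 0L)
  # only-UPRE genes contribute to no pairwise combination
  solo <- data.frame(gene = c("A", "B"), UPRE = c(TRUE, TRUE),
                     `ERSE-I` = c(FALSE, FALSE), check.names = FALSE)
  cc2 <- combination_counts(solo, patterns = c("UPRE", "ERSE-I"))
  expect_identical(unname(cc2[["UPRE"]]), 2L)
  expect_identical(unname(cc2[["UPRE&ERSE-I"]]), 0L)
  # empty table: error-free all-zero output
  empty <- tab[0, ]
  cc3 <- combination_counts(empty, patterns = c("UPRE", "ERSE-I", "ERSE-II"))
  expect_true(all(cc3 == 0L))
})
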