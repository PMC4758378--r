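#' Rank genes by a differential-expression metric
#'
#' The default metric is signal-to-noise, `(mu_case - mu_ctrl) /
#' (s_case + s_ctrl)` with each group standard deviation floored at
#' `0.2 * |mu|` of its group (the floor keeps low-variance genes from
#' dominating). Signal-to-noise needs at least 3 samples per group; with
#' fewer the metric falls back to `log2fc` (difference of group means, on
#' the assumed log-like scale). Ties are broken lexicographically by gene
#' symbol so the ordering is fully deterministic.
#'
#' @param dataset An `ExpressionDataset`.
#' @param metric `"signal2noise"` or `"log2fc"`.
#' @return Object of class `RankedList`: list with `genes` (best-to-worst),
#'   `scores` (same order, descending) and `metric`.
#' @export
rank_genes <- function(dataset, metric = c("signal2noise", "log2fc")) {
  metric <- match.arg(metric)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  case <- dataset$values[, dataset$phenotype == "case", drop = FALSE]
  ctrl <- dataset$values[, dataset$phenotype == "control", drop = FALSE]
  if (ncol(case) < 1L || ncol(ctrl) < 1L) stop("need >= 1 sample per group")
  if (metric == "signal2noise" && (ncol(case) < 3L || ncol(ctrl) < 3L)) {
    metric <- "log2fc"
  }
  scores <- if (metric == "signal2noise") {
    signal2noise_scores(case, ctrl)
  } else {
    rowMeans(case) - rowMeans(ctrl)
  }
  ord <- order(-scores, rownames(dataset$values), method = "radix")
  structure(
    list(genes = rownames(dataset$values)[ord],
         scores = unname(scores[ord]), metric = metric),
    class = "RankedList"
  )
}

# Vectorized signal-to-noise with the 0.2*|mu| variance floor per group.
signal2noise_scores <- function(case, ctrl) {
  m1 <- rowMeans(case); m0 <- rowMeans(ctrl)
  s1 <- sqrt(rowSums((case - m1)^2) / (ncol(case) - 1L))
  s0 <- sqrt(rowSums((ctrl - m0)^2) / (ncol(ctrl) - 1L))
  s1 <- pmax(s1, 0.2 * abs(m1))
  s0 <- pmax(s0, 0.2 * abs(m0))
  (m1 - m0) / (s1 + s0)
}

#' @export
print.RankedList <- function(x, ...) {
  cat("RankedList of", length(x$genes), "genes by", x$metric, "\n")
  invisible(x)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list best-to-worst. At a gene in the set ("hit") the
#' running sum rises by `|score|^p / sum over hits of |score|^p`; at a miss
#' it falls by `1/(N - N_hits)`. The enrichment score is the running-sum
#' value of maximal absolute deviation from zero; its sign says whether the
#' set concentrates at the top (up) or bottom (down) of the ranking.
#'
#' @param ranked A `RankedList`.
#' @param set A `GeneSet` or character vector of symbols.
#' @param p Weight exponent on the metric (default 1, classic weighting).
#' @param min_set_size Minimum size of `set` intersected with the ranking.
#' @return List with `ES` in `[-1, 1]`, `peak_index` (0-based rank of the
#'   extreme deviation) and `running_sum` (length N numeric).
#' @export
enrichment_score <- function(ranked, set, p = 1, min_set_size = 5) {
  members <- if (inherits(set, "GeneSet")) set$members else
    unique(toupper(set))
  hit <- ranked$genes %in% members
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set not represented in the ranked list")
  if (n_hit < min_set_size) {
    stop("gene set intersection (", n_hit, ") below min_set_size (",
         min_set_size, ")")
  }
  n <- length(ranked$genes)
  w <- abs(ranked$scores)^p
  steps <- numeric(n)
  if (n_hit == n) {
    steps <- w / sum(w)             # no miss steps: running sum peaks at 1
  } else {
    steps[hit] <- w[hit] / sum(w[hit])
    steps[!hit] <- -1 / (n - n_hit)
  }
  rs <- cumsum(steps)
  peak <- which.max(abs(rs))
  list(ES = rs[[peak]], peak_index = peak - 1L, running_sum = rs)
}

#' Permutation null distribution of the enrichment score
#'
#' `phenotype` mode permutes the sample labels and re-ranks the whole
#' dataset for every permutation — the stricter null, preserving gene-gene
#' correlation; it needs enough samples to give distinct label assignments.
#' `gene_set` mode keeps the observed ranking fixed and scores random gene
#' sets of the same size.
#'
#' @param dataset An `ExpressionDataset` (used by `phenotype` mode; may be
#'   `NULL` for `gene_set` mode).
#' @param set Gene set (as in [enrichment_score()]).
#' @param ranked The observed `RankedList` (required for `gene_set` mode and
#'   to fix the metric).
#' @param mode `"phenotype"` or `"gene_set"`.
#' @param n_perm Number of permutations (>= 10; < 100 draws a warning).
#' @param seed Integer seed.
#' @param p Weight exponent.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(dataset, set, ranked, mode = c("phenotype",
                             "gene_set"), n_perm = 1000, seed, p = 1) {
  mode <- match.arg(mode)
  if (n_perm < 10) stop("n_perm < 10 gives no usable null")
  if (n_perm < 100) warning("n_perm < 100: null distribution will be coarse")
  members <- if (inherits(set, "GeneSet")) set$members else
    unique(toupper(set))
  set.seed(seed)
  if (mode == "gene_set") {
    n_hit <- sum(ranked$genes %in% members)
    vapply(seq_len(n_perm), function(i) {
      rnd <- sample(ranked$genes, n_hit)
      enrichment_score(ranked, rnd, p = p, min_set_size = 1)$ES
    }, numeric(1))
  } else {
    stopifnot(inherits(dataset, "ExpressionDataset"))
    labels <- dataset$phenotype
    metric <- ranked$metric
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(labels)
      ds <- dataset
      ds$phenotype <- perm
      rl <- rank_genes(ds, metric = metric)
      enrichment_score(rl, members, p = p, min_set_size = 1)$ES
    }, numeric(1))
  }
}

#' Normalize an enrichment score and compute permutation p and FDR
#'
#' NES divides the ES by the mean magnitude of same-sign null scores;
#' `p_perm` is the add-one-smoothed fraction of same-sign null scores at
#' least as extreme. The FDR compares the pooled null NES tail fraction to
#' the observed NES tail fraction (the cited enrichment method's empirical
#' FDR), clamped to `[0, 1]`. When a run tests a single set the pooled
#' null defaults to that set's own null.
#'
#' @param es Observed enrichment score.
#' @param null_es Null ES sample for this set.
#' @param pooled_null_nes Optional pooled null NES across all sets in the
#'   run (defaults to this set's normalized null).
#' @param observed_nes Optional vector of all observed NES in the run
#'   (defaults to the single NES computed here).
#' @return List with `NES`, `p_perm`, `fdr` and logical `flagged` (`TRUE`
#'   when no same-sign null value exists, in which case `NES` is `NA`).
#' @export
normalize_and_test <- function(es, null_es, pooled_null_nes = NULL,
                               observed_nes = NULL) {
  same <- null_es[sign(null_es) == sign(es) & null_es != 0]
  if (es == 0 || length(same) == 0L) {
    return(list(NES = NA_real_, p_perm = NA_real_, fdr = NA_real_,
                flagged = TRUE))
  }
  nes <- es / mean(abs(same))
  p_perm <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  if (is.null(pooled_null_nes)) {
    pooled_null_nes <- null_es / mean(abs(same))
  }
  if (is.null(observed_nes)) observed_nes <- nes
  null_same <- pooled_null_nes[sign(pooled_null_nes) == sign(nes)]
  obs_same <- observed_nes[sign(observed_nes) == sign(nes)]
  null_tail <- if (length(null_same)) mean(abs(null_same) >= abs(nes)) else 0
  obs_tail <- mean(abs(obs_same) >= abs(nes))
  fdr <- if (obs_tail == 0) 0 else min(1, null_tail / obs_tail)
  list(NES = nes, p_perm = p_perm, fdr = fdr, flagged = FALSE)
}

#' Leading-edge ("core enrichment") subset of a gene set
#'
#' For a positive ES the leading edge is the set members at ranks up to and
#' including the running-sum peak; for a negative ES, the members at ranks
#' at or after the peak. These are the genes that drive the enrichment
#' signal.
#'
#' @param ranked A `RankedList`.
#' @param set Gene set (as in [enrichment_score()]).
#' @param es Observed enrichment score (non-zero).
#' @param peak_index 0-based peak position from [enrichment_score()].
#' @return Character vector of leading-edge genes, in rank order.
#' @export
leading_edge <- function(ranked, set, es, peak_index) {
  if (es == 0) stop("leading edge undefined for ES = 0")
  members <- if (inherits(set, "GeneSet")) set$members else
    unique(toupper(set))
  idx <- which(ranked$genes %in% members)   # 1-based ranks of the hits
  keep <- if (es > 0) idx <= peak_index + 1L else idx >= peak_index + 1L
  ranked$genes[idx[keep]]
}

#' Significance thresholds for calling a comparison up or down
#'
#' Defaults follow the convention used throughout this pipeline: a gene set
#' is called up in a comparison when `fdr <= 0.05` and `NES >= +1.4`, down
#' when `fdr <= 0.05` and `NES <= -1.4`.
#'
#' @param fdr_max FDR ceiling.
#' @param nes_up_min Minimum NES to call upregulation (positive).
#' @param nes_down_max Maximum NES to call downregulation (negative).
#' @return List of class `Thresholds`.
#' @export
gsea_thresholds <- function(fdr_max = 0.05, nes_up_min = 1.4,
                            nes_down_max = -1.4) {
  stopifnot(nes_up_min > 0, nes_down_max < 0)
  structure(list(fdr_max = fdr_max, nes_up_min = nes_up_min,
                 nes_down_max = nes_down_max), class = "Thresholds")
}

#' Classify a comparison as up, down or not significant
#'
#' @param nes Normalized enrichment score (may be `NA` for flagged results).
#' @param fdr Empirical FDR.
#' @param thresholds A [gsea_thresholds()] object.
#' @return `"up"`, `"down"` or `"ns"`.
#' @export
classify_regulation <- function(nes, fdr, thresholds = gsea_thresholds()) {
  if (is.na(nes) || is.na(fdr)) return("ns")
  if (fdr <= thresholds$fdr_max && nes >= thresholds$nes_up_min) return("up")
  if (fdr <= thresholds$fdr_max && nes <= thresholds$nes_down_max) return("down")
  "ns"
}

#' Run gene-set enrichment analysis over a collection of sets
#'
#' Ranks the dataset, scores every sufficiently represented set, builds a
#' permutation null per set (phenotype permutation when both groups have at
#' least 7 samples, otherwise random same-size gene sets), normalizes, and
#' computes the empirical FDR from the null NES pooled across all tested
#' sets.
#'
#' @param dataset An `ExpressionDataset`.
#' @param gene_sets Named list of `GeneSet` objects (e.g. [read_gmt()]).
#' @param metric Ranking metric, see [rank_genes()].
#' @param n_perm Permutations per set.
#' @param seed Integer seed.
#' @param mode `"auto"` (sample-size rule above), `"phenotype"` or
#'   `"gene_set"`.
#' @param min_set_size Minimum represented set size.
#' @param thresholds A [gsea_thresholds()] object.
#' @param p Weight exponent.
#' @return Data frame of class `EnrichmentResult` with one row per set:
#'   `set`, `size`, `ES`, `peak_index`, `NES`, `p_perm`, `fdr`,
#'   `direction`, `leading_edge` (comma-joined); attribute `ranked` holds
#'   the ranking used.
#' @export
run_gsea <- function(dataset, gene_sets, metric = "signal2noise",
                     n_perm = 1000, seed, mode = c("auto", "phenotype",
                     "gene_set"), min_set_size = 5,
                     thresholds = gsea_thresholds(), p = 1) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    n_case <- sum(dataset$phenotype == "case")
    n_ctrl <- sum(dataset$phenotype == "control")
    mode <- if (n_case >= 7 && n_ctrl >= 7) "phenotype" else "gene_set"
  }
  ranked <- rank_genes(dataset, metric = metric)
  keep <- vapply(gene_sets, function(s) {
    m <- if (inherits(s, "GeneSet")) s$members else unique(toupper(s))
    sum(ranked$genes %in% m) >= min_set_size
  }, logical(1))
  gene_sets <- gene_sets[keep]
  if (length(gene_sets) == 0L) stop("no gene set passes min_set_size")
  scored <- lapply(gene_sets, function(s)
    enrichment_score(ranked, s, p = p, min_set_size = min_set_size))
  nulls <- lapply(seq_along(gene_sets), function(i)
    permutation_null(dataset, gene_sets[[i]], ranked, mode = mode,
                     n_perm = n_perm, seed = seed + i, p = p))
  # first pass: per-set NES and normalized nulls
  norm1 <- lapply(seq_along(gene_sets), function(i)
    normalize_and_test(scored[[i]]$ES, nulls[[i]]))
  obs_nes <- vapply(norm1, function(x) x$NES %||% NA_real_, numeric(1))
  pooled <- unlist(lapply(seq_along(gene_sets), function(i) {
    same_pos <- nulls[[i]][nulls[[i]] > 0]
    same_neg <- nulls[[i]][nulls[[i]] < 0]
    c(if (length(same_pos)) same_pos / mean(same_pos),
      if (length(same_neg)) same_neg / mean(abs(same_neg)))
  }))
  rows <- lapply(seq_along(gene_sets), function(i) {
    res <- normalize_and_test(scored[[i]]$ES, nulls[[i]],
                              pooled_null_nes = pooled,
                              observed_nes = obs_nes[!is.na(obs_nes)])
    dir <- classify_regulation(res$NES, res$fdr, thresholds)
    le <- if (!res$flagged && scored[[i]]$ES != 0) {
      leading_edge(ranked, gene_sets[[i]], scored[[i]]$ES,
                   scored[[i]]$peak_index)
    } else character()
    m <- if (inherits(gene_sets[[i]], "GeneSet")) gene_sets[[i]]$members
         else unique(toupper(gene_sets[[i]]))
    data.frame(set = names(gene_sets)[[i]],
               size = sum(ranked$genes %in% m),
               ES = scored[[i]]$ES, peak_index = scored[[i]]$peak_index,
               NES = res$NES, p_perm = res$p_perm, fdr = res$fdr,
               direction = dir,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ranked") <- ranked
  class(out) <- c("EnrichmentResult", class(out))
  out
}
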