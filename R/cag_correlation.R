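#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Returns
#' `NA` when either vector has zero variance; callers flag such records
#' rather than propagating silent NaN.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y))
}

#' Per-gene Spearman correlation with CAG repeat number, permutation FDR
#'
#' For every gene, correlates FPKM with CAG repeat number, then estimates
#' tail-specific empirical FDRs by permutation: the CAG labels are permuted
#' independently and repeatedly for each gene, and for a threshold `t > 0`
#' the positive-tail FDR is the mean number of null correlations `>= t`
#' per permutation round divided by the number of observed correlations
#' `>= t` (mirrored with `<= -t` for the negative tail), clamped to
#' `[0, 1]`. Each gene's FDR is the estimate at `t = |rho|`, monotonized so
#' the FDR is non-increasing in `|rho|` (a gene can never have a larger FDR
#' than a less-correlated gene in the same tail). Genes with zero FPKM
#' variance have undefined correlation; they are excluded from both the
#' observed and the null tallies and flagged.
#'
#' @param series A `CAGSeries` (list with `fpkm` genes x samples matrix and
#'   per-sample `cag` numbers), e.g. from [simulate_cag_series()].
#' @param n_perm Permutation rounds per gene (>= 100).
#' @param seed Integer seed.
#' @param fdr_threshold Significance cutoff on the empirical FDR
#'   (default 0.01).
#' @return Data frame of class `CorrelationRecord` with one row per gene:
#'   `gene`, `rho`, `fdr_pos`, `fdr_neg`, `significant_pos`,
#'   `significant_neg`, `flagged` (zero-variance records).
#' @export
permutation_fdr <- function(series, n_perm = 1000, seed,
                            fdr_threshold = 0.01) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  fpkm <- series$fpkm
  cag <- series$cag
  m <- length(cag)
  stopifnot(ncol(fpkm) == m)
  set.seed(seed)
  cag_rank <- rank(cag)
  zc <- (cag_rank - mean(cag_rank))
  zc <- zc / sqrt(sum(zc^2))
  gene_ranks <- t(apply(fpkm, 1L, rank))
  var_ok <- apply(fpkm, 1L, function(v) stats::sd(v) > 0)
  gz <- gene_ranks - rowMeans(gene_ranks)
  norms <- sqrt(rowSums(gz^2))
  rho <- rep(NA_real_, nrow(fpkm))
  rho[var_ok] <- (gz[var_ok, , drop = FALSE] %*% zc) / norms[var_ok]
  # null: per gene, n_perm independent permutations of the CAG labels
  idx_ok <- which(var_ok)
  null_rho <- matrix(NA_real_, nrow = length(idx_ok), ncol = n_perm)
  for (j in seq_along(idx_ok)) {
    g <- idx_ok[[j]]
    zg <- gz[g, ] / norms[[g]]
    perms <- vapply(seq_len(n_perm), function(i) sample.int(m), integer(m))
    null_rho[j, ] <- crossprod(matrix(zc[perms], nrow = m), zg)
  }
  fdr_pos <- rep(1, nrow(fpkm))
  fdr_neg <- rep(1, nrow(fpkm))
  obs <- rho[var_ok]
  if (length(obs)) {
    pos_idx <- which(var_ok)[obs > 0]
    if (length(pos_idx)) {
      t_pos <- rho[pos_idx]
      raw <- vapply(t_pos, function(t) {
        o <- sum(obs >= t)
        if (o == 0) return(1)
        min(1, sum(null_rho >= t, na.rm = TRUE) / n_perm / o)
      }, numeric(1))
      fdr_pos[pos_idx] <- monotonize_fdr(t_pos, raw)
    }
    neg_idx <- which(var_ok)[obs < 0]
    if (length(neg_idx)) {
      t_neg <- rho[neg_idx]
      raw <- vapply(t_neg, function(t) {
        o <- sum(obs <= t)
        if (o == 0) return(1)
        min(1, sum(null_rho <= t, na.rm = TRUE) / n_perm / o)
      }, numeric(1))
      fdr_neg[neg_idx] <- monotonize_fdr(-t_neg, raw)
    }
  }
  out <- data.frame(
    gene = rownames(fpkm), rho = rho,
    fdr_pos = fdr_pos, fdr_neg = fdr_neg,
    significant_pos = !is.na(rho) & rho > 0 & fdr_pos < fdr_threshold,
    significant_neg = !is.na(rho) & rho < 0 & fdr_neg < fdr_threshold,
    flagged = !var_ok,
    row.names = NULL, stringsAsFactors = FALSE)
  if (any(!var_ok)) {
    message(sum(!var_ok), " gene(s) with zero FPKM variance excluded from ",
            "observed and null tallies")
  }
  class(out) <- c("CorrelationRecord", class(out))
  out
}

# q_i = min over thresholds no more stringent than |rho_i| of the raw FDR:
# genes sorted by decreasing stringency take the suffix minimum.
monotonize_fdr <- function(stringency, raw) {
  ord <- order(-stringency)
  q <- raw[ord]
  q <- rev(cummin(rev(q)))
  out <- numeric(length(raw))
  out[ord] <- q
  out
}

#' Over-representation of a gene set among significantly correlated genes
#'
#' One-sided Fisher test (greater) on the 2x2 table of in/out of the
#' significant list against in/out of the target set, over a stated
#' universe.
#'
#' @param significant Character vector of significantly correlated genes.
#' @param target A `GeneSet` or character vector (e.g. the UPR genes).
#' @param universe Character vector of all genes tested.
#' @return List with the 2x2 cell counts and `p`.
#' @export
set_overrepresentation <- function(significant, target, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("empty universe")
  significant <- intersect(unique(toupper(significant)), universe)
  members <- if (inherits(target, "GeneSet")) target$members else
    unique(toupper(target))
  members <- intersect(members, universe)
  a <- length(intersect(significant, members))
  b <- length(significant) - a
  c <- length(members) - a
  d <- length(universe) - a - b - c
  list(a = a, b = b, c = c, d = d,
       p = fisher_exact_2x2(a, b, c, d, alternative = "greater"))
}

#' Expected-by-chance overlap of a gene list with the correlated fraction
#'
#' Under independence, a list of `set_size` genes is expected to contain
#' `set_size * genomewide_fraction` significantly correlated genes; the
#' value is reported to one decimal.
#'
#' @param set_size Size of the gene list.
#' @param genomewide_fraction Fraction of all genes called significantly
#'   correlated (in `[0, 1]`).
#' @return Expected count, rounded to one decimal.
#' @export
expected_overlap <- function(set_size, genomewide_fraction) {
  if (genomewide_fraction < 0 || genomewide_fraction > 1) {
    stop("fraction must lie in [0, 1]")
  }
  round(set_size * genomewide_fraction, 1)
}
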