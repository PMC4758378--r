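#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` that contains `K` genes with the property, the
#' probability of seeing `k` or more with it. Computed on the log scale
#' internally (via the stable base distribution function).
#'
#' @param k Observed hits in the list.
#' @param K Property size in the universe.
#' @param n List size.
#' @param N Universe size.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n)) {
    stop("invalid hypergeometric parameters: k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Fisher's exact test on a 2x2 table
#'
#' Rows index in/out of the gene list, columns with/without the property.
#' `greater` is the hypergeometric upper tail on cell `a` given the
#' margins; `two_sided` sums the probabilities of all tables (with the same
#' margins) no more probable than the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts (`a` = in-list
#'   with-property).
#' @param alternative `"greater"` or `"two_sided"`.
#' @return P-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("empty table")
  K <- a + b        # row-1 margin: list size
  n <- a + c        # col-1 margin: property size
  N <- a + b + c + d
  if (alternative == "greater") {
    return(hypergeom_tail(a, K, n, N))
  }
  lo <- max(0L, K + n - N)
  hi <- min(K, n)
  probs <- stats::dhyper(lo:hi, K, N - K, n)
  obs <- stats::dhyper(a, K, N - K, n)
  # relative tolerance guards against ties broken by floating-point noise
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= i} (p_(j) * m / j)` over ascending p-values, clamped at
#' 1 and returned in input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values (same length/order).
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Over-representation analysis against flat term annotations
#'
#' One hypergeometric upper-tail test per term, Benjamini-Hochberg across
#' all tested terms. Genes in `list` that are outside the universe are
#' dropped with a warning; term memberships are intersected with the
#' universe before testing.
#'
#' @param list Character vector of query gene symbols.
#' @param annotations Named list: term -> character vector of member
#'   symbols (`GeneSet` objects accepted), e.g. from [read_gmt()].
#' @param universe Character vector of background gene symbols.
#' @param min_term_size Terms with fewer in-universe members are skipped.
#' @return Data frame sorted by `fdr`: `term`, `k` (hits in list), `K`
#'   (term size in universe), `n` (list size), `N` (universe size), `p`,
#'   `fdr`, `significant` (`fdr <= 0.05`).
#' @export
ora <- function(list, annotations, universe, min_term_size = 1) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("empty universe")
  list <- unique(toupper(list))
  outside <- setdiff(list, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    list <- intersect(list, universe)
  }
  members <- lapply(annotations, function(s) {
    m <- if (inherits(s, "GeneSet")) s$members else unique(toupper(s))
    intersect(m, universe)
  })
  keep <- vapply(members, length, integer(1)) >= min_term_size
  members <- members[keep]
  if (length(members) == 0L) stop("no term intersects the universe")
  n <- length(list)
  N <- length(universe)
  k <- vapply(members, function(m) length(intersect(m, list)), integer(1))
  K <- vapply(members, length, integer(1))
  p <- vapply(seq_along(members), function(i)
    hypergeom_tail(k[[i]], K[[i]], n, N), numeric(1))
  fdr <- bh_adjust(p)
  out <- data.frame(term = names(members), k = k, K = K, n = n, N = N,
                    p = p, fdr = fdr, significant = fdr <= 0.05,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$fdr, out$p, out$term), , drop = FALSE]
}

#' Motif enrichment of a target gene list against a promoter universe
#'
#' For each pattern, tests whether presence calls are over-represented in
#' the target genes relative to all promoters supplied (hypergeometric
#' upper tail, the natural background being every promoter scanned).
#' Target genes without a promoter record are excluded from both sides of
#' the test and reported.
#'
#' @param presence A `MotifHitTable` (presence over the promoter universe).
#' @param targets Character vector of target gene symbols.
#' @param patterns Presence column names (default: logical columns).
#' @return Data frame: `pattern`, `k`, `K`, `n`, `N`, `p`, `fdr`;
#'   attribute `excluded_targets` lists targets lacking promoters.
#' @export
motif_enrichment <- function(presence, targets, patterns = NULL) {
  if (is.null(patterns)) {
    patterns <- names(presence)[vapply(presence, is.logical, logical(1))]
  }
  targets <- unique(toupper(targets))
  excluded <- setdiff(targets, presence$gene)
  if (length(excluded)) {
    warning(length(excluded), " target gene(s) lack promoter records and ",
            "were excluded from the enrichment universe")
  }
  targets <- intersect(targets, presence$gene)
  in_target <- presence$gene %in% targets
  N <- nrow(presence)
  n <- sum(in_target)
  rows <- lapply(patterns, function(pat) {
    K <- sum(presence[[pat]])
    k <- sum(presence[[pat]] & in_target)
    data.frame(pattern = pat, k = k, K = K, n = n, N = N,
               p = hypergeom_tail(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  attr(out, "excluded_targets") <- excluded
  out
}
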