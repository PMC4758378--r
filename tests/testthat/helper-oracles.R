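# Independent brute-force oracles used to validate the fast implementations.
# Each is written from the definition, without reusing package internals.

# Running-sum enrichment score: explicit position-by-position walk.
oracle_es <- function(scores, is_hit, p = 1) {
  n <- length(scores)
  n_hit <- sum(is_hit)
  denom_hit <- sum(abs(scores[is_hit])^p)
  rs <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (is_hit[i]) {
      if (n_hit == n) abs(scores[i])^p / denom_hit else
        abs(scores[i])^p / denom_hit
    } else {
      -1 / (n - n_hit)
    }
    rs[i] <- acc
  }
  peak <- which.max(abs(rs))
  list(ES = rs[peak], peak_index = peak - 1L)
}

# Naive motif scanner: test every position character by character.
# Sequence letter N never matches; R in the pattern matches G or A; N in the
# pattern matches any of ACGT.
oracle_scan <- function(sequence, expanded, both_strands = TRUE) {
  allowed <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("G", "A"), N = c("A", "C", "G", "T"))
  match_at <- function(seq_chars, pat_chars, pos) {
    for (j in seq_along(pat_chars)) {
      s <- seq_chars[pos + j - 1L]
      if (!(s %in% allowed[[pat_chars[j]]])) return(FALSE)
    }
    TRUE
  }
  revcomp_chars <- function(chars) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", N = "N")
    rev(unname(comp[chars]))
  }
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  pat_chars <- strsplit(expanded, "")[[1]]
  w <- length(pat_chars)
  npos <- length(seq_chars) - w + 1L
  hits <- data.frame(start = integer(), strand = character())
  for (pos in seq_len(npos)) {
    if (match_at(seq_chars, pat_chars, pos)) {
      hits <- rbind(hits, data.frame(start = pos, strand = "+"))
    }
  }
  if (both_strands) {
    # reverse-strand hit = forward match of the reverse-complemented pattern
    rc <- revcomp_chars(pat_chars)
    rc_allowed <- list(A = "A", C = "C", G = "G", T = "T",
                       Y = c("C", "T"), N = c("A", "C", "G", "T"))
    match_rc <- function(pos) {
      for (j in seq_along(rc)) {
        s <- seq_chars[pos + j - 1L]
        if (!(s %in% rc_allowed[[rc[j]]])) return(FALSE)
      }
      TRUE
    }
    for (pos in seq_len(npos)) {
      if (match_rc(pos)) {
        hits <- rbind(hits, data.frame(start = pos, strand = "-"))
      }
    }
  }
  hits
}

# Exact hypergeometric upper tail by binomial-coefficient summation.
oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

ranked_list <- function(genes, scores, metric = "test") {
  structure(list(genes = genes, scores = scores, metric = metric),
            class = "RankedList")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
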