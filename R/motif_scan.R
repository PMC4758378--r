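#' Compile a degenerate consensus pattern
#'
#' Accepted alphabet: A, C, G, T, R (= G or A), N (any base), with an
#' optional `{k}` repeat after a symbol (so `CCAATN{9}CCACG` is the
#' 19-nt pattern CCAAT + 9 spacer positions + CCACG). The compiled matcher
#' accepts exactly the strings the consensus denotes, except that the
#' letter N in a *sequence* never matches anything (masked bases must not
#' create hits).
#'
#' @param consensus Consensus string.
#' @param name Pattern name.
#' @return Object of class `MotifPattern`: list with `name`, `consensus`,
#'   `expanded` (one symbol per position) and `width`.
#' @export
compile_pattern <- function(consensus, name = consensus) {
  expanded <- character()
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (!ch %in% c("A", "C", "G", "T", "R", "N")) {
      stop("unknown consensus symbol '", ch, "' in ", consensus)
    }
    reps <- 1L
    if (i < length(chars) && chars[[i + 1L]] == "{") {
      close <- which(chars == "}" & seq_along(chars) > i)[1]
      if (is.na(close)) stop("unclosed {k} repeat in ", consensus)
      reps <- as.integer(paste(chars[(i + 2L):(close - 1L)], collapse = ""))
      i <- close
    }
    expanded <- c(expanded, rep(ch, reps))
    i <- i + 1L
  }
  structure(
    list(name = name, consensus = consensus,
         expanded = paste(expanded, collapse = ""),
         width = length(expanded)),
    class = "MotifPattern"
  )
}

#' The three ER-stress response elements
#'
#' UPRE (unfolded protein response element) TGACGTG(G/A), ERSE-I
#' CCAAT-N9-CCACG and ERSE-II ATTGG-N-CCACG: the promoter elements bound by
#' the UPR transcription factors ATF6 and XBP1.
#'
#' @return Named list of three compiled `MotifPattern` objects
#'   (`UPRE`, `ERSE-I`, `ERSE-II`).
#' @export
upr_motifs <- function() {
  list(
    UPRE = compile_pattern("TGACGTGR", name = "UPRE"),
    `ERSE-I` = compile_pattern("CCAATN{9}CCACG", name = "ERSE-I"),
    `ERSE-II` = compile_pattern("ATTGGNCCACG", name = "ERSE-II")
  )
}

# Degenerate consensus -> IUPAC string understood by Biostrings (R and N are
# already IUPAC; nothing to translate, kept for clarity at call sites).
pattern_to_iupac <- function(pattern) pattern$expanded

#' Scan one promoter window for a pattern
#'
#' Tests every window position; on `strands = "both"` the reverse strand is
#' scanned by matching the reverse-complemented pattern on the forward
#' sequence, and reverse hits are reported at the forward coordinate of the
#' match start. All overlapping occurrences are reported. Positions where
#' the sequence contains N never match.
#'
#' @param sequence Promoter sequence (character, length >= pattern width).
#' @param pattern A `MotifPattern`.
#' @param strands `"both"` or `"forward"`.
#' @param window Integer pair giving the TSS-relative coordinate of the
#'   first base (default `c(-1000, 500)`); offsets are reported relative to
#'   the TSS.
#' @return Data frame with columns `offset` (TSS-relative, 0-based match
#'   start), `strand` and `match` (the matched forward-strand substring).
#' @export
scan_promoter <- function(sequence, pattern, strands = c("both", "forward"),
                          window = c(-1000, 500)) {
  strands <- match.arg(strands)
  window <- as.integer(window)
  sequence <- toupper(sequence)
  if (nchar(sequence) < pattern$width) {
    stop("sequence shorter than pattern width")
  }
  subj <- Biostrings::DNAString(sequence)
  hits_at <- function(iupac) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(iupac), subj,
                                  fixed = "subject")
    starts <- Biostrings::start(m)
    if (length(starts)) {
      frag <- substring(sequence, starts, starts + pattern$width - 1L)
      starts <- starts[!grepl("N", frag, fixed = TRUE)]
    }
    starts
  }
  hit_frame <- function(starts, strand) {
    data.frame(
      offset = starts - 1L + window[1],
      strand = rep(strand, length(starts)),
      match = if (length(starts)) {
        substring(sequence, starts, starts + pattern$width - 1L)
      } else character(),
      stringsAsFactors = FALSE)
  }
  out <- hit_frame(hits_at(pattern_to_iupac(pattern)), "+")
  if (strands == "both") {
    out <- rbind(out, hit_frame(hits_at(revcomp(pattern_to_iupac(pattern))),
                                "-"))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Per-gene motif presence and hit counts
#'
#' A gene is counted once per pattern regardless of hit multiplicity
#' (presence semantics); full per-hit records are retained as an attribute
#' for occurrence-based analyses.
#'
#' @param promoters Named character vector of promoter sequences (names =
#'   gene symbols; duplicates are an error) or the result of
#'   [simulate_promoters()] / [read_promoters_fasta()].
#' @param patterns Named list of `MotifPattern` (default [upr_motifs()]).
#' @param strands `"both"` or `"forward"`.
#' @param window TSS-relative window of the first base.
#' @return Data frame of class `MotifHitTable`: column `gene`, then per
#'   pattern `<name>_count` and logical `<name>` presence columns;
#'   attribute `hits` holds the per-hit records (gene, pattern, offset,
#'   strand, match).
#' @export
presence_table <- function(promoters, patterns = upr_motifs(),
                           strands = c("both", "forward"),
                           window = NULL) {
  strands <- match.arg(strands)
  if (is.list(promoters) && !is.null(promoters$sequences)) {
    if (is.null(window)) window <- promoters$window
    promoters <- promoters$sequences
  }
  if (is.null(window)) window <- attr(promoters, "window") %||% c(-1000, 500)
  window <- as.integer(window)
  if (length(promoters) == 0L || length(patterns) == 0L) {
    stop("promoters and patterns must be non-empty")
  }
  genes <- names(promoters)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop("promoters must carry unique gene names")
  }
  hit_records <- list()
  counts <- matrix(0L, nrow = length(promoters), ncol = length(patterns),
                   dimnames = list(genes, names(patterns)))
  for (pat_name in names(patterns)) {
    pat <- patterns[[pat_name]]
    for (i in seq_along(promoters)) {
      h <- scan_promoter(promoters[[i]], pat, strands = strands,
                         window = window)
      counts[i, pat_name] <- nrow(h)
      if (nrow(h)) {
        hit_records[[length(hit_records) + 1L]] <-
          cbind(data.frame(gene = genes[[i]], pattern = pat_name,
                           stringsAsFactors = FALSE), h)
      }
    }
  }
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (pat_name in names(patterns)) {
    tab[[paste0(pat_name, "_count")]] <- counts[, pat_name]
    tab[[pat_name]] <- counts[, pat_name] >= 1L
  }
  rownames(tab) <- NULL
  attr(tab, "hits") <- if (length(hit_records)) {
    do.call(rbind, hit_records)
  } else {
    data.frame(gene = character(), pattern = character(), offset = integer(),
               strand = character(), match = character(),
               stringsAsFactors = FALSE)
  }
  class(tab) <- c("MotifHitTable", class(tab))
  tab
}

#' Counts of pattern combinations across genes
#'
#' Combination counts are of the "at least these" form: a gene carrying all
#' three elements contributes to every pairwise "both" count as well as to
#' the triple count. `any` counts genes with at least one element and
#' `none` the remainder.
#'
#' @param table A `MotifHitTable` (or any data frame with logical presence
#'   columns named after the patterns).
#' @param patterns Character vector of presence column names (default: the
#'   logical columns of `table`).
#' @return Named integer vector: one entry per non-empty pattern
#'   combination (names joined by `&`), plus `any` and `none`.
#' @export
combination_counts <- function(table, patterns = NULL) {
  if (is.null(patterns)) {
    patterns <- names(table)[vapply(table, is.logical, logical(1))]
  }
  flags <- as.matrix(table[, patterns, drop = FALSE])
  n <- nrow(flags)
  k <- length(patterns)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  out <- integer(nrow(combos) + 2L)
  nm <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- patterns[unlist(combos[i, ])]
    nm[[i]] <- paste(sel, collapse = "&")
    out[[i]] <- if (n == 0L) 0L else
      sum(rowSums(flags[, sel, drop = FALSE]) == length(sel))
  }
  out[nrow(combos) + 1L] <- if (n == 0L) 0L else sum(rowSums(flags) >= 1L)
  out[nrow(combos) + 2L] <- if (n == 0L) 0L else sum(rowSums(flags) == 0L)
  names(out) <- c(nm, "any", "none")
  out
}

#' Write per-hit and presence tables as TSV
#'
#' @param table A `MotifHitTable`.
#' @param presence_path,hits_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_motif_tables <- function(table, presence_path = NULL,
                               hits_path = NULL) {
  if (!is.null(presence_path)) {
    utils::write.table(as.data.frame(table), presence_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(hits_path)) {
    utils::write.table(attr(table, "hits"), hits_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(presence_path, hits_path))
}
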