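#' Simulate a two-group expression dataset with a planted coordinated shift
#'
#' Emulates the statistical structure of a case/control HD expression
#' comparison: background genes are Normal(baseline, noise_sd) in both groups,
#' and a planted gene set is shifted by `effect * noise_sd` in cases only
#' (negative `effect` plants coordinated repression). Expression is on a
#' log-like scale, so the enrichment stage only relies on rank structure.
#'
#' @param n_genes Total number of genes.
#' @param n_case,n_control Samples per group.
#' @param planted_set_size Size of the coordinately shifted set.
#' @param effect Mean shift of planted genes in cases, in noise-SD units.
#' @param noise_sd Standard deviation of the expression noise.
#' @param baseline Background mean expression.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return List with `dataset` (an `ExpressionDataset`) and `truth` (class
#'   `SimulationTruth`: `planted_set`, `effect_size`, `seed`).
#' @export
simulate_expression <- function(n_genes, n_case, n_control,
                                planted_set_size, effect,
                                noise_sd = 1, baseline = 6, seed) {
  if (n_genes <= 0 || n_case <= 0 || n_control <= 0 || planted_set_size < 0) {
    stop("sizes must be positive")
  }
  if (planted_set_size > n_genes) {
    stop("planted_set_size exceeds n_genes")
  }
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  n_samp <- n_case + n_control
  vals <- matrix(stats::rnorm(n_genes * n_samp, baseline, noise_sd),
                 nrow = n_genes,
                 dimnames = list(genes, c(sprintf("CASE%02d", seq_len(n_case)),
                                          sprintf("CTRL%02d", seq_len(n_control)))))
  planted <- sample(genes, planted_set_size)
  case_idx <- seq_len(n_case)
  vals[planted, case_idx] <- vals[planted, case_idx] + effect * noise_sd
  ds <- expression_dataset(vals, c(rep("case", n_case), rep("control", n_control)))
  truth <- structure(
    list(planted_set = planted, effect_size = effect, noise_sd = noise_sd,
         seed = seed),
    class = "SimulationTruth"
  )
  list(dataset = ds, truth = truth)
}

#' Simulate TSS-anchored promoter windows with planted motifs
#'
#' Background sequence is i.i.d. uniform over A/C/G/T, which keeps chance-hit
#' rates analytic (e.g. the UPRE pattern matches a random position with
#' probability 2 * (1/4)^7 per strand). Each gene independently receives each
#' motif with its configured rate, at a uniform random offset and strand;
#' degenerate positions (R) and spacers (N) are spelled with random admissible
#' bases.
#'
#' @param n_genes Number of promoters.
#' @param window Integer pair, TSS-relative half-open window (default
#'   `c(-1000, 500)`, i.e. 1500 nt).
#' @param motif_rates Named numeric vector in `[0,1]`, per-pattern planting
#'   rate; names must match [upr_motifs()] patterns.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector of promoter
#'   sequences), `window`, and `truth` whose `planted_motif_positions` is a
#'   data frame (gene, motif, offset relative to TSS, strand).
#' @export
simulate_promoters <- function(n_genes, window = c(-1000, 500),
                               motif_rates = c(UPRE = 0, `ERSE-I` = 0,
                                               `ERSE-II` = 0),
                               seed) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  window <- as.integer(window)
  motif_rates <- unlist(motif_rates)   # accept a named list (e.g. from YAML)
  if (any(motif_rates < 0 | motif_rates > 1)) stop("rates must lie in [0,1]")
  width <- window[2] - window[1]
  patterns <- upr_motifs()
  unknown <- setdiff(names(motif_rates), names(patterns))
  if (length(unknown)) stop("unknown motif name(s): ",
                            paste(unknown, collapse = ", "))
  too_long <- vapply(patterns[names(motif_rates)], function(p) p$width > width,
                     logical(1))
  if (any(too_long)) stop("motif longer than promoter window")
  set.seed(seed)
  genes <- sprintf("P%05d", seq_len(n_genes))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_genes), function(i) {
    paste(sample(bases, width, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- genes
  plant <- list()
  for (motif in names(motif_rates)) {
    rate <- motif_rates[[motif]]
    if (rate == 0) next
    pat <- patterns[[motif]]
    hit <- stats::runif(n_genes) < rate
    for (i in which(hit)) {
      start <- sample.int(width - pat$width + 1L, 1L)  # 1-based in window
      strand <- sample(c("+", "-"), 1L)
      inst <- spell_motif_instance(pat)
      if (strand == "-") inst <- revcomp(inst)
      substr(seqs[[i]], start, start + pat$width - 1L) <- inst
      plant[[length(plant) + 1L]] <- data.frame(
        gene = genes[[i]], motif = motif,
        offset = start - 1L + window[1], strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(plant)) do.call(rbind, plant) else
    data.frame(gene = character(), motif = character(),
               offset = integer(), strand = character(),
               stringsAsFactors = FALSE)
  truth <- structure(
    list(planted_motif_positions = planted, motif_rates = motif_rates,
         seed = seed),
    class = "SimulationTruth"
  )
  list(sequences = seqs, window = window, truth = truth)
}

# Spell one concrete instance of a degenerate consensus.
spell_motif_instance <- function(pattern) {
  chars <- strsplit(pattern$expanded, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  out <- vapply(chars, function(ch) {
    switch(ch,
           R = sample(c("G", "A"), 1L),
           N = sample(bases, 1L),
           ch)
  }, character(1))
  paste(out, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x Single character string over A/C/G/T/N (and IUPAC R).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y", Y = "R")
  chars <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  paste(comp[chars], collapse = "")
}

#' Write promoter sequences as FASTA
#'
#' Headers carry the TSS-relative window: `>GENE|window=-1000:+500`.
#'
#' @param promoters Result of [simulate_promoters()], or a named character
#'   vector of sequences (then `window` must be given).
#' @param path Output FASTA path.
#' @param window Integer pair; default taken from `promoters$window`.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path, window = NULL) {
  if (is.list(promoters)) {
    window <- promoters$window
    promoters <- promoters$sequences
  }
  hdr <- if (is.null(window)) names(promoters) else
    sprintf("%s|window=%d:%+d", names(promoters), window[1], window[2])
  set <- Biostrings::DNAStringSet(promoters)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read promoter FASTA into named sequences
#'
#' Accepts headers `>GENE` or `>GENE|window=-1000:+500`.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences; attribute `window` when the
#'   header carried one.
#' @export
read_promoters_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  hdr <- names(set)
  gene <- toupper(sub("\\|.*$", "", hdr))
  seqs <- stats::setNames(as.character(set), gene)
  win <- regmatches(hdr[1], regexec("window=(-?\\d+):([+-]?\\d+)", hdr[1]))[[1]]
  if (length(win) == 3L) {
    attr(seqs, "window") <- as.integer(win[2:3])
  }
  seqs
}

#' Simulate an allelic-series FPKM table over CAG repeat lengths
#'
#' Emulates an HD knock-in allelic series: heterozygote animals with a ladder
#' of CAG repeat lengths (default 20, 80, 92, 111, 140, 175), `replicates`
#' animals per genotype, FPKM per gene. A planted fraction of genes receives a
#' monotone association with `rank(CAG)` (positive or negative), making the
#' planted truth exactly monotone for a rank-based (Spearman) analysis; the
#' rest is pure noise. FPKM is clamped at 0.
#'
#' @param cag_values Integer vector of CAG repeat lengths (>= 3 distinct).
#' @param replicates Samples per CAG genotype.
#' @param n_genes Number of genes.
#' @param frac_pos,frac_neg Fractions of genes planted with positive/negative
#'   association (`frac_pos + frac_neg <= 1`).
#' @param effect Slope per unit CAG rank, in FPKM units.
#' @param noise_sd FPKM noise standard deviation.
#' @param baseline Baseline FPKM.
#' @param seed Integer seed.
#' @return List with `series` (class `CAGSeries`: `fpkm` matrix genes x
#'   samples, `cag` per-sample repeat number) and `truth`
#'   (`planted_correlated` data frame gene/sign).
#' @export
simulate_cag_series <- function(cag_values = c(20, 80, 92, 111, 140, 175),
                                replicates = 4, n_genes = 200,
                                frac_pos = 0.1, frac_neg = 0.1,
                                effect = 1, noise_sd = 1, baseline = 10,
                                seed) {
  if (length(unique(cag_values)) < 3L) {
    stop("need at least 3 distinct CAG values")
  }
  if (frac_pos + frac_neg > 1) stop("frac_pos + frac_neg must be <= 1")
  set.seed(seed)
  cag <- rep(cag_values, each = replicates)
  n_samp <- length(cag)
  genes <- sprintf("G%05d", seq_len(n_genes))
  fpkm <- matrix(stats::rnorm(n_genes * n_samp, baseline, noise_sd),
                 nrow = n_genes,
                 dimnames = list(genes, sprintf("CAG%d_r%d",
                                                cag, sequence(rep(replicates,
                                                length(cag_values))))))
  n_pos <- round(frac_pos * n_genes)
  n_neg <- round(frac_neg * n_genes)
  planted <- sample(genes, n_pos + n_neg)
  pos_genes <- planted[seq_len(n_pos)]
  neg_genes <- planted[seq_len(n_neg) + n_pos]
  cag_rank <- match(cag, sort(unique(cag)))  # 1..k, exactly monotone in CAG
  if (n_pos > 0) {
    fpkm[pos_genes, ] <- fpkm[pos_genes, ] +
      matrix(effect * cag_rank, nrow = n_pos, ncol = n_samp, byrow = TRUE)
  }
  if (n_neg > 0) {
    fpkm[neg_genes, ] <- fpkm[neg_genes, ] -
      matrix(effect * cag_rank, nrow = n_neg, ncol = n_samp, byrow = TRUE)
  }
  fpkm[fpkm < 0] <- 0
  series <- structure(list(fpkm = fpkm, cag = cag), class = "CAGSeries")
  truth <- structure(
    list(planted_correlated = data.frame(
      gene = c(pos_genes, neg_genes),
      sign = rep(c(1L, -1L), c(n_pos, n_neg)),
      stringsAsFactors = FALSE),
      effect = effect, seed = seed),
    class = "SimulationTruth"
  )
  list(series = series, truth = truth)
}

#' Simulate a seed-centered interactome with planted annotation overlaps
#'
#' Builds an undirected simple graph in which every designated seed node has
#' at least one edge, then constructs annotation lists (an apoptosis-style
#' list and an HTT-interactor-style list with direct/indirect types) that
#' intersect the 1-hop seed interactome in exactly the planted numbers; the
#' HTT overlap is drawn from within the apoptosis overlap, mirroring a nested
#' cross-annotation design.
#'
#' @param n_nodes Number of network nodes.
#' @param n_edges Number of edges (must not exceed the simple-graph maximum).
#' @param seed_nodes Character vector of seed node names (subset of generated
#'   nodes by index, or new names prepended).
#' @param planted_apoptosis_overlap Number of interactome nodes carried by the
#'   apoptosis list.
#' @param planted_htt_overlap Number of those also on the HTT list.
#' @param n_direct How many of the planted HTT-overlap genes are typed
#'   `direct` (the rest are `indirect`).
#' @param seed Integer seed.
#' @return List with `edges` (data frame geneA/geneB/source), `seeds`,
#'   `apoptosis` (character vector), `htt_interactors` (data frame
#'   gene/type), and `truth` (planted overlap counts and node ids).
#' @export
simulate_network <- function(n_nodes, n_edges, seed_nodes = c("ATF6", "ATF4",
                             "DDIT3", "EIF2AK3", "ERN1", "XBP1"),
                             planted_apoptosis_overlap,
                             planted_htt_overlap, n_direct = 2, seed) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) stop("n_edges exceeds simple-graph maximum")
  if (planted_apoptosis_overlap > n_nodes ||
      planted_htt_overlap > planted_apoptosis_overlap) {
    stop("planted overlaps exceed available nodes")
  }
  set.seed(seed)
  n_other <- n_nodes - length(seed_nodes)
  if (n_other < 0) stop("more seed nodes than nodes")
  nodes <- c(toupper(seed_nodes), sprintf("N%04d", seq_len(n_other)))
  g <- igraph::sample_gnm(n_nodes, n_edges, directed = FALSE)
  igraph::V(g)$name <- nodes
  # guarantee every seed node >= 1 edge: attach isolated seeds to a random
  # non-seed node, compensating by dropping an edge not incident to any seed
  seed_upper <- toupper(seed_nodes)
  for (s in seed_upper) {
    if (igraph::degree(g, s) == 0L) {
      partner <- sample(setdiff(nodes, seed_upper), 1L)
      g <- igraph::add_edges(g, c(s, partner))
      em <- igraph::as_data_frame(g, what = "edges")
      droppable <- which(!(em$from %in% seed_upper) &
                           !(em$to %in% seed_upper) &
                           igraph::degree(g, em$from) > 1L &
                           igraph::degree(g, em$to) > 1L)
      if (length(droppable)) {
        g <- igraph::delete_edges(g, droppable[[1L]])
      }
      g <- igraph::simplify(g)
    }
  }
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(geneA = ed$from, geneB = ed$to, source = "synthetic",
                      stringsAsFactors = FALSE)
  net_nodes <- unique(c(toupper(seed_nodes),
                        edges$geneB[edges$geneA %in% toupper(seed_nodes)],
                        edges$geneA[edges$geneB %in% toupper(seed_nodes)]))
  if (planted_apoptosis_overlap > length(net_nodes)) {
    stop("planted apoptosis overlap exceeds interactome size (",
         length(net_nodes), ")")
  }
  apo_in <- sample(net_nodes, planted_apoptosis_overlap)
  # filler annotation genes guaranteed outside the whole node universe
  apo_out <- sprintf("APO%04d", seq_len(20))
  apoptosis <- c(apo_in, apo_out)
  htt_in <- if (planted_htt_overlap > 0) {
    sample(apo_in, planted_htt_overlap)
  } else character()
  htt_out <- sprintf("HTTX%04d", seq_len(10))
  htt_genes <- c(htt_in, htt_out)
  types <- rep("indirect", length(htt_genes))
  if (n_direct > 0 && length(htt_in) > 0) {
    types[seq_len(min(n_direct, length(htt_in)))] <- "direct"
  }
  truth <- structure(
    list(planted_overlaps = c(apoptosis = planted_apoptosis_overlap,
                              htt = planted_htt_overlap),
         apoptosis_in_net = apo_in, htt_in_net = htt_in, seed = seed),
    class = "SimulationTruth"
  )
  list(edges = edges, seeds = toupper(seed_nodes), apoptosis = apoptosis,
       htt_interactors = data.frame(gene = htt_genes, type = types,
                                    stringsAsFactors = FALSE),
       truth = truth)
}

#' Serialize a simulation truth record as TSV
#'
#' Each generated dataset carries its ground truth; writing it alongside the
#' data lets downstream recovery be scored without re-reading generator
#' internals.
#'
#' @param truth A `SimulationTruth`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  rows <- list()
  for (nm in names(truth)) {
    v <- truth[[nm]]
    if (is.data.frame(v)) {
      rows[[nm]] <- data.frame(field = nm,
                               value = apply(v, 1, paste, collapse = ":"),
                               stringsAsFactors = FALSE)
    } else {
      rows[[nm]] <- data.frame(field = nm,
                               value = paste(v, collapse = ","),
                               stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
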