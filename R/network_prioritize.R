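#' Build a seed-centered interactome
#'
#' The network is the seeds plus their direct (1-hop) interaction partners;
#' by default every edge among the included nodes is retained (induced
#' subgraph), optionally restricted to seed-incident edges only. Self-loops
#' and duplicate edges are removed.
#'
#' @param edges Data frame with at least columns `geneA`, `geneB`
#'   (optionally `type`, `source`), or a path to such a TSV.
#' @param seeds Character vector of seed gene symbols (non-empty); seeds
#'   absent from the edge list are dropped with a warning, and it is an
#'   error if none remains.
#' @param induced Keep all edges among included nodes (`TRUE`, default) or
#'   only seed-incident edges.
#' @return Object of class `InteractionNetwork`: list with `graph` (an
#'   igraph object with vertex attribute `seed`), `nodes`, `seeds`.
#' @export
build_interactome <- function(edges, seeds, induced = TRUE) {
  if (is.character(edges) && length(edges) == 1L) {
    edges <- utils::read.delim(edges, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("geneA", "geneB") %in% names(edges)))
  if (length(seeds) == 0L) stop("seeds must be non-empty")
  seeds <- unique(toupper(seeds))
  edges$geneA <- toupper(edges$geneA)
  edges$geneB <- toupper(edges$geneB)
  edges <- edges[edges$geneA != edges$geneB, , drop = FALSE]
  g_full <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g_full <- igraph::simplify(g_full, edge.attr.comb = "first")
  present <- intersect(seeds, igraph::V(g_full)$name)
  if (length(present) == 0L) stop("no seed present in the edge list")
  if (length(present) < length(seeds)) {
    warning("seed(s) absent from the edge list: ",
            paste(setdiff(seeds, present), collapse = ", "))
  }
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(g_full, present),
                               names)))
  nodes <- unique(c(present, nbrs))
  g <- igraph::induced_subgraph(g_full, nodes)
  if (!induced) {
    keep <- unique(unlist(igraph::incident_edges(g, present)))
    g <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
  }
  igraph::V(g)$seed <- igraph::V(g)$name %in% present
  structure(list(graph = g, nodes = igraph::V(g)$name, seeds = present),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork:", length(x$nodes), "nodes,",
      igraph::ecount(x$graph), "edges,", length(x$seeds), "seeds\n")
  invisible(x)
}

#' Overlay an annotation list on a network
#'
#' @param net An `InteractionNetwork`.
#' @param annotation A `GeneSet` or character vector.
#' @return List with `table` (data frame node/annotated) and `count`
#'   (number of network nodes carrying the annotation).
#' @export
overlay_annotation <- function(net, annotation) {
  members <- if (inherits(annotation, "GeneSet")) annotation$members else
    unique(toupper(annotation))
  flag <- net$nodes %in% members
  list(table = data.frame(node = net$nodes, annotated = flag,
                          stringsAsFactors = FALSE),
       count = sum(flag))
}

#' Cross two annotations on a network, carrying interaction type
#'
#' Reports the network nodes present in both annotation lists, with the
#' direct/indirect interaction type carried by the second list.
#'
#' @param net An `InteractionNetwork`.
#' @param annotA A `GeneSet` or character vector.
#' @param annotB Data frame with columns `gene` and `type`
#'   (`direct`/`indirect`); one type per gene (conflicts are an error).
#' @return Data frame `gene`, `type` for nodes in both annotations, plus
#'   attribute `type_counts`.
#' @export
cross_annotation <- function(net, annotA, annotB) {
  membersA <- if (inherits(annotA, "GeneSet")) annotA$members else
    unique(toupper(annotA))
  stopifnot(all(c("gene", "type") %in% names(annotB)))
  annotB$gene <- toupper(annotB$gene)
  agg <- tapply(annotB$type, annotB$gene, function(t) length(unique(t)))
  if (any(agg > 1L)) {
    stop("conflicting interaction types for: ",
         paste(names(agg)[agg > 1L], collapse = ", "))
  }
  annotB <- annotB[!duplicated(annotB$gene), , drop = FALSE]
  both <- intersect(intersect(net$nodes, membersA), annotB$gene)
  out <- data.frame(gene = both,
                    type = annotB$type[match(both, annotB$gene)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "type_counts") <- table(factor(out$type,
                                           levels = c("direct", "indirect")))
  out
}

#' Tri-set prioritization of UPR-HD connector genes
#'
#' Integrates three lines of evidence: membership in the differential UPR
#' consensus signature(s), membership in the curated therapeutic-target
#' list (HDTT), and physical association with HTT (direct or indirect).
#' One record is emitted per gene in the three-way intersection; promoter
#' motif flags and CAG-correlation statistics are joined when available.
#' Records are sorted by correlation significance (smaller tail FDR first),
#' then gene symbol.
#'
#' @param diff_upr A `ConsensusSignature`, a list of them (up/down), or a
#'   character vector of differentially regulated UPR genes.
#' @param hdtt A `GeneSet` or character vector of therapeutic-target genes.
#' @param htt_int Data frame `gene`, `type` of HTT interactors.
#' @param motif_table Optional `MotifHitTable` over these genes.
#' @param corr_records Optional `CorrelationRecord` data frame.
#' @return Data frame of class `PrioritizationRecord`: `gene`,
#'   `direction`, `htt_interaction`, `upre`, `erse1`, `erse2`, `rho`,
#'   `fdr_cor`, `significant_cor`.
#' @export
triset_prioritize <- function(diff_upr, hdtt, htt_int,
                              motif_table = NULL, corr_records = NULL) {
  sig_genes <- function(x) {
    if (inherits(x, "ConsensusSignature")) {
      stats::setNames(rep(x$direction, length(x$genes)), x$genes)
    } else if (is.list(x) && !is.null(x[[1]]) &&
               inherits(x[[1]], "ConsensusSignature")) {
      do.call(c, lapply(x, function(s)
        stats::setNames(rep(s$direction, length(s$genes)), s$genes)))
    } else {
      g <- if (inherits(x, "GeneSet")) x$members else unique(toupper(x))
      stats::setNames(rep(NA_character_, length(g)), g)
    }
  }
  upr <- sig_genes(diff_upr)
  hdtt_genes <- if (inherits(hdtt, "GeneSet")) hdtt$members else
    unique(toupper(hdtt))
  stopifnot(all(c("gene", "type") %in% names(htt_int)))
  htt_int$gene <- toupper(htt_int$gene)
  common <- Reduce(intersect, list(names(upr), hdtt_genes, htt_int$gene))
  out <- data.frame(
    gene = common,
    direction = unname(upr[common]),
    htt_interaction = htt_int$type[match(common, htt_int$gene)],
    stringsAsFactors = FALSE)
  if (!is.null(motif_table)) {
    i <- match(out$gene, toupper(motif_table$gene))
    pick <- function(col) {
      v <- if (col %in% names(motif_table)) motif_table[[col]][i] else
        rep(NA, length(i))
      v[is.na(i)] <- NA
      v
    }
    out$upre <- pick("UPRE")
    out$erse1 <- pick("ERSE-I")
    out$erse2 <- pick("ERSE-II")
  } else {
    out$upre <- out$erse1 <- out$erse2 <- rep(NA, nrow(out))
  }
  if (!is.null(corr_records)) {
    i <- match(out$gene, toupper(corr_records$gene))
    out$rho <- corr_records$rho[i]
    fp <- corr_records$fdr_pos[i]
    fn <- corr_records$fdr_neg[i]
    out$fdr_cor <- ifelse(!is.na(out$rho) & out$rho >= 0, fp, fn)
    out$significant_cor <- !is.na(out$fdr_cor) & out$fdr_cor < 0.01
  } else {
    out$rho <- out$fdr_cor <- rep(NA_real_, nrow(out))
    out$significant_cor <- rep(NA, nrow(out))
  }
  ord <- order(ifelse(is.na(out$fdr_cor), Inf, out$fdr_cor), out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PrioritizationRecord", class(out))
  out
}

#' Export a network as SIF and node/edge TSV
#'
#' @param net An `InteractionNetwork`.
#' @param sif_path,nodes_path,edges_path Output paths (any may be `NULL`).
#' @param relation SIF relation label.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, sif_path = NULL, nodes_path = NULL,
                          edges_path = NULL, relation = "pp") {
  ed <- igraph::as_data_frame(net$graph, what = "edges")
  if (!is.null(sif_path)) {
    writeLines(paste(ed$from, relation, ed$to, sep = "\t"), sif_path)
  }
  if (!is.null(nodes_path)) {
    utils::write.table(
      data.frame(node = net$nodes, seed = net$nodes %in% net$seeds,
                 stringsAsFactors = FALSE),
      nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(edges_path)) {
    utils::write.table(
      data.frame(geneA = ed$from, geneB = ed$to, stringsAsFactors = FALSE),
      edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(sif_path, nodes_path, edges_path))
}
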