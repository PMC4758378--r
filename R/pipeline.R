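#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with the
#' default study conditions of the synthetic end-to-end run: six
#' case/control comparisons with a planted coordinately upregulated set,
#' promoter windows with planted stress-response elements, a CAG allelic
#' series with planted monotone genes, and a seed-centered interactome
#' with planted annotation overlaps. Thresholds are the pipeline
#' conventions: enrichment calls at `fdr <= 0.05` and `|NES| >= 1.4`,
#' correlation significance at empirical `fdr < 0.01`.
#'
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it deterministically.
#' @param out_dir Run directory (created if needed).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("uprhd_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    expression = list(n_comparisons = 6, n_genes = 600, n_case = 10,
                      n_control = 10, planted_set_size = 40, effect = 2,
                      noise_sd = 1),
    gsea = list(metric = "signal2noise", n_perm = 200, fdr_max = 0.05,
                nes_min = 1.4, min_set_size = 5),
    consensus = list(min_support = NULL),  # NULL -> all up-classified
    promoters = list(motif_rates = list(UPRE = 0.3, `ERSE-I` = 0.1,
                                        `ERSE-II` = 0.05)),
    cag = list(cag_values = c(20, 80, 92, 111, 140, 175), replicates = 4,
               n_genes = 200, frac_pos = 0.1, frac_neg = 0.05, effect = 1,
               noise_sd = 1, n_perm = 500, fdr_threshold = 0.01),
    network = list(n_nodes = 200, n_edges = 600,
                   apoptosis_overlap = 40, htt_overlap = 6, n_direct = 2)
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure, mandatory seeds, and that any referenced input paths
#' exist, before any stage runs.
#'
#' @param config Configuration list or path to a YAML file.
#' @return The normalized configuration list, invisibly on success;
#'   errors otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  required <- c("seed", "out_dir", "expression", "gsea", "consensus",
                "promoters", "cag", "network")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config is missing section(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(config$seed)) stop("config$seed must be an integer seed")
  for (p in config$inputs) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  invisible(config)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order: simulate expression
#' comparisons, enrichment analysis of the planted set per comparison,
#' consensus signature over up-classified comparisons, promoter simulation
#' and motif scanning with enrichment of the consensus genes, CAG-series
#' correlation with permutation FDR and set over-representation, network
#' overlay and tri-set prioritization. Every stage writes TSVs under
#' `out_dir`, one log line, and the run closes with a manifest of output
#' hashes; re-running with the same configuration reproduces every output
#' byte-for-byte. A stage failure aborts with the failing stage named;
#' outputs of completed stages are retained.
#'
#' @param config Configuration list (see [default_config()]) or YAML path.
#' @return List with per-stage results: `gsea` (list of result tables),
#'   `consensus`, `motifs`, `motif_enrichment`, `correlation`,
#'   `overrepresentation`, `network`, `prioritization`, `truth`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = log_path,
        append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- as.integer(config$seed)
  cfg_e <- config$expression
  cfg_g <- config$gsea
  th <- gsea_thresholds(fdr_max = cfg_g$fdr_max,
                        nes_up_min = cfg_g$nes_min,
                        nes_down_max = -cfg_g$nes_min)

  # simulate + enrichment per comparison (shared planted set across
  # comparisons, different noise realizations — the cross-model design)
  sims <- run_stage("simulate_expression", {
    first <- simulate_expression(cfg_e$n_genes, cfg_e$n_case,
                                 cfg_e$n_control, cfg_e$planted_set_size,
                                 cfg_e$effect, cfg_e$noise_sd, seed = seed)
    planted <- first$truth$planted_set
    sims <- vector("list", cfg_e$n_comparisons)
    sims[[1]] <- first
    for (i in seq_len(cfg_e$n_comparisons - 1L)) {
      s <- simulate_expression(cfg_e$n_genes, cfg_e$n_case, cfg_e$n_control,
                               0, 0, cfg_e$noise_sd, seed = seed + i)
      genes <- rownames(s$dataset$values)
      case <- s$dataset$phenotype == "case"
      s$dataset$values[planted, case] <-
        s$dataset$values[planted, case] + cfg_e$effect * cfg_e$noise_sd
      s$truth$planted_set <- planted
      s$truth$effect_size <- cfg_e$effect
      sims[[i + 1L]] <- s
    }
    sims
  })
  planted <- sims[[1]]$truth$planted_set
  gene_sets <- list(PLANTED = gene_set("PLANTED", planted,
                                       description = "planted set"))
  gsea_res <- run_stage("gsea", {
    lapply(seq_along(sims), function(i) {
      res <- run_gsea(sims[[i]]$dataset, gene_sets, metric = cfg_g$metric,
                      n_perm = cfg_g$n_perm, seed = seed + 100 + i,
                      min_set_size = cfg_g$min_set_size, thresholds = th)
      utils::write.table(as.data.frame(res),
                         file.path(config$out_dir,
                                   sprintf("gsea_comparison%02d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_line("gsea", "comparison ", i, ": NES=",
               round(res$NES[1], 3), " fdr=", round(res$fdr[1], 4),
               " direction=", res$direction[1], " seed=", seed + 100 + i)
      res
    })
  })

  consensus <- run_stage("consensus", {
    up <- Filter(function(r) r$direction[1] == "up", gsea_res)
    if (length(up) == 0L) stop("no comparison classified up")
    edges <- lapply(up, function(r)
      strsplit(r$leading_edge[1], ",", fixed = TRUE)[[1]])
    names(edges) <- sprintf("comparison%02d",
                            which(vapply(gsea_res, function(r)
                              r$direction[1] == "up", logical(1))))
    ms <- config$consensus$min_support %||% length(edges)
    sig <- consensus_signature(edges, required = character(),
                               min_support = min(ms, length(edges)),
                               direction = "up")
    write_consensus(sig, file.path(config$out_dir, "consensus_up.tsv"))
    log_line("consensus", length(sig$genes), " genes from ",
             length(edges), " up-classified comparisons")
    sig
  })

  motifs <- run_stage("motif_scan", {
    pr <- simulate_promoters(cfg_e$n_genes,
                             motif_rates = config$promoters$motif_rates,
                             seed = seed + 200)
    names(pr$sequences) <- rownames(sims[[1]]$dataset$values)
    pr$truth$planted_motif_positions$gene <-
      rownames(sims[[1]]$dataset$values)[
        match(pr$truth$planted_motif_positions$gene,
              sprintf("P%05d", seq_len(cfg_e$n_genes)))]
    tab <- presence_table(pr$sequences, window = pr$window)
    write_motif_tables(tab,
                       presence_path = file.path(config$out_dir,
                                                 "motif_presence.tsv"),
                       hits_path = file.path(config$out_dir,
                                             "motif_hits.tsv"))
    log_line("motif_scan", nrow(tab), " promoters scanned, ",
             nrow(attr(tab, "hits")), " hits")
    list(table = tab, truth = pr$truth)
  })

  menr <- run_stage("motif_enrichment", {
    me <- motif_enrichment(motifs$table, consensus$genes)
    utils::write.table(me, file.path(config$out_dir,
                                     "motif_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("motif_enrichment", paste(me$pattern, signif(me$p, 3),
                                       collapse = "; "))
    me
  })

  cfg_c <- config$cag
  corr <- run_stage("cag_correlation", {
    cs <- simulate_cag_series(cfg_c$cag_values, cfg_c$replicates,
                              cfg_c$n_genes, cfg_c$frac_pos, cfg_c$frac_neg,
                              cfg_c$effect, cfg_c$noise_sd,
                              seed = seed + 300)
    rec <- permutation_fdr(cs$series, n_perm = cfg_c$n_perm,
                           seed = seed + 301,
                           fdr_threshold = cfg_c$fdr_threshold)
    utils::write.table(as.data.frame(rec),
                       file.path(config$out_dir, "cag_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("cag_correlation",
             sum(rec$significant_pos), " positive / ",
             sum(rec$significant_neg), " negative significant at fdr<",
             cfg_c$fdr_threshold)
    list(records = rec, truth = cs$truth)
  })

  over <- run_stage("set_overrepresentation", {
    sig_genes <- corr$records$gene[corr$records$significant_pos |
                                     corr$records$significant_neg]
    target <- corr$truth$planted_correlated$gene
    res <- set_overrepresentation(sig_genes, target, corr$records$gene)
    log_line("set_overrepresentation", "Fisher p=", signif(res$p, 3))
    res
  })

  cfg_n <- config$network
  netres <- run_stage("network", {
    sim <- simulate_network(cfg_n$n_nodes, cfg_n$n_edges,
                            planted_apoptosis_overlap =
                              cfg_n$apoptosis_overlap,
                            planted_htt_overlap = cfg_n$htt_overlap,
                            n_direct = cfg_n$n_direct, seed = seed + 400)
    net <- build_interactome(sim$edges, sim$seeds)
    apo <- overlay_annotation(net, sim$apoptosis)
    cross <- cross_annotation(net, sim$apoptosis, sim$htt_interactors)
    write_network(net,
                  sif_path = file.path(config$out_dir, "interactome.sif"),
                  nodes_path = file.path(config$out_dir,
                                         "interactome_nodes.tsv"))
    log_line("network", length(net$nodes), " nodes; apoptosis overlay ",
             apo$count, "; cross-annotation ", nrow(cross))
    list(sim = sim, net = net, apoptosis = apo, cross = cross)
  })

  prior <- run_stage("prioritize", {
    htt_int <- netres$sim$htt_interactors
    hdtt <- planted  # curated-target stand-in: the planted signature genes
    pr <- triset_prioritize(consensus, hdtt,
                            data.frame(gene = c(htt_int$gene,
                                                consensus$genes),
                                       type = c(htt_int$type,
                                                rep("indirect",
                                                    length(consensus$genes))),
                                       stringsAsFactors = FALSE),
                            motif_table = motifs$table,
                            corr_records = NULL)
    utils::write.table(as.data.frame(pr),
                       file.path(config$out_dir, "prioritization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("prioritize", nrow(pr), " tri-set records")
    pr
  })

  manifest <- run_stage("manifest", {
    files <- sort(list.files(config$out_dir, pattern = "\\.(tsv|sif)$",
                             full.names = TRUE))
    mf <- data.frame(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE)
    utils::write.table(mf, file.path(config$out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("manifest", nrow(mf), " outputs hashed; master seed ", seed)
    mf
  })

  list(gsea = gsea_res, consensus = consensus, motifs = motifs,
       motif_enrichment = menr, correlation = corr,
       overrepresentation = over, network = netres,
       prioritization = prior, manifest = manifest,
       truth = list(expression = sims[[1]]$truth, motifs = motifs$truth,
                    cag = corr$truth, network = netres$sim$truth),
       out_dir = config$out_dir)
}

#' Read the shipped prioritization fixture
#'
#' Loads the packaged 13-gene prioritization table (gene, promoter-element
#' flags, HTT interaction type, CAG correlation coefficient and its
#' empirical FDR) used by the worked examples and the test suite.
#'
#' @param path Path to a prioritization TSV; defaults to the packaged
#'   fixture.
#' @return Data frame with columns `gene`, `upre`, `erse1`, `erse2`
#'   (logical), `interaction_type` (`direct`/`indirect`), `rho`,
#'   `fdr_cor`.
#' @export
read_prioritization_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table3_prioritization.tsv",
                        package = "uprhd", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character())
  data.frame(
    gene = toupper(tab$gene),
    upre = tab$upre == "+",
    erse1 = tab$erse1 == "+",
    erse2 = tab$erse2 == "+",
    interaction_type = tolower(tab$interaction_type),
    rho = as.numeric(tab$rho),
    fdr_cor = as.numeric(tab$fdr_cor),
    stringsAsFactors = FALSE)
}
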