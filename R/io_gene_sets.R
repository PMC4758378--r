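#' Construct a gene set
#'
#' A gene set is a named collection of gene symbols. Symbols are canonicalized
#' to upper case because the data mix human, mouse, rat, worm and yeast symbol
#' conventions; duplicates are removed.
#'
#' @param name Set name (non-empty string, unique within a collection).
#' @param members Character vector of gene symbols.
#' @param description Free-text description.
#' @param source Provenance tag (e.g. file of origin).
#' @return An object of class `GeneSet`: a list with elements `name`,
#'   `description`, `members` (upper-case, de-duplicated) and `source`.
#' @export
gene_set <- function(name, members, description = "", source = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- unique(toupper(as.character(members)))
  members <- members[nzchar(members)]
  if (length(members) == 0L) {
    stop("gene set '", name, "' has no members")
  }
  structure(
    list(name = name, description = description, members = members,
         source = source),
    class = "GeneSet"
  )
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$name, "' (", length(x$members), " genes)\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one or more member symbols,
#' tab-separated. Member symbols are upper-cased and de-duplicated.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields, got ", length(fields))
    }
    sets[[i]] <- gene_set(fields[[1]], fields[-(1:2)],
                          description = fields[[2]], source = basename(path))
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate gene set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(sets) <- nm
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of `GeneSet` objects (or plain character vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (!inherits(s, "GeneSet")) {
      s <- gene_set(names(sets)[[i]] %||% paste0("set", i), s)
    }
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Construct an expression dataset
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param phenotype Character vector, one of `"case"`/`"control"` per sample.
#' @return Object of class `ExpressionDataset` with elements `values` and
#'   `phenotype`.
#' @export
expression_dataset <- function(values, phenotype) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(!nzchar(rownames(values)))) {
    stop("expression matrix must have complete gene ids as rownames")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  phenotype <- as.character(phenotype)
  if (length(phenotype) != ncol(values)) {
    stop("phenotype length (", length(phenotype),
         ") does not match sample count (", ncol(values), ")")
  }
  if (!all(phenotype %in% c("case", "control"))) {
    stop("phenotype labels must be 'case' or 'control'")
  }
  if (!all(c("case", "control") %in% phenotype)) {
    stop("need at least one sample per phenotype")
  }
  rownames(values) <- toupper(rownames(values))
  structure(list(values = values, phenotype = phenotype),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$phenotype == "case"), " case / ",
      sum(x$phenotype == "control"), " control)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix (plain TSV or GCT v1.2)
#'
#' Plain TSV: header row of sample ids, first column gene ids. GCT v1.2:
#' `#1.2` line, dimensions line, then a table whose first two columns are
#' NAME and Description.
#'
#' @param path Path to the file.
#' @param format `"auto"` (sniff the `#1.2` magic), `"tsv"` or `"gct"`.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (identical(trimws(first), "#1.2")) "gct" else "tsv"
  }
  if (format == "gct") {
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    mat <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(mat) <- toupper(tab[[1]])
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- toupper(tab[[1]])
  }
  storage.mode(mat) <- "double"
  mat
}

#' Write an expression matrix as plain TSV
#'
#' @param values Numeric matrix with gene rownames.
#' @param path Output path.
#' @param id_col Name of the gene-id column in the header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path, id_col = "gene") {
  df <- data.frame(values, check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(values)), id_col), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phenotype labels (CLS or two-column TSV)
#'
#' CLS: three lines (`n k 1`, `# label...`, space-separated assignments).
#' TSV: columns sample id and label.
#'
#' @param path Path to the phenotype file.
#' @param n_samples Optional expected sample count (validated when given).
#' @return Character vector of per-sample labels.
#' @export
read_phenotype <- function(path, n_samples = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  labels <- if (length(lines) >= 2L && startsWith(trimws(lines[[2]]), "#")) {
    class_names <- strsplit(trimws(sub("^#", "", lines[[2]])), "[ \t]+")[[1]]
    assign <- strsplit(trimws(lines[[3]]), "[ \t]+")[[1]]
    if (all(assign %in% class_names)) assign
    else class_names[as.integer(assign) + 1L]
  } else {
    tab <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE,
                             skip = if (grepl("\t", lines[[1]], fixed = TRUE) &&
                                        !grepl("^[A-Za-z0-9_.-]+\t", lines[[1]]))
                                      1L else 0L)
    if (ncol(tab) < 2L) stop("phenotype TSV needs two columns: ", path)
    tab[[2]]
  }
  if (!is.null(n_samples) && length(labels) != n_samples) {
    stop("phenotype file has ", length(labels), " labels, expected ",
         n_samples)
  }
  as.character(labels)
}

#' Write phenotype labels as a CLS file
#'
#' @param phenotype Character vector of labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(phenotype, path) {
  classes <- unique(phenotype)
  writeLines(c(
    paste(length(phenotype), length(classes), 1),
    paste("#", paste(classes, collapse = " ")),
    paste(phenotype, collapse = " ")
  ), path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' @param path TSV with columns source-species id and human symbol (header
#'   optional; detected when the first line contains no self-mapping).
#' @return Data frame with columns `source_id`, `human_symbol`.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("ortholog map needs two columns: ", path)
  if (identical(tolower(tab[1, 1]), "source_id") ||
      identical(tolower(tab[1, 1]), "source")) {
    tab <- tab[-1, , drop = FALSE]
  }
  data.frame(source_id = as.character(tab[[1]]),
             human_symbol = toupper(as.character(tab[[2]])),
             stringsAsFactors = FALSE)
}

#' Map a dataset's gene ids to human symbols via an ortholog map
#'
#' Many-to-one mappings (several source genes hitting one human symbol) are
#' resolved by `collapse`; `max-mean-probe` keeps the row with the largest row
#' mean, the common microarray probe-collapse convention. Unmapped ids are
#' dropped with a warning that reports their count, never silently.
#'
#' @param dataset An `ExpressionDataset`.
#' @param map Data frame as returned by [read_ortholog_map()].
#' @param collapse One of `"max-mean-probe"`, `"first"`,
#'   `"error-on-collision"`.
#' @return An `ExpressionDataset` with human-symbol rownames; attribute
#'   `unmapped` carries the ids that had no mapping.
#' @export
apply_ortholog_map <- function(dataset, map,
                               collapse = c("max-mean-probe", "first",
                                            "error-on-collision")) {
  collapse <- match.arg(collapse)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (nrow(map) == 0L) stop("empty ortholog map")
  lookup <- stats::setNames(map$human_symbol, toupper(map$source_id))
  src <- rownames(dataset$values)
  human <- lookup[src]
  unmapped <- src[is.na(human)]
  if (length(unmapped) > 0L) {
    warning(length(unmapped), " gene id(s) had no ortholog mapping and were dropped")
  }
  keep <- !is.na(human)
  vals <- dataset$values[keep, , drop = FALSE]
  human <- human[keep]
  if (anyDuplicated(human)) {
    if (collapse == "error-on-collision") {
      stop("many-to-one ortholog collision for: ",
           paste(unique(human[duplicated(human)]), collapse = ", "))
    }
    ord <- if (collapse == "max-mean-probe") {
      order(human, -rowMeans(vals))
    } else {
      order(human, seq_len(nrow(vals)))
    }
    vals <- vals[ord, , drop = FALSE]
    human <- human[ord]
    keep2 <- !duplicated(human)
    vals <- vals[keep2, , drop = FALSE]
    human <- human[keep2]
  }
  rownames(vals) <- human
  out <- expression_dataset(vals, dataset$phenotype)
  attr(out, "unmapped") <- unmapped
  out
}

#' Venn region counts for 2-7 gene sets
#'
#' Every element of the union is assigned to exactly one region (the exact
#' membership signature), so region counts always sum to the union size.
#'
#' @param sets Named list of `GeneSet` objects or character vectors (2-7).
#' @return Data frame with columns `region` (set names joined by `&`) and
#'   `count`, including zero-count regions.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2L || length(sets) > 7L) {
    stop("venn_counts needs between 2 and 7 sets, got ", length(sets))
  }
  members <- lapply(sets, function(s) {
    if (inherits(s, "GeneSet")) s$members else unique(toupper(as.character(s)))
  })
  nm <- names(members)
  if (is.null(nm) || any(!nzchar(nm))) nm <- LETTERS[seq_along(members)]
  universe <- unique(unlist(members))
  signature <- vapply(universe, function(g) {
    paste0(as.integer(vapply(members, function(m) g %in% m, logical(1))),
           collapse = "")
  }, character(1))
  k <- length(members)
  grid <- expand.grid(rep(list(0:1), k))[-1, , drop = FALSE]  # drop all-zero
  region_sig <- apply(grid, 1L, paste0, collapse = "")
  region_name <- apply(grid, 1L, function(bits) {
    paste(nm[bits == 1L], collapse = "&")
  })
  counts <- vapply(region_sig, function(s) sum(signature == s), integer(1))
  data.frame(region = region_name, count = counts,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a one-symbol-per-line annotation list
#'
#' @param path Plain-text file, one gene symbol per line; blank lines and
#'   lines starting with `#` ignored.
#' @return Upper-cased, de-duplicated character vector.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(toupper(lines))
}
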