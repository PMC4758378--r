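#' Consensus signature across comparisons
#'
#' Intersects per-comparison leading-edge gene sets at configurable
#' stringency. A gene enters the signature when it is present in every
#' `required` comparison (e.g. the human comparison) and in at least
#' `min_support` of the remaining ("optional") comparisons. With
#' `min_support` equal to the number of optional comparisons and no
#' required ids this reduces to the plain intersection; lowering
#' `min_support` yields relaxed signatures (e.g. "at least four of six
#' models").
#'
#' @param leading_edges Named list: comparison id -> character vector of
#'   leading-edge genes.
#' @param required Character vector of comparison ids that must all contain
#'   the gene (subset of `names(leading_edges)`).
#' @param min_support Minimum number of optional comparisons containing the
#'   gene (`0 <= min_support <=` number of optional comparisons).
#' @param direction `"up"` or `"down"` tag carried on the output; build up-
#'   and down-signatures separately from up- and down-classified
#'   comparisons.
#' @return Object of class `ConsensusSignature`: list with `genes`,
#'   `support` (named integer, count of contributing comparisons per gene,
#'   required included), `direction` and `rule`.
#' @export
consensus_signature <- function(leading_edges, required = character(),
                                min_support, direction = c("up", "down")) {
  direction <- match.arg(direction)
  ids <- names(leading_edges)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("leading_edges must be a named list of comparisons")
  }
  unknown <- setdiff(required, ids)
  if (length(unknown)) {
    stop("unknown comparison id(s) in `required`: ",
         paste(unknown, collapse = ", "))
  }
  optional <- setdiff(ids, required)
  if (min_support < 0 || min_support > length(optional)) {
    stop("min_support must lie in [0, ", length(optional), "]")
  }
  sets <- lapply(leading_edges, function(x) unique(toupper(x)))
  universe <- unique(unlist(sets))
  in_req <- if (length(required)) {
    Reduce(`&`, lapply(sets[required], function(s) universe %in% s))
  } else rep(TRUE, length(universe))
  opt_support <- if (length(optional)) {
    Reduce(`+`, lapply(sets[optional], function(s) as.integer(universe %in% s)))
  } else rep(0L, length(universe))
  keep <- in_req & opt_support >= min_support
  genes <- sort(universe[keep])
  total_support <- vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  structure(
    list(genes = genes, support = total_support, direction = direction,
         rule = list(required = required, min_support = min_support)),
    class = "ConsensusSignature"
  )
}

#' @export
print.ConsensusSignature <- function(x, ...) {
  cat("ConsensusSignature (", x$direction, "): ", length(x$genes),
      " genes [required: ",
      if (length(x$rule$required)) paste(x$rule$required, collapse = ",")
      else "none",
      "; min_support ", x$rule$min_support, "]\n", sep = "")
  invisible(x)
}

#' Write a consensus signature as TSV
#'
#' @param sig A `ConsensusSignature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(sig, path) {
  utils::write.table(
    data.frame(gene = sig$genes, support = unname(sig$support),
               direction = sig$direction, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
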