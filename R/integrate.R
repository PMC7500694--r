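#' Select RT-qPCR candidates from consensus genes and literature occurrences
#'
#' A consensus gene qualifies when it occurs at least once in abstracts
#' about HIV and at least once in abstracts about B cells or T cells. The
#' \code{k} qualifiers with the smallest cross-dataset mean p-value are
#' selected (ties broken by larger absolute mean fold change, then by
#' symbol).
#'
#' @param consensus consensus data.frame from [consensusFilter()]; only
#'   rows with \code{passed == TRUE} are considered.
#' @param occTables named list of \linkS4class{OccurrenceTable}s (or plain
#'   count data.frames) whose names include \code{hivLabel}, \code{bLabel}
#'   and \code{tLabel}; all consensus genes must be covered.
#' @param k number of candidates to select.
#' @param hivLabel,bLabel,tLabel names of the three corpora within
#'   \code{occTables}.
#' @return data.frame with one row per passed consensus gene: \code{gene},
#'   \code{mean_p}, \code{mean_logFC}, \code{occ_HIV}, \code{occ_B},
#'   \code{occ_T} (abstract counts), \code{qualifies} and \code{selected};
#'   sorted by ascending \code{mean_p}.
#' @export
selectCandidates <- function(consensus, occTables, k = 3,
                             hivLabel = "HIV", bLabel = "Bcell",
                             tLabel = "Tcell") {
  need <- c(hivLabel, bLabel, tLabel)
  miss <- setdiff(need, names(occTables))
  if (length(miss))
    ssStop(sprintf("occurrence table(s) missing for corpus label(s): %s",
                   paste(miss, collapse = ", ")), "configuration")
  genes <- consensus$gene[consensus$passed]
  cons <- consensus[consensus$passed, , drop = FALSE]
  getCount <- function(tab, genes) {
    cts <- if (is(tab, "OccurrenceTable")) tab@counts else tab
    i <- match(genes, cts$gene)
    if (anyNA(i))
      ssStop(sprintf("occurrence table does not cover gene(s): %s",
                     paste(genes[is.na(i)], collapse = ", ")),
             "configuration")
    cts$abstract_count[i]
  }
  out <- data.frame(gene = genes,
                    mean_p = cons$mean_p,
                    mean_logFC = cons$mean_logFC,
                    occ_HIV = getCount(occTables[[hivLabel]], genes),
                    occ_B = getCount(occTables[[bLabel]], genes),
                    occ_T = getCount(occTables[[tLabel]], genes),
                    stringsAsFactors = FALSE)
  out$qualifies <- out$occ_HIV >= 1 & (out$occ_B >= 1 | out$occ_T >= 1)
  out <- out[order(out$mean_p, -abs(out$mean_logFC), out$gene), ,
             drop = FALSE]
  out$selected <- FALSE
  qi <- which(out$qualifies)
  out$selected[utils::head(qi, k)] <- TRUE
  if (!any(out$qualifies))
    ssWarn("no consensus gene occurs in HIV and (B or T) abstracts",
           "empty")
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member...}. Duplicate members within a
#' set are removed; sets left empty are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (set members), with the
#'   descriptions attached as attribute \code{"description"}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    ssStop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]),
           "format")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, `[`, character(1), 2L)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    ssWarn(sprintf("dropping %d empty gene set(s)", sum(empty)), "empty")
    sets <- sets[!empty]; desc <- desc[!empty]
  }
  attr(sets, "description") <- desc
  sets
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For every set, tests whether the overlap with the query is larger than
#' expected by chance: \code{p = P(X >= k)} for
#' \code{X ~ Hypergeometric(N = universeN, K = set size, n = |query|)}.
#' p-values are Benjamini-Hochberg adjusted across all tested categories.
#'
#' @param query character vector of gene symbols (uppercased internally).
#' @param collection named list of gene sets (see [readGmt()]).
#' @param universeN size of the gene universe; default is the number of
#'   distinct genes in the collection.
#' @return data.frame sorted by ascending \code{q}: \code{category},
#'   \code{set_size}, \code{overlap_k}, \code{universe_N}, \code{query_n},
#'   \code{p}, \code{q}.
#' @export
overlapTest <- function(query, collection, universeN = NULL) {
  query <- unique(toupper(query))
  collection <- lapply(collection, toupper)
  if (is.null(universeN))
    universeN <- length(unique(unlist(collection, use.names = FALSE)))
  K <- lengths(collection)
  if (any(K > universeN))
    ssStop("universe smaller than a gene set", "parameter")
  if (universeN < length(query))
    ssStop("universe smaller than the query", "parameter")
  n <- length(query)
  k <- vapply(collection, function(s) length(intersect(query, s)),
              integer(1))
  ## upper tail including k itself
  p <- stats::phyper(k - 1, K, universeN - K, n, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(category = names(collection), set_size = K,
                    overlap_k = k, universe_N = universeN, query_n = n,
                    p = p, q = q, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$q, out$p, out$category), , drop = FALSE]
}
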