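#' Accessors for sexscreen classes
#'
#' \code{datasetId} returns the dataset identifier of an
#' \linkS4class{ExpressionDataset}; \code{provenance} its processing notes
#' (e.g. whether a log2 transform was applied at read time);
#' \code{probeGene} the probe-to-gene map; \code{lexiconGenes} the panel of
#' a \linkS4class{GeneLexicon}; \code{blacklist} the excluded surface forms
#' of a lexicon or matcher set; \code{occurrenceCounts} the per-gene counts
#' of an \linkS4class{OccurrenceTable}; \code{corpusLabel} a corpus or
#' table label.
#'
#' @param x an object of the documented class.
#' @return See the description; vectors or data.frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @rdname accessors
#' @export
setMethod("datasetId", "ExpressionDataset",
          function(x) metadata(x)$dataset_id)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ExpressionDataset",
          function(x) metadata(x)$provenance)

#' @rdname accessors
#' @export
setGeneric("probeGene", function(x) standardGeneric("probeGene"))
#' @rdname accessors
#' @export
setMethod("probeGene", "ExpressionDataset", function(x) {
  g <- rowData(x)$gene
  names(g) <- rownames(x)
  g
})

#' @rdname accessors
#' @export
setGeneric("lexiconGenes", function(x) standardGeneric("lexiconGenes"))
#' @rdname accessors
#' @export
setMethod("lexiconGenes", "GeneLexicon", function(x) names(x@entries))

#' @rdname accessors
#' @export
setGeneric("blacklist", function(x) standardGeneric("blacklist"))
#' @rdname accessors
#' @export
setMethod("blacklist", "GeneLexicon", function(x) x@blacklist)
#' @rdname accessors
#' @export
setMethod("blacklist", "MatcherSet", function(x) x@blacklist)

#' @rdname accessors
#' @export
setGeneric("occurrenceCounts", function(x) standardGeneric("occurrenceCounts"))
#' @rdname accessors
#' @export
setMethod("occurrenceCounts", "OccurrenceTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("corpusLabel", function(x) standardGeneric("corpusLabel"))
#' @rdname accessors
#' @export
setMethod("corpusLabel", "AbstractCorpus", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("corpusLabel", "OccurrenceTable", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("corpusRecords", function(x) standardGeneric("corpusRecords"))
#' @rdname accessors
#' @export
setMethod("corpusRecords", "AbstractCorpus", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("cqRecords", function(x) standardGeneric("cqRecords"))
#' @rdname accessors
#' @export
setMethod("cqRecords", "CqTable", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))
#' @rdname accessors
#' @export
setMethod("referenceGenes", "CqTable", function(x) x@referenceGenes)

setMethod("show", "ExpressionDataset", function(object) {
  cd <- colData(object)
  cat(sprintf("ExpressionDataset '%s': %d probes x %d samples (%d F / %d M)\n",
              datasetId(object), nrow(object), ncol(object),
              sum(cd$sex == "female"), sum(cd$sex == "male")))
  mapped <- sum(nzchar(rowData(object)$gene))
  cat(sprintf("  probes mapped to genes: %d; provenance: %s\n", mapped,
              if (length(provenance(object)))
                paste(provenance(object), collapse = "; ") else "none"))
})

setMethod("show", "GeneLexicon", function(object) {
  nf <- sum(vapply(object@entries, function(e)
    1L + length(e$alias_symbols) + length(e$previous_symbols) +
      length(e$alias_names) + as.integer(nzchar(e$approved_name)),
    integer(1)))
  cat(sprintf("GeneLexicon: %d genes, %d surface forms, %d blacklisted\n",
              length(object@entries), nf, length(object@blacklist)))
})

setMethod("show", "MatcherSet", function(object) {
  cat(sprintf("MatcherSet: %d patterns for %d genes (%d blacklisted forms)\n",
              nrow(object@patterns), length(unique(object@patterns$gene)),
              length(object@blacklist)))
})

setMethod("show", "AbstractCorpus", function(object) {
  cat(sprintf("AbstractCorpus '%s': %d abstracts\n", object@label,
              nrow(object@records)))
})

setMethod("show", "OccurrenceTable", function(object) {
  cat(sprintf("OccurrenceTable '%s': %d genes over %d abstracts\n",
              object@label, nrow(object@counts), object@corpusSize))
})

setMethod("show", "CqTable", function(object) {
  r <- object@records
  cat(sprintf("CqTable: %d wells, %d samples, %d genes (refs: %s)\n",
              nrow(r), length(unique(r$sample_id)),
              length(unique(r$gene)),
              paste(object@referenceGenes, collapse = ", ")))
})
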