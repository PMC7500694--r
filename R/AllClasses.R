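#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

#' ExpressionDataset: a sex-annotated expression matrix
#'
#' An \code{ExpressionDataset} is a thin extension of
#' \linkS4class{SummarizedExperiment} holding a probes-by-samples matrix of
#' log2 intensities (assay \code{"exprs"}), per-sample metadata (\code{sex},
#' \code{age}, \code{health} in \code{colData}), a probe-to-gene map
#' (\code{gene} in \code{rowData}; empty string for unmapped probes) and a
#' dataset identifier plus provenance notes in \code{metadata()}.
#'
#' Validity requires unique probe identifiers, \code{sex} restricted to
#' \code{"female"}/\code{"male"} (no \code{NA}), non-negative ages where
#' present, and \code{health} in \code{"healthy"}/\code{"other"}.
#'
#' @seealso [ExpressionDataset()], [readSeriesMatrix()], [filterSamples()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe ids")
  cd <- colData(object)
  req <- c("sex", "age", "health")
  miss <- setdiff(req, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (any(is.na(cd$sex)) || !all(cd$sex %in% c("female", "male")))
      msg <- c(msg, "sex must be 'female' or 'male' for every sample")
    if (any(!is.na(cd$age) & cd$age < 0))
      msg <- c(msg, "negative age")
    if (!all(cd$health %in% c("healthy", "other")))
      msg <- c(msg, "health must be 'healthy' or 'other'")
  }
  if (!"gene" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData lacks 'gene'")
  if (is.null(metadata(object)$dataset_id))
    msg <- c(msg, "metadata lacks 'dataset_id'")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of log2 intensities, probes in rows, samples
#'   in columns. Missing values are allowed and flagged in the provenance.
#' @param probeIds character vector of unique probe identifiers (defaults to
#'   \code{rownames(values)}).
#' @param sampleData data.frame with one row per sample: \code{sample_id},
#'   \code{sex} ("female"/"male"), \code{age} (years, may be NA),
#'   \code{health} ("healthy"/"other").
#' @param probeGene character vector mapping each probe to a gene symbol
#'   ("" for unmapped), or a named vector indexed by probe id.
#' @param datasetId character scalar.
#' @param provenance character vector of free-text processing notes.
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' sd <- data.frame(sample_id = colnames(m),
#'                  sex = c("female", "female", "male", "male"),
#'                  age = c(25L, 30L, 28L, 33L), health = "healthy")
#' ExpressionDataset(m, sampleData = sd, probeGene = c("A", "B", "B"),
#'                   datasetId = "toy")
#' @export
ExpressionDataset <- function(values, probeIds = rownames(values), sampleData,
                              probeGene = NULL, datasetId = "dataset",
                              provenance = character()) {
  values <- as.matrix(values)
  if (is.null(probeIds))
    ssStop("probe ids are required", "input")
  if (nrow(values) != length(probeIds))
    ssStop("matrix row count does not match probe id count", "consistency")
  if (nrow(sampleData) != ncol(values))
    ssStop(sprintf(
      "sample metadata rows (%d) do not match matrix columns (%d)",
      nrow(sampleData), ncol(values)), "consistency")
  if (is.null(probeGene)) probeGene <- rep("", length(probeIds))
  if (!is.null(names(probeGene))) {
    probeGene <- unname(probeGene[probeIds])
    probeGene[is.na(probeGene)] <- ""
  }
  if (length(probeGene) != length(probeIds))
    ssStop("probeGene length does not match probes", "consistency")
  rownames(values) <- probeIds
  colnames(values) <- sampleData$sample_id
  if (anyNA(values))
    provenance <- c(provenance,
                    sprintf("missing_values=%d", sum(is.na(values))))
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    rowData = DataFrame(gene = as.character(probeGene),
                        row.names = probeIds),
    colData = DataFrame(sample_id = sampleData$sample_id,
                        sex = as.character(sampleData$sex),
                        age = as.integer(sampleData$age),
                        health = as.character(sampleData$health),
                        row.names = sampleData$sample_id))
  metadata(se)$dataset_id <- datasetId
  metadata(se)$provenance <- provenance
  new("ExpressionDataset", se)
}

#' GeneLexicon: HGNC-derived surface forms for a gene panel
#'
#' Holds, per approved gene symbol, the approved name plus alias and previous
#' symbols/names, and a blacklist of surface forms excluded from matching
#' (too short, ambiguous across genes, or stop-listed English homonyms).
#'
#' @slot entries named list; one element per gene with components
#'   \code{approved_name}, \code{alias_symbols}, \code{previous_symbols},
#'   \code{alias_names} (character vectors).
#' @slot blacklist character vector of excluded surface forms.
#' @seealso [loadHgncLexicon()], [compileMatchers()]
#' @export
setClass("GeneLexicon",
         representation(entries = "list", blacklist = "character"))

setValidity("GeneLexicon", function(object) {
  if (anyDuplicated(names(object@entries))) return("duplicate gene symbols")
  ok <- vapply(object@entries, function(e)
    all(c("approved_name", "alias_symbols", "previous_symbols",
          "alias_names") %in% names(e)), logical(1))
  if (!all(ok)) return("malformed lexicon entry")
  TRUE
})

#' MatcherSet: compiled dictionary patterns
#'
#' Compiled regular-expression matchers for every non-blacklisted surface
#' form in a \linkS4class{GeneLexicon}. Symbol-like forms (no internal
#' spaces) are case-sensitive whole-token patterns; name-like forms are
#' case-insensitive phrase patterns tolerant of hyphen/whitespace
#' interchange.
#'
#' @slot patterns data.frame with columns \code{gene}, \code{form},
#'   \code{pattern} (PCRE), \code{type} ("symbol"/"name").
#' @slot blacklist character vector of forms that were excluded.
#' @export
setClass("MatcherSet",
         representation(patterns = "data.frame", blacklist = "character"))

setValidity("MatcherSet", function(object) {
  need <- c("gene", "form", "pattern", "type")
  if (!all(need %in% colnames(object@patterns)))
    return("patterns must have gene/form/pattern/type")
  TRUE
})

#' AbstractCorpus: a labelled set of abstracts
#'
#' @slot label character scalar, e.g. \code{"HIV"}.
#' @slot records data.frame with columns \code{pmid} (unique) and
#'   \code{text} (title + abstract, non-empty).
#' @seealso [readMedline()], [simCorpus()]
#' @export
setClass("AbstractCorpus",
         representation(label = "character", records = "data.frame"))

setValidity("AbstractCorpus", function(object) {
  r <- object@records
  if (!all(c("pmid", "text") %in% colnames(r)))
    return("records must have pmid and text")
  if (anyDuplicated(r$pmid)) return("duplicate pmids")
  if (nrow(r) && any(!nzchar(r$text))) return("empty abstract text")
  TRUE
})

#' AbstractCorpus constructor
#' @param label corpus label (e.g. "HIV", "Bcell", "Tcell").
#' @param pmid character vector of unique record identifiers.
#' @param text character vector of titles + abstracts.
#' @return An \linkS4class{AbstractCorpus}.
#' @export
AbstractCorpus <- function(label, pmid, text) {
  new("AbstractCorpus", label = as.character(label),
      records = data.frame(pmid = as.character(pmid),
                           text = as.character(text)))
}

#' OccurrenceTable: gene mentions per corpus
#'
#' @slot label corpus label.
#' @slot counts data.frame with columns \code{gene}, \code{abstract_count}
#'   (abstracts with at least one mention) and \code{mention_count} (total
#'   non-overlapping mentions).
#' @slot detail integer matrix, genes x abstracts, of mention counts.
#' @slot corpusSize number of abstracts searched.
#' @seealso [countOccurrences()]
#' @export
setClass("OccurrenceTable",
         representation(label = "character", counts = "data.frame",
                        detail = "matrix", corpusSize = "integer"))

setValidity("OccurrenceTable", function(object) {
  cts <- object@counts
  if (!all(c("gene", "abstract_count", "mention_count") %in% colnames(cts)))
    return("counts must have gene/abstract_count/mention_count")
  if (any(cts$abstract_count < 0) || any(cts$abstract_count > object@corpusSize))
    return("abstract_count out of [0, corpus size]")
  bad <- cts$abstract_count > 0 & cts$mention_count < cts$abstract_count
  if (any(bad)) return("mention_count below abstract_count")
  TRUE
})

#' CqTable: long-format qPCR quantification cycles
#'
#' @slot records data.frame with columns \code{sample_id}, \code{gene},
#'   \code{replicate}, \code{cq} (cycles, > 0).
#' @slot efficiencies named numeric, amplification factor per cycle per gene
#'   (in (1, 2]; genes absent from the map default to 2.0 with a warning).
#' @slot referenceGenes character, housekeeping genes used for
#'   normalization (e.g. HPRT1, HMBS); each must be measured in every sample.
#' @seealso [readCqTable()], [qbaseNRQ()]
#' @export
setClass("CqTable",
         representation(records = "data.frame", efficiencies = "numeric",
                        referenceGenes = "character"))

setValidity("CqTable", function(object) {
  r <- object@records
  if (!all(c("sample_id", "gene", "replicate", "cq") %in% colnames(r)))
    return("records must have sample_id/gene/replicate/cq")
  if (any(!is.finite(r$cq)) || any(r$cq <= 0)) return("cq must be > 0")
  if (length(object@efficiencies)) {
    e <- object@efficiencies
    if (any(e <= 1 | e > 2)) return("efficiencies must lie in (1, 2]")
  }
  if (!length(object@referenceGenes))
    return("at least one reference gene is required")
  samples <- unique(r$sample_id)
  for (g in object@referenceGenes) {
    have <- unique(r$sample_id[r$gene == g])
    if (length(setdiff(samples, have)))
      return(sprintf("reference gene %s missing for sample(s) %s", g,
                     paste(setdiff(samples, have), collapse = ", ")))
  }
  TRUE
})

#' CqTable constructor
#'
#' @param records data.frame with \code{sample_id}, \code{gene},
#'   \code{replicate}, \code{cq}.
#' @param efficiencies named numeric vector of per-gene amplification
#'   factors; unlisted genes default to 2.0 (100\% efficiency) at
#'   quantification time.
#' @param referenceGenes character vector of housekeeping genes.
#' @return A \linkS4class{CqTable}.
#' @export
CqTable <- function(records, efficiencies = numeric(),
                    referenceGenes = c("HPRT1", "HMBS")) {
  records$sample_id <- as.character(records$sample_id)
  records$gene <- as.character(records$gene)
  new("CqTable", records = as.data.frame(records),
      efficiencies = efficiencies,
      referenceGenes = as.character(referenceGenes))
}
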