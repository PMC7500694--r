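#' Read an abstract corpus from MEDLINE text or a PMID+text TSV
#'
#' The MEDLINE dialect uses 4-letter tags padded to a hyphen at column 5
#' (\code{PMID- }, \code{TI  - }, \code{AB  - }) with continuation lines
#' indented by spaces; title and abstract are concatenated with one space,
#' and records lacking an abstract are kept with the title only. A file
#' whose first line contains a tab and no MEDLINE tag is read as a
#' two-column TSV (pmid, text) instead, with an optional header line.
#'
#' @param path path to the corpus file.
#' @param label corpus label (e.g. \code{"HIV"}); defaults to the file
#'   name without extension.
#' @return An \linkS4class{AbstractCorpus}.
#' @export
readMedline <- function(path, label = NULL) {
  if (!file.exists(path))
    ssStop(sprintf("file not found: %s", path), "input")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  isMedline <- any(grepl("^PMID- ", lines))
  if (isMedline) {
    recs <- parseMedlineLines(lines)
  } else {
    recs <- parseCorpusTsv(lines)
  }
  if (!nrow(recs))
    ssStop(sprintf("no parseable abstract records in %s", path), "format")
  AbstractCorpus(label, recs$pmid, recs$text)
}

parseMedlineLines <- function(lines) {
  pmid <- ti <- ab <- character()
  cur <- list()
  field <- ""
  flush <- function(cur, pmid, ti, ab) {
    if (!is.null(cur$PMID)) {
      pmid <- c(pmid, squishWs(cur$PMID))
      ti <- c(ti, if (is.null(cur$TI)) "" else squishWs(cur$TI))
      ab <- c(ab, if (is.null(cur$AB)) "" else squishWs(cur$AB))
    }
    list(pmid = pmid, ti = ti, ab = ab)
  }
  for (ln in lines) {
    if (grepl("^PMID- ", ln)) {
      st <- flush(cur, pmid, ti, ab)
      pmid <- st$pmid; ti <- st$ti; ab <- st$ab
      cur <- list(PMID = sub("^PMID- ", "", ln))
      field <- "PMID"
    } else if (grepl("^[A-Z]{1,4}\\s*- ", ln)) {
      field <- sub("^([A-Z]{1,4})\\s*- .*$", "\\1", ln)
      val <- sub("^[A-Z]{1,4}\\s*- ", "", ln)
      cur[[field]] <- if (is.null(cur[[field]])) val else
        paste(cur[[field]], val)
    } else if (grepl("^\\s+\\S", ln) && nzchar(field)) {
      cur[[field]] <- paste(cur[[field]], squishWs(ln))
    }
  }
  st <- flush(cur, pmid, ti, ab)
  text <- squishWs(paste(st$ti, st$ab))
  keep <- nzchar(st$pmid) & nzchar(text)
  data.frame(pmid = st$pmid[keep], text = text[keep],
             stringsAsFactors = FALSE)
}

parseCorpusTsv <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !any(grepl("\t", lines)))
    return(data.frame(pmid = character(), text = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- lengths(parts) >= 2
  parts <- parts[keep]
  pmid <- vapply(parts, `[`, character(1), 1L)
  text <- vapply(parts, function(p)
    squishWs(paste(p[-1], collapse = " ")), character(1))
  ## tolerate a header line
  if (length(pmid) && tolower(pmid[1]) %in% c("pmid", "id")) {
    pmid <- pmid[-1]; text <- text[-1]
  }
  keep2 <- nzchar(pmid) & nzchar(text)
  data.frame(pmid = pmid[keep2], text = text[keep2],
             stringsAsFactors = FALSE)
}

## Per-gene, per-abstract mention counts. Overlapping matches of different
## surface forms of one gene are resolved longest-match-first, then
## leftmost, so each text span is counted at most once per gene.
matchDetail <- function(corpus, matchers) {
  texts <- corpus@records$text
  pat <- matchers@patterns
  genes <- sort(unique(pat$gene))
  detail <- matrix(0L, length(genes), length(texts),
                   dimnames = list(genes, corpus@records$pmid))
  ## collect all matches per pattern over the whole corpus (vectorized)
  hits <- vector("list", nrow(pat))
  for (i in seq_len(nrow(pat))) {
    m <- gregexpr(pat$pattern[i], texts, perl = TRUE)
    hits[[i]] <- m
  }
  for (j in seq_along(texts)) {
    byGene <- list()
    for (i in seq_len(nrow(pat))) {
      m <- hits[[i]][[j]]
      if (m[1] == -1L) next
      g <- pat$gene[i]
      byGene[[g]] <- rbind(byGene[[g]],
                           cbind(start = as.integer(m),
                                 len = attr(m, "match.length")))
    }
    for (g in names(byGene)) {
      iv <- byGene[[g]]
      ord <- order(-iv[, "len"], iv[, "start"])
      iv <- iv[ord, , drop = FALSE]
      taken <- matrix(numeric(0), 0, 2)
      n <- 0L
      for (r in seq_len(nrow(iv))) {
        s <- iv[r, "start"]; e <- s + iv[r, "len"] - 1L
        if (!nrow(taken) ||
            all(e < taken[, 1] | s > taken[, 2])) {
          taken <- rbind(taken, c(s, e))
          n <- n + 1L
        }
      }
      detail[g, j] <- n
    }
  }
  detail
}

#' Count gene occurrences in an abstract corpus
#'
#' Scans every abstract with the compiled matchers and aggregates, per
#' gene: the number of abstracts containing at least one mention
#' (\code{abstract_count}) and the total number of non-overlapping mentions
#' (\code{mention_count}). Overlapping matches from different surface forms
#' of the same gene count once (longest match wins, then leftmost).
#'
#' @param corpus an \linkS4class{AbstractCorpus}.
#' @param matchers a \linkS4class{MatcherSet}.
#' @return An \linkS4class{OccurrenceTable}.
#' @export
countOccurrences <- function(corpus, matchers) {
  if (!nrow(corpus@records))
    ssStop("corpus is empty", "input")
  detail <- matchDetail(corpus, matchers)
  counts <- data.frame(gene = rownames(detail),
                       abstract_count = as.integer(rowSums(detail > 0)),
                       mention_count = as.integer(rowSums(detail)),
                       stringsAsFactors = FALSE)
  new("OccurrenceTable", label = corpus@label, counts = counts,
      detail = detail, corpusSize = nrow(corpus@records))
}

#' Evaluate the dictionary matcher against gold annotations
#'
#' Scores abstract-level presence/absence per (gene, abstract) pair against
#' gold labels and reports the confusion counts, sensitivity
#' \code{tp / (tp + fn)} and specificity \code{tn / (tn + fp)}.
#'
#' @param corpus an \linkS4class{AbstractCorpus}.
#' @param gold data.frame with columns \code{pmid}, \code{gene},
#'   \code{is_mentioned} (logical); every scored pair must be covered.
#' @param matchers a \linkS4class{MatcherSet}.
#' @return list with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{sensitivity}, \code{specificity}.
#' @export
evaluateMatcher <- function(corpus, gold, matchers) {
  if (is.null(gold) || !nrow(gold))
    ssStop("gold annotation set is empty", "input")
  occ <- countOccurrences(corpus, matchers)
  detail <- occ@detail
  pred <- detail[cbind(match(gold$gene, rownames(detail)),
                       match(gold$pmid, colnames(detail)))] > 0
  if (anyNA(pred))
    ssStop("gold labels reference genes/abstracts outside the corpus",
           "input")
  truth <- as.logical(gold$is_mentioned)
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
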