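#' Default stop list of homonym-prone surface forms
#'
#' Gene symbols and aliases that double as common English words or
#' ubiquitous biomedical abbreviations produce large numbers of spurious
#' dictionary matches in abstracts. This conservative default list is
#' applied (on top of the automatic length and ambiguity rules) whenever a
#' lexicon is loaded; it can be extended or replaced via the
#' \code{stopWords} / \code{extraBlacklist} arguments.
#'
#' @return character vector of surface forms.
#' @export
defaultStopWords <- function() {
  c("ACT", "AIM", "ALL", "ANOVA", "ARM", "CAMP", "CAN", "CELL", "CO2",
    "DNA", "FACT", "FATE", "FOR", "GC", "HIV", "HR", "IMPACT", "LARGE",
    "MASS", "MEN", "MICE", "NOT", "OUT", "PCR", "RNA", "SET", "TYPE",
    "UP", "WAS", "WHO")
}

## Split an HGNC-style list field: pipe-separated, optionally quoted
## ('"A", "B"' dialect also accepted). Returns a trimmed character vector.
parseListField <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  if (grepl("|", x, fixed = TRUE)) {
    parts <- strsplit(x, "|", fixed = TRUE)[[1]]
  } else if (grepl('",', x, fixed = TRUE)) {
    parts <- strsplit(x, '",\\s*"')[[1]]
  } else {
    parts <- x
  }
  parts <- squishWs(gsub('^"|"$', "", parts))
  parts[nzchar(parts)]
}

#' Load an HGNC nomenclature table into a gene lexicon
#'
#' Reads a tab-separated HGNC download (columns for approved symbol,
#' approved name, alias symbols, previous symbols and alias names; list
#' fields pipe- or quote-delimited), restricts it to the requested genes
#' and assembles the surface-form dictionary. Forms shorter than
#' \code{minLength} characters, forms on the stop list, and forms shared by
#' more than one gene of the panel are blacklisted automatically (the
#' latter with a warning).
#'
#' @param path path to the HGNC TSV (a header line is required; column
#'   names are matched case-insensitively against \code{columns}).
#' @param genes character vector of approved symbols to retain.
#' @param columns named character vector mapping the roles
#'   \code{symbol}, \code{name}, \code{alias_symbol}, \code{prev_symbol},
#'   \code{alias_name} to column names in the file.
#' @param stopWords surface forms excluded from matching a priori.
#' @param minLength minimum surface-form length (shorter forms are
#'   blacklisted).
#' @return A \linkS4class{GeneLexicon}.
#' @export
loadHgncLexicon <- function(path, genes,
                            columns = c(symbol = "symbol",
                                        name = "name",
                                        alias_symbol = "alias_symbol",
                                        prev_symbol = "prev_symbol",
                                        alias_name = "alias_name"),
                            stopWords = defaultStopWords(),
                            minLength = 2) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, quote = "")
  cn <- tolower(colnames(tab))
  idx <- match(tolower(columns), cn)
  if (is.na(idx[1]))
    ssStop(sprintf("column '%s' not found in %s", columns[["symbol"]], path),
           "format")
  sym <- squishWs(tab[[idx[1]]])
  hit <- match(genes, sym)
  if (anyNA(hit))
    ssStop(sprintf("gene(s) not found in HGNC table: %s",
                   paste(genes[is.na(hit)], collapse = ", ")), "lookup")
  getCol <- function(k, i) {
    if (is.na(idx[k])) return("")
    tab[[idx[k]]][i]
  }
  entries <- lapply(seq_along(genes), function(g) {
    i <- hit[g]
    list(approved_name = squishWs(getCol(2L, i)),
         alias_symbols = parseListField(getCol(3L, i)),
         previous_symbols = parseListField(getCol(4L, i)),
         alias_names = parseListField(getCol(5L, i)))
  })
  names(entries) <- genes
  buildLexicon(entries, stopWords = stopWords, minLength = minLength)
}

## Shared blacklist logic for loadHgncLexicon and hand-built lexicons:
## short forms, stop-listed forms, and forms ambiguous across genes.
buildLexicon <- function(entries, stopWords = defaultStopWords(),
                         minLength = 2) {
  forms <- lapply(entries, function(e)
    unique(c(e$alias_symbols, e$previous_symbols, e$alias_names,
             if (nzchar(e$approved_name)) e$approved_name)))
  allForms <- data.frame(
    gene = rep(c(names(entries), names(entries)),
               c(rep(1L, length(entries)), lengths(forms))),
    form = c(names(entries), unlist(forms, use.names = FALSE)),
    stringsAsFactors = FALSE)
  key <- ifelse(grepl(" ", allForms$form), tolower(allForms$form),
                allForms$form)
  short <- unique(allForms$form[nchar(allForms$form) < minLength])
  stopped <- unique(allForms$form[key %in% c(stopWords, tolower(stopWords)) |
                                    allForms$form %in% stopWords])
  dupKeys <- unique(key[duplicated(paste(key))])
  ambiguous <- character()
  for (k in dupKeys) {
    g <- unique(allForms$gene[key == k])
    if (length(g) > 1) ambiguous <- c(ambiguous, unique(allForms$form[key == k]))
  }
  if (length(ambiguous))
    ssWarn(sprintf("blacklisting %d ambiguous form(s) shared across genes: %s",
                   length(ambiguous),
                   paste(utils::head(ambiguous, 10), collapse = ", ")),
           "ambiguous")
  bl <- unique(c(short, stopped, ambiguous))
  new("GeneLexicon", entries = entries, blacklist = bl)
}

#' Build a gene lexicon directly from R objects
#'
#' Convenience constructor used in tests and simulations; applies the same
#' automatic blacklisting rules as [loadHgncLexicon()].
#'
#' @param entries named list (one element per gene) of lists with
#'   \code{approved_name}, \code{alias_symbols}, \code{previous_symbols},
#'   \code{alias_names}.
#' @inheritParams loadHgncLexicon
#' @return A \linkS4class{GeneLexicon}.
#' @export
GeneLexicon <- function(entries, stopWords = defaultStopWords(),
                        minLength = 2) {
  entries <- lapply(entries, function(e) {
    defaults <- list(approved_name = "", alias_symbols = character(),
                     previous_symbols = character(),
                     alias_names = character())
    defaults[names(e)] <- e
    defaults
  })
  buildLexicon(entries, stopWords = stopWords, minLength = minLength)
}

#' All surface forms of a lexicon
#'
#' @param lexicon a \linkS4class{GeneLexicon}.
#' @param includeBlacklisted keep blacklisted forms in the output?
#' @return data.frame with columns \code{gene}, \code{form}, \code{type}
#'   ("symbol" for space-free forms, "name" for multi-word forms) and
#'   \code{blacklisted}.
#' @export
lexiconForms <- function(lexicon, includeBlacklisted = TRUE) {
  e <- lexicon@entries
  rows <- lapply(names(e), function(g) {
    f <- unique(c(g, e[[g]]$alias_symbols, e[[g]]$previous_symbols,
                  if (nzchar(e[[g]]$approved_name)) e[[g]]$approved_name,
                  e[[g]]$alias_names))
    data.frame(gene = g, form = f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$type <- ifelse(grepl(" ", out$form), "name", "symbol")
  out$blacklisted <- out$form %in% lexicon@blacklist
  if (!includeBlacklisted) out <- out[!out$blacklisted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compile dictionary matchers from a lexicon
#'
#' Symbol-like forms (no internal whitespace) become case-sensitive
#' whole-token patterns: the form may contain hyphens and digits, and both
#' token boundaries must be non-alphanumeric, so \code{DPP4} matches
#' \code{"(DPP4)"} and \code{"DPP4-positive"} but not \code{"ADPP4X"}.
#' Name-like forms (with internal whitespace) become case-insensitive
#' phrase patterns in which hyphens and whitespace are interchangeable.
#' The lexicon blacklist plus \code{extraBlacklist} is applied last.
#'
#' @param lexicon a \linkS4class{GeneLexicon}.
#' @param extraBlacklist additional surface forms to exclude.
#' @return A \linkS4class{MatcherSet}.
#' @export
compileMatchers <- function(lexicon, extraBlacklist = character()) {
  forms <- lexiconForms(lexicon, includeBlacklisted = TRUE)
  bl <- unique(c(lexicon@blacklist, extraBlacklist))
  blKey <- c(bl, tolower(bl))
  keep <- !(forms$form %in% blKey) &
    !(ifelse(forms$type == "name", tolower(forms$form), forms$form) %in% blKey)
  forms <- forms[keep, , drop = FALSE]
  if (!nrow(forms))
    ssStop("no matchable surface forms remain after blacklisting",
           "configuration")
  esc <- function(x) gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", x,
                          perl = TRUE)
  forms$pattern <- vapply(seq_len(nrow(forms)), function(i) {
    f <- forms$form[i]
    if (forms$type[i] == "symbol") {
      paste0("(?<![A-Za-z0-9])", esc(f), "(?![A-Za-z0-9])")
    } else {
      toks <- strsplit(f, "[\\s-]+", perl = TRUE)[[1]]
      paste0("(?i)(?<![A-Za-z0-9])",
             paste(vapply(toks, esc, character(1)), collapse = "[\\s-]+"),
             "(?![A-Za-z0-9])")
    }
  }, character(1))
  new("MatcherSet",
      patterns = forms[, c("gene", "form", "pattern", "type")],
      blacklist = bl)
}
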