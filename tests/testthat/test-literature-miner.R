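test_that("HGNC lexicon loads requested genes with aliases and auto-blacklists", {
  lex <- suppressWarnings(loadHgncLexicon(panelPath(), genes = c("DPP4")))
  expect_s4_class(lex, "GeneLexicon")
  expect_identical(lexiconGenes(lex), "DPP4")
  expect_true("CD26" %in% lex@entries$DPP4$alias_symbols)
  expect_identical(lex@entries$DPP4$approved_name, "dipeptidyl peptidase 4")

  ## a form shared by two genes is blacklisted with a warning
  expect_warning(
    lexAll <- loadHgncLexicon(panelPath(), genes = panelGenes()),
    class = "sexscreen_ambiguous_warning")
  expect_true("MGC9999" %in% blacklist(lexAll))
  ## stop-listed English-word symbol is blacklisted too
  expect_true("CAMP" %in% blacklist(lexAll))

  expect_error(loadHgncLexicon(panelPath(), genes = "NOTAGENE"),
               class = "sexscreen_lookup_error")
})

test_that("short and hand-blacklisted forms never match", {
  lex <- GeneLexicon(list(
    GENEA = list(alias_symbols = c("X", "AB12")),
    CAMP = list(approved_name = "cathelicidin antimicrobial peptide")))
  expect_true("X" %in% blacklist(lex))     # shorter than 2 characters
  expect_true("CAMP" %in% blacklist(lex))  # default stop list
  ms <- compileMatchers(lex)
  expect_false("X" %in% ms@patterns$form)
  expect_false("CAMP" %in% ms@patterns$form)
  corpus <- AbstractCorpus("t", "1", "cAMP signaling and CAMP were studied; X marks AB12.")
  occ <- occurrenceCounts(countOccurrences(corpus, ms))
  expect_identical(occ$mention_count[occ$gene == "CAMP"], 0L)  # symbol stop-listed
  expect_identical(occ$mention_count[occ$gene == "GENEA"], 1L) # AB12 only, not X
})

test_that("symbol matchers are case-sensitive whole tokens; name matchers tolerate hyphens and case", {
  lex <- GeneLexicon(list(
    DPP4 = list(approved_name = "dipeptidyl peptidase 4",
                alias_symbols = "CD26")))
  ms <- compileMatchers(lex)
  hit <- function(txt) {
    occ <- countOccurrences(AbstractCorpus("t", "1", txt), ms)
    occ@counts$mention_count[occ@counts$gene == "DPP4"]
  }
  expect_identical(hit("Inhibition of DPP4 was tested."), 1L)
  expect_identical(hit("the (DPP4) protease"), 1L)
  expect_identical(hit("DPP4-positive cells"), 1L)
  expect_identical(hit("the ADPP4X construct"), 0L)
  expect_identical(hit("dpp4 lowercase symbol"), 0L)
  expect_identical(hit("Dipeptidyl-peptidase 4 activity"), 1L)
  expect_identical(hit("DIPEPTIDYL PEPTIDASE 4 was measured"), 1L)
  ## overlapping surface forms of one gene count once; distinct spans add up
  expect_identical(hit("DPP4 (CD26) cleaves CCL5"), 2L)
})

test_that("occurrence counting matches hand-annotated fixtures", {
  lex <- GeneLexicon(list(
    DPP4 = list(approved_name = "dipeptidyl peptidase 4",
                alias_symbols = "CD26"),
    SOCS3 = list(approved_name = "suppressor of cytokine signaling 3",
                 alias_symbols = "CIS3")))
  ms <- compileMatchers(lex)
  texts <- c(
    "DPP4 (CD26) cleaves chemokines.",          # DPP4 x2
    "CD26 is dipeptidyl peptidase 4.",          # DPP4 x2
    "SOCS3 inhibits signaling.",                # SOCS3 x1
    "Suppressor of cytokine signaling 3 (SOCS3, CIS3) acts on STAT.",  # SOCS3 x3
    "No gene here.",
    "the ADPP4X and socs3 decoys",              # nothing (boundary/case)
    "DPP4 with SOCS3 together.",                # one each
    "CD26+ T cells expand.",                    # DPP4 x1
    "cis3 lowercase does not count.",
    "CIS3 and SOCS3 and CIS3 again.")           # SOCS3 x3
  corpus <- AbstractCorpus("mix", sprintf("A%02d", 1:10), texts)
  occ <- countOccurrences(corpus, ms)
  cts <- occurrenceCounts(occ)
  expect_identical(cts$abstract_count[cts$gene == "DPP4"], 4L)
  expect_identical(cts$mention_count[cts$gene == "DPP4"], 6L)
  expect_identical(cts$abstract_count[cts$gene == "SOCS3"], 4L)
  expect_identical(cts$mention_count[cts$gene == "SOCS3"], 8L)
  expect_identical(occ@corpusSize, 10L)
})

test_that("MEDLINE and TSV corpus dialects parse; empty input is a format error", {
  f <- tempfile(fileext = ".txt")
  writeLines(c(
    "PMID- 101",
    "TI  - DPP4 in T cells.",
    "AB  - We studied dipeptidyl peptidase 4 in",
    "      activated lymphocytes.",
    "",
    "PMID- 102",
    "TI  - A title-only record."), f)
  corpus <- readMedline(f, label = "HIV")
  r <- corpusRecords(corpus)
  expect_identical(nrow(r), 2L)
  expect_identical(corpusLabel(corpus), "HIV")
  expect_match(r$text[r$pmid == "101"],
               "DPP4 in T cells. We studied dipeptidyl peptidase 4 in activated lymphocytes.",
               fixed = TRUE)
  expect_identical(r$text[r$pmid == "102"], "A title-only record.")

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("pmid\ttext", "201\tSOCS3 signaling.", "202\tNothing."), f2)
  corpus2 <- readMedline(f2)
  expect_identical(corpusRecords(corpus2)$pmid, c("201", "202"))

  f3 <- tempfile()
  writeLines(character(), f3)
  expect_error(readMedline(f3), class = "sexscreen_format_error")
})

test_that("matcher evaluation computes the abstract-level confusion", {
  lex <- GeneLexicon(list(DPP4 = list(alias_symbols = "CD26")))
  ms <- compileMatchers(lex)
  corpus <- AbstractCorpus("t", c("1", "2", "3"),
                           c("DPP4 here.", "nothing", "also nothing"))
  gold <- data.frame(pmid = c("1", "2", "3"), gene = "DPP4",
                     is_mentioned = c(TRUE, FALSE, FALSE))
  ev <- evaluateMatcher(corpus, gold, ms)
  expect_identical(ev[c("tp", "fp", "tn", "fn")],
                   list(tp = 1L, fp = 0L, tn = 2L, fn = 0L))
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)

  ## a matcher that cannot fire on this corpus: sensitivity 0,
  ## specificity 1 (gold knows of a mention the dictionary cannot see)
  corpus2 <- AbstractCorpus("t", c("1", "2", "3"),
                            c("the dipeptidylpeptidase is discussed",
                              "nothing", "also nothing"))
  gold2 <- data.frame(pmid = c("1", "2", "3"), gene = "DPP4",
                      is_mentioned = c(TRUE, FALSE, FALSE))
  ev2 <- evaluateMatcher(corpus2, gold2, ms)
  expect_equal(ev2$sensitivity, 0.0)
  expect_equal(ev2$specificity, 1.0)

  expect_error(evaluateMatcher(corpus, gold[0, ], ms),
               class = "sexscreen_input_error")
})

test_that("occurrence tables are deterministic, order-invariant and monotone", {
  lex <- loadPanelLexicon()
  ms <- compileMatchers(lex)
  bench <- simCorpus(lex, nPositive = 60, nNegative = 60, seed = 5)
  occ1 <- countOccurrences(bench$corpus, ms)
  occ2 <- countOccurrences(bench$corpus, ms)
  expect_identical(occ1@detail, occ2@detail)

  ## shuffling record order leaves the counts unchanged
  r <- corpusRecords(bench$corpus)
  set.seed(1)
  idx <- sample(nrow(r))
  shuf <- AbstractCorpus("b", r$pmid[idx], r$text[idx])
  occ3 <- countOccurrences(shuf, ms)
  expect_identical(occurrenceCounts(occ3)[order(occurrenceCounts(occ3)$gene), ],
                   occurrenceCounts(occ1)[order(occurrenceCounts(occ1)$gene), ])

  ## adding an abstract never decreases abstract counts
  r2 <- rbind(r, data.frame(pmid = "EXTRA1", text = "DPP4 was measured."))
  occ4 <- countOccurrences(AbstractCorpus("b", r2$pmid, r2$text), ms)
  expect_true(all(occurrenceCounts(occ4)$abstract_count >=
                    occurrenceCounts(occ1)$abstract_count))

  ## adding a blacklist entry never increases any count; blacklisting
  ## every surface form of a gene silences it completely
  dpp4Forms <- lexiconForms(lex)
  dpp4Forms <- dpp4Forms$form[dpp4Forms$gene == "DPP4"]
  ms2 <- compileMatchers(lex, extraBlacklist = dpp4Forms)
  occ5 <- countOccurrences(bench$corpus, ms2)
  c1 <- occurrenceCounts(occ1)
  c5 <- occurrenceCounts(occ5)
  expect_true(all(c5$mention_count <= c1$mention_count[match(c5$gene,
                                                             c1$gene)]))
  ## with every surface form blacklisted the gene drops out of the matcher
  expect_false("DPP4" %in% c5$gene)
})
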