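#' Write a data.frame as a TSV
#'
#' Plain tab-separated output without quoting or row names; the dialect the
#' package's readers and downstream tools accept.
#'
#' @param x data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an abstract corpus as a PMID+text TSV
#' @param corpus an \linkS4class{AbstractCorpus}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCorpusTsv <- function(corpus, path) {
  r <- corpus@records
  writeLines(c("pmid\ttext", paste(r$pmid, gsub("\t", " ", r$text),
                                   sep = "\t")), path)
  invisible(path)
}

#' Write a CqTable as a long-format TSV
#' @param cq a \linkS4class{CqTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCqTsv <- function(cq, path) {
  writeTsv(cq@records, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Returns the full RunConfig as a named list, with every threshold at its
#' documented default. Fields supplied in \code{...} (or loaded from a YAML
#' file via [readRunConfig()]) override the defaults.
#'
#' @param ... overrides, e.g. \code{series = c("a.txt", "b.txt")}.
#' @return named list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    series = character(),          # series-matrix paths
    annotations = NULL,            # optional parallel probe->gene TSVs
    min_age = 17, max_age = 43, min_per_sex = 10,
    p_strict = 0.01, p_loose = 0.05, min_strict = 2,
    hgnc = NULL,                   # HGNC nomenclature TSV
    corpora = list(),              # named label -> corpus path (HIV/Bcell/Tcell)
    extra_blacklist = character(),
    k = 3,
    gmt = NULL, universe_n = NULL,
    cq = NULL, reference_genes = c("HPRT1", "HMBS"),
    efficiencies = list(),
    cohort = NULL,
    compare = list(),              # list of list(measure=, group=)
    correlate = list(),            # list of c(measure_x, measure_y)
    stratify_by_sex = TRUE,
    exact_limit = 30,
    seed = 1,
    out_dir = "sexscreen_out",
    resume = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a RunConfig from a YAML file
#' @param path YAML file with (a subset of) the [runConfig()] fields.
#' @return named list (defaults filled in).
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

stageFile <- function(outDir, stage, name) {
  d <- file.path(outDir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  file.path(d, name)
}

#' Run the full discovery pipeline
#'
#' Executes, in order: \emph{screen} (read series matrices, apply the
#' inclusion filter, moderated-t contrast, probe collapse, consensus
#' filter), \emph{mine} (lexicon + occurrence counting over the configured
#' corpora), \emph{integrate} (HIV and B-or-T qualification, mean-p
#' ranking), and, when the corresponding inputs are configured, \emph{go}
#' (gene-set overlap), \emph{qpcr} (qBase NRQ) and \emph{stats} (cohort
#' comparisons/correlations). Each stage writes its TSVs under
#' \code{<out_dir>/<stage>/}; a manifest with configuration hash and
#' per-stage row counts is written to \code{<out_dir>/manifest.yaml}.
#' With \code{resume = TRUE}, stages whose outputs already exist are
#' skipped. A failing stage aborts with an error naming the stage.
#'
#' @param config a list from [runConfig()]/[readRunConfig()], or a path to
#'   a YAML config file.
#' @return the manifest, invisibly (list with elements \code{stages},
#'   \code{config_hash}, \code{outputs}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- do.call(runConfig, config)
  outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  cfgHash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(package = as.character(utils::packageVersion("sexscreen")),
                   config_hash = cfgHash, stages = list())
  outputs <- character()

  runStage <- function(stage, outFiles, fun) {
    paths <- vapply(outFiles, function(f) stageFile(outDir, stage, f),
                    character(1))
    if (cfg$resume && all(file.exists(paths))) {
      manifest$stages[[stage]] <<- list(status = "resumed",
                                        outputs = unname(paths))
      outputs <<- c(outputs, paths)
      return(NULL)
    }
    res <- tryCatch(fun(paths), error = function(e)
      ssStop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), "stage"))
    manifest$stages[[stage]] <<- c(list(status = "complete",
                                        outputs = unname(paths)), res)
    outputs <<- c(outputs, paths)
    invisible(NULL)
  }

  ## ---- screen ----------------------------------------------------------
  consensus <- NULL
  runStage("screen", c("consensus.tsv"), function(paths) {
    if (!length(cfg$series))
      ssStop("no series-matrix files configured", "configuration")
    perDataset <- list()
    for (i in seq_along(cfg$series)) {
      ann <- if (!is.null(cfg$annotations)) cfg$annotations[[i]] else NULL
      ds <- readSeriesMatrix(cfg$series[[i]], annotation = ann)
      ds <- filterSamples(ds, minAge = cfg$min_age, maxAge = cfg$max_age,
                          minPerSex = cfg$min_per_sex)
      st <- moderatedTScreen(ds)
      writeTsv(st, stageFile(outDir, "screen",
                             paste0(datasetId(ds), "_probes.tsv")))
      perDataset[[datasetId(ds)]] <- collapseProbes(st)
    }
    cons <- consensusFilter(perDataset, pStrict = cfg$p_strict,
                            pLoose = cfg$p_loose,
                            minStrict = cfg$min_strict)
    writeTsv(cons, paths[1])
    consensus <<- cons
    list(datasets = length(perDataset), genes = nrow(cons),
         passed = sum(cons$passed))
  })

  ## ---- mine ------------------------------------------------------------
  occTables <- NULL
  runStage("mine", c("occurrences.tsv"), function(paths) {
    if (is.null(cfg$hgnc)) ssStop("no HGNC table configured", "configuration")
    if (!length(cfg$corpora)) ssStop("no corpora configured", "configuration")
    genes <- consensus$gene[consensus$passed]
    lex <- loadHgncLexicon(cfg$hgnc, genes)
    matchers <- compileMatchers(lex, extraBlacklist = cfg$extra_blacklist)
    tabs <- list()
    rows <- list()
    for (lbl in names(cfg$corpora)) {
      corpus <- readMedline(cfg$corpora[[lbl]], label = lbl)
      occ <- countOccurrences(corpus, matchers)
      tabs[[lbl]] <- occ
      cts <- occ@counts
      cts$corpus <- lbl
      cts$corpus_size <- occ@corpusSize
      rows[[lbl]] <- cts
    }
    writeTsv(do.call(rbind, rows), paths[1])
    occTables <<- tabs
    list(corpora = length(tabs), genes = length(genes))
  })

  ## ---- integrate -------------------------------------------------------
  runStage("integrate", c("ranking.tsv"), function(paths) {
    rk <- selectCandidates(consensus, occTables, k = cfg$k)
    writeTsv(rk, paths[1])
    list(qualifiers = sum(rk$qualifies), selected = sum(rk$selected))
  })

  ## ---- go --------------------------------------------------------------
  if (!is.null(cfg$gmt)) {
    runStage("go", c("overlap.tsv"), function(paths) {
      sets <- readGmt(cfg$gmt)
      res <- overlapTest(consensus$gene[consensus$passed], sets,
                         universeN = cfg$universe_n)
      writeTsv(res, paths[1])
      list(categories = nrow(res))
    })
  }

  ## ---- qpcr ------------------------------------------------------------
  if (!is.null(cfg$cq)) {
    runStage("qpcr", c("nrq.tsv"), function(paths) {
      eff <- unlist(cfg$efficiencies)
      cq <- readCqTable(cfg$cq,
                        efficiencies = if (length(eff)) eff else numeric(),
                        referenceGenes = cfg$reference_genes)
      nrq <- qbaseNRQ(cq)
      writeTsv(nrq, paths[1])
      list(samples = length(unique(nrq$sample_id)),
           targets = length(unique(nrq$gene)))
    })
  }

  ## ---- stats -----------------------------------------------------------
  if (!is.null(cfg$cohort)) {
    runStage("stats", c("comparisons.tsv", "correlations.tsv"),
             function(paths) {
      cohort <- readCohortTable(cfg$cohort)
      comps <- lapply(cfg$compare, function(cp) {
        r <- compareBySex(cohort, cp$measure, group = cp$group,
                          exactLimit = cfg$exact_limit)
        data.frame(measure = r$measure, group = r$group, U = r$statistic,
                   p = r$p, n_female = r$n1, n_male = r$n2,
                   median_female = r$median_female,
                   median_male = r$median_male, method = r$method)
      })
      compDf <- if (length(comps)) do.call(rbind, comps) else
        data.frame()
      writeTsv(compDf, paths[1])
      corDf <- if (length(cfg$correlate)) {
        correlateMarkers(cohort, cfg$correlate,
                         stratifyBySex = isTRUE(cfg$stratify_by_sex),
                         group = c("controller", "progressor"))
      } else data.frame()
      writeTsv(corDf, paths[2])
      list(comparisons = nrow(compDf), correlations = nrow(corDf))
    })
  }

  manifest$outputs <- unname(outputs)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}
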