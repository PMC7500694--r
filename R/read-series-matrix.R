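#' Read a GEO series-matrix file into an ExpressionDataset
#'
#' Parses the `!Sample_*` metadata header and the
#' `!series_matrix_table_begin` ... `!series_matrix_table_end` block of a
#' GEO series-matrix text file (optionally gzip-compressed). Sample sex and
#' age are extracted from `!Sample_characteristics_ch1` key:value fields;
#' the keys are matched case-insensitively and configurable. If the data do
#' not look log-scaled (99th percentile of finite values above
#' \code{logThreshold}), intensities are floored at 1 and log2-transformed,
#' and the transform is recorded in the provenance.
#'
#' @param path path to a series-matrix file (".gz" accepted).
#' @param annotation optional probe-to-gene map: a named character vector
#'   (names = probe ids), a two-column data.frame (probe id, gene symbol) or
#'   a path to a two-column TSV with a header line.
#' @param datasetId dataset identifier; defaults to the file name.
#' @param sexKeys,ageKeys,healthKeys character vectors of characteristics
#'   keys (case-insensitive) searched for sex, age and health status. When
#'   no health-like key exists in the series at all, samples are assumed
#'   healthy; an unrecognized value maps to \code{"other"}.
#' @param logThreshold auto-log detection threshold on the 99th percentile
#'   of the raw values.
#' @return An \linkS4class{ExpressionDataset}.
#' @export
readSeriesMatrix <- function(path, annotation = NULL, datasetId = NULL,
                             sexKeys = c("sex", "gender"),
                             ageKeys = c("age", "age (years)", "age_years"),
                             healthKeys = c("health", "health status",
                                            "status", "disease",
                                            "disease state", "condition"),
                             logThreshold = 50) {
  if (!file.exists(path))
    ssStop(sprintf("file not found: %s", path), "input")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    ssStop("no !series_matrix_table_begin/_end block found", "format")

  splitFields <- function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    gsub('^"|"$', "", f)
  }

  ## ---- sample metadata ------------------------------------------------
  metaLines <- grep("^!Sample_", lines[seq_len(begin - 1L)], value = TRUE)
  accLine <- grep("^!Sample_geo_accession", metaLines, value = TRUE)
  titleLine <- grep("^!Sample_title", metaLines, value = TRUE)
  idLine <- if (length(accLine)) accLine[1] else
    if (length(titleLine)) titleLine[1] else NULL

  ## ---- expression table -----------------------------------------------
  header <- splitFields(lines[begin + 1L])
  sampleIds <- header[-1]
  body <- lines[(begin + 2L):(end - 1L)]
  bodyFields <- lapply(body, splitFields)
  nf <- lengths(bodyFields)
  if (any(nf != length(header)))
    ssStop("matrix rows do not all match the header field count",
           "consistency")
  probeIds <- vapply(bodyFields, `[`, character(1), 1L)
  if (anyDuplicated(probeIds))
    ssStop("duplicate probe ids in matrix", "format")
  values <- matrix(NA_real_, length(probeIds), length(sampleIds),
                   dimnames = list(probeIds, sampleIds))
  for (i in seq_along(bodyFields)) {
    v <- bodyFields[[i]][-1]
    v[v %in% c("", "null", "NULL", "NA")] <- NA
    values[i, ] <- as.numeric(v)
  }

  if (!is.null(idLine)) {
    ids <- splitFields(idLine)[-1]
    if (length(ids) != length(sampleIds))
      ssStop(sprintf(
        "header declares %d samples but the matrix has %d columns",
        length(ids), length(sampleIds)), "consistency")
  }

  ## ---- characteristics ------------------------------------------------
  chLines <- grep("^!Sample_characteristics", metaLines, value = TRUE)
  chars <- vector("list", length(sampleIds))
  for (ln in chLines) {
    f <- splitFields(ln)[-1]
    if (length(f) != length(sampleIds))
      ssStop("characteristics line length does not match sample count",
             "consistency")
    for (j in seq_along(f)) {
      kv <- regmatches(f[j], regexec("^\\s*([^:]+?)\\s*:\\s*(.*)$", f[j]))[[1]]
      if (length(kv) == 3L)
        chars[[j]][[tolower(squishWs(kv[2]))]] <- squishWs(kv[3])
    }
  }
  pickKey <- function(map, keys) {
    hit <- intersect(tolower(keys), names(map))
    if (length(hit)) map[[hit[1]]] else NA_character_
  }

  sexRaw <- vapply(chars, pickKey, character(1), keys = sexKeys)
  sex <- parseSexValue(sexRaw)
  if (anyNA(sex))
    ssStop(sprintf("could not parse sex for sample(s): %s",
                   paste(sampleIds[is.na(sex)], collapse = ", ")),
           "metadata")

  ageRaw <- vapply(chars, pickKey, character(1), keys = ageKeys)
  age <- suppressWarnings(as.integer(round(as.numeric(
    sub("^([0-9]+(\\.[0-9]+)?).*", "\\1", ageRaw)))))

  healthSeen <- any(vapply(chars, function(m)
    length(intersect(tolower(healthKeys), names(m))) > 0, logical(1)))
  if (healthSeen) {
    hRaw <- tolower(vapply(chars, pickKey, character(1), keys = healthKeys))
    health <- ifelse(!is.na(hRaw) & hRaw %in%
                       c("healthy", "normal", "control", "healthy control",
                         "healthy donor", "none"),
                     "healthy", "other")
  } else {
    health <- rep("healthy", length(sampleIds))
  }

  ## ---- log detection --------------------------------------------------
  prov <- character()
  fin <- values[is.finite(values)]
  if (length(fin) && stats::quantile(fin, 0.99, names = FALSE) > logThreshold) {
    values <- log2(pmax(values, 1))
    prov <- c(prov, "log2")
  }

  probeGene <- resolveAnnotation(annotation, probeIds)
  if (is.null(datasetId)) datasetId <- sub("\\.gz$", "", basename(path))

  ExpressionDataset(values, probeIds = probeIds,
                    sampleData = data.frame(sample_id = sampleIds,
                                            sex = sex, age = age,
                                            health = health),
                    probeGene = probeGene, datasetId = datasetId,
                    provenance = prov)
}

## Accept a named vector, a 2-column data.frame or a TSV path.
resolveAnnotation <- function(annotation, probeIds) {
  if (is.null(annotation)) return(rep("", length(probeIds)))
  if (is.character(annotation) && is.null(names(annotation)) &&
      length(annotation) == 1L && file.exists(annotation)) {
    annotation <- utils::read.delim(annotation, header = TRUE,
                                    colClasses = "character")
  }
  if (is.data.frame(annotation)) {
    map <- annotation[[2]]
    names(map) <- annotation[[1]]
    annotation <- map
  }
  out <- unname(annotation[probeIds])
  out[is.na(out)] <- ""
  out
}

#' Write an ExpressionDataset as a GEO-style series-matrix file
#'
#' Emits the minimal series-matrix dialect that [readSeriesMatrix()]
#' accepts (accession line, sex/age/status characteristics, the expression
#' table) plus, optionally, a probe annotation TSV next to it. Used by the
#' synthetic-data module to exercise the file-based pipeline end to end.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param path output path (".gz" to compress).
#' @param annotationPath optional path for a probe-to-gene TSV.
#' @return \code{path}, invisibly.
#' @export
writeSeriesMatrix <- function(ds, path, annotationPath = NULL) {
  cd <- colData(ds)
  q <- function(x) paste0('"', x, '"')
  line <- function(tag, vals) paste(c(tag, q(vals)), collapse = "\t")
  hdr <- c(
    line("!Sample_geo_accession", cd$sample_id),
    line("!Sample_characteristics_ch1", paste0("Sex: ", cd$sex)),
    line("!Sample_characteristics_ch1",
         paste0("age: ", ifelse(is.na(cd$age), "", cd$age))),
    line("!Sample_characteristics_ch1", paste0("status: ", cd$health)))
  m <- assay(ds, "exprs")
  tbl <- c(paste(c(q("ID_REF"), q(colnames(m))), collapse = "\t"),
           vapply(seq_len(nrow(m)), function(i)
             paste(c(q(rownames(m)[i]),
                     formatC(m[i, ], format = "g", digits = 10)),
                   collapse = "\t"), character(1)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(hdr, "!series_matrix_table_begin", tbl,
               "!series_matrix_table_end"), con)
  if (!is.null(annotationPath)) {
    utils::write.table(
      data.frame(probe_id = rownames(ds), gene = rowData(ds)$gene),
      annotationPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
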