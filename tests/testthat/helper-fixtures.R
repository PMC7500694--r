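## Shared fixtures and independent oracles, built in code at test time.

panelPath <- function() {
  system.file("extdata", "hgnc_panel_synthetic.tsv", package = "sexscreen")
}

panelGenes <- function() {
  read.delim(panelPath(), colClasses = "character")$symbol
}

loadPanelLexicon <- function() {
  suppressWarnings(loadHgncLexicon(panelPath(), genes = panelGenes()))
}

## A tiny hand-specified dataset: values chosen so the group means and
## pooled variances can be verified by hand arithmetic.
toyDataset <- function(values, sex = NULL, genes = NULL, ages = NULL) {
  values <- as.matrix(values)
  n <- ncol(values)
  if (is.null(sex)) sex <- rep(c("female", "male"), each = n / 2)
  if (is.null(ages)) ages <- rep(30L, n)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(genes)) genes <- rep("", nrow(values))
  ExpressionDataset(
    values,
    sampleData = data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                            sex = sex, age = ages, health = "healthy"),
    probeGene = genes, datasetId = "toy")
}

## Write a minimal hand-rolled series-matrix file (not via the package
## writer, so the reader is tested against independently constructed text).
writeRawSeriesMatrix <- function(path, values, sexes, ages = NULL,
                                 status = NULL, header_n = NULL) {
  n <- ncol(values)
  if (is.null(ages)) ages <- rep(30, n)
  if (is.null(status)) status <- rep("healthy", n)
  ids <- paste0("GSM", seq_len(if (is.null(header_n)) n else header_n))
  q <- function(x) paste0('"', x, '"')
  lines <- c(
    paste(c("!Sample_geo_accession", q(ids)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            q(paste0("Sex: ", sexes))), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            q(paste0("age: ", ages))), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            q(paste0("disease state: ", status))), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c(q("ID_REF"), q(paste0("GSM", seq_len(n)))), collapse = "\t"),
    vapply(seq_len(nrow(values)), function(i)
      paste(c(q(paste0("probe", i)), values[i, ]), collapse = "\t"),
      character(1)),
    "!series_matrix_table_end")
  writeLines(lines, path)
  path
}

## Brute-force one-sided Mann-Whitney p over all rank assignments.
enumMannWhitneyP <- function(n1, n2, uObs,
                             alternative = c("greater", "less",
                                             "two_sided")) {
  alternative <- match.arg(alternative)
  n <- n1 + n2
  sets <- combn(n, n1)
  u <- colSums(sets) - n1 * (n1 + 1) / 2
  switch(alternative,
         greater = mean(u >= uObs),
         less = mean(u <= uObs),
         two_sided = min(1, 2 * min(mean(u >= uObs), mean(u <= uObs))))
}

## Brute-force hypergeometric upper tail: draw n of N, K marked, P(X >= k).
enumHyperTail <- function(N, K, n, k) {
  marked <- seq_len(K)
  sets <- combn(N, n)
  hits <- colSums(matrix(sets %in% marked, nrow = n))
  mean(hits >= k)
}

screenOne <- function(ds, ...) collapseProbes(moderatedTScreen(ds, ...))
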