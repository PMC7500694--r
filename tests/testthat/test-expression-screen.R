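test_that("series-matrix reader parses metadata, joins samples and detects log scale", {
  f <- tempfile(fileext = ".txt")
  vals <- matrix(round(runif(20, 5, 14), 3), 5, 4)
  writeRawSeriesMatrix(f, vals, sexes = c("female", "Female", "M", "male"))
  ds <- readSeriesMatrix(f)
  expect_s4_class(ds, "ExpressionDataset")
  expect_identical(dim(ds), c(5L, 4L))
  expect_identical(as.character(SummarizedExperiment::colData(ds)$sex),
                   c("female", "female", "male", "male"))
  ## values max at 14 -> treated as already log2
  expect_false("log2" %in% provenance(ds))
  expect_equal(unname(SummarizedExperiment::assay(ds, "exprs")[1, 1]),
               vals[1, 1])

  ## unlogged data: floored at 1 and log2-transformed, recorded
  f2 <- tempfile(fileext = ".txt")
  writeRawSeriesMatrix(f2, matrix(c(0.5, 150, 20000, 800), 2, 2),
                       sexes = c("female", "male"))
  ds2 <- readSeriesMatrix(f2)
  expect_true("log2" %in% provenance(ds2))
  expect_equal(unname(SummarizedExperiment::assay(ds2, "exprs")[2, 2]),
               log2(800))
  expect_equal(unname(SummarizedExperiment::assay(ds2, "exprs")[1, 1]),
               0)  # floored at 1 before log2
})

test_that("series-matrix reader signals format, consistency and metadata errors", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("!Sample_geo_accession\t\"GSM1\"", "\"probe1\"\t1"), f)
  expect_error(readSeriesMatrix(f), class = "sexscreen_format_error")

  f2 <- tempfile(fileext = ".txt")
  writeRawSeriesMatrix(f2, matrix(1:4 + 5, 2, 2),
                       sexes = c("female", "male"), header_n = 3)
  expect_error(readSeriesMatrix(f2), class = "sexscreen_consistency_error")

  f3 <- tempfile(fileext = ".txt")
  writeRawSeriesMatrix(f3, matrix(1:4 + 5, 2, 2),
                       sexes = c("female", "unknown"))
  err <- tryCatch(readSeriesMatrix(f3), error = identity)
  expect_s3_class(err, "sexscreen_metadata_error")
  expect_match(conditionMessage(err), "GSM2")
})

test_that("sample filter applies inclusive age bounds, health and per-sex minima", {
  vals <- matrix(rnorm(4 * 24, 8), 4, 24)
  sex <- rep(c("female", "male"), 12)
  ages <- c(16L, 17L, 43L, 44L, rep(30L, 20))
  ds <- toyDataset(vals, sex = sex, ages = ages)
  out <- filterSamples(ds, minPerSex = 10)
  kept <- colnames(out)
  expect_false("s01" %in% kept)  # age 16 dropped
  expect_true(all(c("s02", "s03") %in% kept))  # 17 and 43 inclusive
  expect_false("s04" %in% kept)  # age 44 dropped
  expect_identical(ncol(out), 22L)

  ## 12 female / 9 male -> eligibility error reporting counts
  ds2 <- toyDataset(matrix(rnorm(4 * 21, 8), 4, 21),
                    sex = c(rep("female", 12), rep("male", 9)))
  err <- tryCatch(filterSamples(ds2, minPerSex = 10), error = identity)
  expect_s3_class(err, "sexscreen_eligibility_error")
  expect_match(conditionMessage(err), "9 male")

  ## all eligible -> identity on columns
  ds3 <- toyDataset(matrix(rnorm(80, 8), 4, 20))
  expect_identical(colnames(filterSamples(ds3)), colnames(ds3))

  ## unhealthy samples are excluded
  ds4 <- ExpressionDataset(
    matrix(rnorm(4 * 22, 8), 4, 22),
    probeIds = paste0("p", 1:4),
    sampleData = data.frame(
      sample_id = sprintf("s%02d", 1:22),
      sex = rep(c("female", "male"), 11), age = 30L,
      health = c(rep("healthy", 20), "other", "other")),
    datasetId = "h")
  expect_identical(ncol(filterSamples(ds4)), 20L)
})

test_that("per-probe two-group fit matches hand arithmetic and handles degenerate probes", {
  ## probe 1: F {2,2} M {1,1} -> logFC 1, s2 0 (flagged)
  ## probe 2: equal means -> logFC 0
  ## probe 3: F {3,5} M {1,3} -> logFC 2, pooled s2 = (2+2)/2 = 2, df = 2
  vals <- rbind(c(2, 2, 1, 1),
                c(4, 6, 4, 6),
                c(3, 5, 1, 3))
  ds <- toyDataset(vals)
  fit <- fitGeneVariances(ds)
  expect_equal(fit$logFC, c(1, 0, 2))
  expect_equal(fit$s_sq, c(0, 2, 2))
  expect_equal(fit$df_resid, c(2, 2, 2))
  expect_identical(fit$zero_var, c(TRUE, FALSE, FALSE))
  expect_equal(fit$avg_expr, c(1.5, 5, 3))

  ## a probe with too many missing values is excluded with a warning
  vals2 <- rbind(c(2, 2, 1, 1), c(NA, NA, NA, 4))
  expect_warning(fit2 <- fitGeneVariances(toyDataset(vals2)),
                 class = "sexscreen_missing_warning")
  expect_identical(nrow(fit2), 1L)
})

test_that("empirical-Bayes moments recover simulated hyper-parameters and flag degenerate spread", {
  ## identical variances, identical df -> no excess spread -> d0 infinite,
  ## s0 equals the bias-corrected log-scale mean
  eb <- ebayesMoments(c(1, 1), c(4, 4))
  expect_identical(eb$d0, Inf)
  expect_equal(eb$s0_sq, exp(mean(log(c(1, 1))) - digamma(2) + log(2)))

  ## parameter recovery: s2 ~ s0 * d0/chisq(d0) * chisq(df)/df
  set.seed(11)
  d0 <- 4; s0 <- 1.3; df <- 10; n <- 10000
  sigma2 <- s0 * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  eb2 <- ebayesMoments(s2, rep(df, n))
  expect_lt(abs(eb2$d0 - d0) / d0, 0.2)
  expect_lt(abs(eb2$s0_sq - s0) / s0, 0.1)

  expect_error(ebayesMoments(c(0, 0, 0), 4),
               class = "sexscreen_degenerate_error")
})

test_that("moderated t equals pooled t at d0 = 0, orders by logFC at d0 = Inf, and matches limma", {
  set.seed(7)
  nper <- 8
  sds <- sqrt(1.5 * 4 / rchisq(200, 4))  # heterogeneous true variances
  vals <- matrix(rnorm(200 * 2 * nper, 8, sds), 200, 2 * nper)
  ds <- toyDataset(vals)
  sex <- rep(c("female", "male"), each = nper)

  st0 <- moderatedTScreen(ds, d0 = 0, s0_sq = 1)
  pClassical <- apply(vals, 1, function(v)
    t.test(v[sex == "female"], v[sex == "male"], var.equal = TRUE)$p.value)
  expect_lt(max(abs(st0$p - pClassical)), 1e-12)

  stInf <- moderatedTScreen(ds, d0 = Inf, s0_sq = 2)
  expect_identical(order(-abs(stInf$t_mod)), order(-abs(stInf$logFC)))

  skip_if_not_installed("limma")
  st <- moderatedTScreen(ds)
  design <- cbind(male = as.numeric(sex == "male"),
                  female = as.numeric(sex == "female"))
  fit <- limma::lmFit(vals, design)
  fit <- limma::contrasts.fit(
    fit, limma::makeContrasts(female - male, levels = design))
  fit <- limma::eBayes(fit)
  expect_lt(abs(attr(st, "ebayes")$d0 - fit$df.prior), 1e-6)
  expect_lt(max(abs(st$p - fit$p.value[, 1])), 1e-9)
})

test_that("probe collapse keeps the smallest-p probe with documented tie-breaks", {
  st <- data.frame(
    probe_id = c("a1", "a2", "b1", "c1", "c2"),
    gene = c("GA", "GA", "GB", "GC", "GC"),
    logFC = c(0.5, -0.2, 1, 0.3, 0.4),
    t_mod = 1, p = c(0.01, 0.20, 0.5, 0.04, 0.04),
    avg_expr = c(7, 8, 5, 5, 9), df_resid = 10,
    stringsAsFactors = FALSE)
  out <- collapseProbes(st)
  expect_identical(out$probe_id[out$gene == "GA"], "a1")   # smallest p
  expect_true(out$sign_conflict[out$gene == "GA"])         # sibling flips
  expect_identical(out$probe_id[out$gene == "GB"], "b1")   # singleton
  expect_identical(out$probe_id[out$gene == "GC"], "c2")   # tie -> avg_expr 9
  expect_false(out$sign_conflict[out$gene == "GC"])
  ## unmapped probes are dropped
  st$gene[1:2] <- ""
  expect_false(any(collapseProbes(st)$gene == ""))
})

test_that("consensus filter applies the two-tier significance and direction rules", {
  mk <- function(p, fc) data.frame(gene = paste0("G", seq_along(p)),
                                   p = p, logFC = fc,
                                   stringsAsFactors = FALSE)
  ## G1 passes; G2 fails (one strict p only); G3 fails (sign conflict)
  d1 <- mk(c(0.009, 0.009, 0.001), c(0.4, 0.3, 0.4))
  d2 <- mk(c(0.004, 0.02, 0.001), c(0.2, 0.3, 0.2))
  d3 <- mk(c(0.03, 0.03, 0.001), c(0.1, 0.2, -0.1))
  res <- consensusFilter(list(A = d1, B = d2, C = d3))
  expect_identical(res$passed[res$gene == "G1"], TRUE)
  expect_identical(res$direction[res$gene == "G1"], "up_in_women")
  expect_identical(res$passed[res$gene == "G2"], FALSE)
  expect_identical(res$passed[res$gene == "G3"], FALSE)
  expect_equal(res$mean_p[res$gene == "G1"],
               mean(c(0.009, 0.004, 0.03)))
  expect_equal(res$mean_logFC[res$gene == "G1"], mean(c(0.4, 0.2, 0.1)))
  ## sorted ascending by mean p
  expect_true(!is.unsorted(res$mean_p))
  ## genes absent from one dataset are ineligible
  d2b <- d2[-1, ]
  res2 <- consensusFilter(list(A = d1, B = d2b, C = d3))
  expect_false("G1" %in% res2$gene)
})

test_that("consensus filter is monotone in its thresholds and symmetric under sex swap", {
  set.seed(21)
  sim <- simExpressionStudies(nDatasets = 3, nGenes = 150, nSpiked = 15,
                              nPerSex = 12, seed = 21)
  per <- lapply(sim$datasets, screenOne)
  base <- consensusFilter(per)
  tighter <- consensusFilter(per, pStrict = 0.001, pLoose = 0.01)
  expect_true(all(tighter$gene[tighter$passed] %in% base$gene[base$passed]))

  ## swapping sex labels negates logFC and flips directions, same passed set
  swapped <- lapply(sim$datasets, function(d) {
    cd <- SummarizedExperiment::colData(d)
    ExpressionDataset(SummarizedExperiment::assay(d, "exprs"),
                      sampleData = data.frame(
                        sample_id = cd$sample_id,
                        sex = ifelse(cd$sex == "female", "male", "female"),
                        age = cd$age, health = cd$health),
                      probeGene = probeGene(d), datasetId = datasetId(d))
  })
  perSw <- lapply(swapped, screenOne)
  sw <- consensusFilter(perSw)
  expect_identical(sw$gene[sw$passed], base$gene[base$passed])
  m <- match(base$gene, sw$gene)
  expect_equal(sw$mean_logFC[m], -base$mean_logFC, tolerance = 1e-12)
  pb <- base$passed
  expect_identical(sw$direction[m][pb],
                   ifelse(base$direction[pb] == "up_in_women",
                          "up_in_men", "up_in_women"))
})
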