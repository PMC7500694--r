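#' Apply the cohort inclusion criteria to an expression dataset
#'
#' Keeps healthy samples whose age lies within the inclusive
#' \code{[minAge, maxAge]} window, then checks that at least
#' \code{minPerSex} samples of each sex remain. Samples with missing age are
#' excluded (age had to be available for inclusion).
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param minAge,maxAge inclusive age bounds in years.
#' @param minPerSex minimum number of retained samples per sex.
#' @return The filtered \linkS4class{ExpressionDataset}.
#' @export
filterSamples <- function(ds, minAge = 17, maxAge = 43, minPerSex = 10) {
  cd <- colData(ds)
  keep <- cd$health == "healthy" & !is.na(cd$age) &
    cd$age >= minAge & cd$age <= maxAge
  out <- ds[, keep]
  nF <- sum(colData(out)$sex == "female")
  nM <- sum(colData(out)$sex == "male")
  if (nF < minPerSex || nM < minPerSex)
    ssStop(sprintf(
      "dataset '%s' not eligible after filtering: %d female / %d male (need >= %d each)",
      datasetId(ds), nF, nM, minPerSex), "eligibility")
  metadata(out)$provenance <- c(provenance(ds),
                                sprintf("filter_samples:kept=%d/%d",
                                        sum(keep), ncol(ds)))
  out
}

#' Per-probe two-group statistics for the female-minus-male contrast
#'
#' For every probe computes the log2 fold change (mean over female samples
#' minus mean over male samples), the pooled residual variance of the
#' two-group model, the residual degrees of freedom and the mean intensity.
#' Missing values are tolerated: a probe is retained as long as at least two
#' finite values remain per sex, otherwise it is excluded with a warning.
#' Probes with zero residual variance are retained and flagged.
#'
#' @param ds an \linkS4class{ExpressionDataset} (already sample-filtered).
#' @return data.frame with columns \code{probe_id}, \code{gene},
#'   \code{logFC}, \code{s_sq}, \code{df_resid}, \code{avg_expr},
#'   \code{n_f}, \code{n_m}, \code{zero_var}.
#' @export
fitGeneVariances <- function(ds) {
  m <- assay(ds, "exprs")
  sex <- colData(ds)$sex
  if (sum(sex == "female") < 2 || sum(sex == "male") < 2)
    ssStop("need at least 2 samples per sex", "eligibility")
  mf <- m[, sex == "female", drop = FALSE]
  mm <- m[, sex == "male", drop = FALSE]
  nF <- rowSums(is.finite(mf))
  nM <- rowSums(is.finite(mm))
  ok <- nF >= 2 & nM >= 2
  if (!all(ok)) {
    dropped <- rownames(m)[!ok]
    ssWarn(sprintf("%d probe(s) excluded (fewer than 2 values per sex): %s",
                   length(dropped),
                   paste(utils::head(dropped, 5), collapse = ", ")),
           "missing")
  }
  mf[!is.finite(mf)] <- NA
  mm[!is.finite(mm)] <- NA
  muF <- rowMeans(mf, na.rm = TRUE)
  muM <- rowMeans(mm, na.rm = TRUE)
  ssF <- rowSums((mf - muF)^2, na.rm = TRUE)
  ssM <- rowSums((mm - muM)^2, na.rm = TRUE)
  df <- nF + nM - 2
  s2 <- (ssF + ssM) / df
  avg <- rowMeans(cbind(mf, mm), na.rm = TRUE)
  out <- data.frame(probe_id = rownames(m),
                    gene = rowData(ds)$gene,
                    logFC = muF - muM,
                    s_sq = s2,
                    df_resid = df,
                    avg_expr = avg,
                    n_f = nF, n_m = nM,
                    zero_var = s2 <= 0,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  out[ok, , drop = FALSE]
}

## Newton inversion of the trigamma function (x > 0 such that
## trigamma(x) = y); standard monotone iteration, converges in < 10 steps.
trigammaInverse <- function(y) {
  out <- y
  lo <- y < 1e-7
  hi <- y > 1e7
  out[lo] <- 1 / sqrt(y[lo])
  out[hi] <- 1 / y[hi]
  mid <- which(!lo & !hi)
  x <- 0.5 + 1 / y[mid]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(-dif / x) < 1e-10) break
  }
  out[mid] <- x
  out
}

#' Empirical-Bayes moments of the gene-wise variances
#'
#' Estimates the prior degrees of freedom \code{d0} and prior variance
#' \code{s0_sq} of a scaled inverse chi-square prior on the true gene
#' variances, by the method of moments on the log variances (closed-form
#' digamma/trigamma identities). When the observed spread of log variances
#' does not exceed what sampling alone explains, \code{d0} is infinite and
#' \code{s0_sq} is the bias-corrected mean variance on the log scale.
#' Zero or non-finite variances are ignored for estimation.
#'
#' @param s_sq numeric vector of residual variances.
#' @param df_resid residual degrees of freedom (scalar or vector).
#' @return list with elements \code{d0} (possibly \code{Inf}) and
#'   \code{s0_sq}.
#' @export
ebayesMoments <- function(s_sq, df_resid) {
  df <- rep(df_resid, length.out = length(s_sq))
  keep <- is.finite(s_sq) & s_sq > 0 & df > 0
  if (!any(keep))
    ssStop("all variances are zero or non-finite; cannot estimate prior",
           "degenerate")
  if (sum(keep) < 2)
    ssStop("need at least 2 positive finite variances", "degenerate")
  z <- log(s_sq[keep])
  df <- df[keep]
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
  }
  list(d0 = d0, s0_sq = s0)
}

#' Moderated t screen of a dataset for sex-biased probes
#'
#' Computes, per probe, the shrunken variance
#' \code{s_tilde_sq = (d0 s0_sq + df s_sq) / (d0 + df)}, the moderated
#' t-statistic for the female-minus-male contrast and its two-sided p-value
#' on \code{d0 + df} degrees of freedom (normal reference when \code{d0} is
#' infinite). With \code{d0 = 0} (override) the statistic reduces to the
#' classical pooled two-sample t.
#'
#' @param ds an \linkS4class{ExpressionDataset}, already passed through
#'   [filterSamples()] (or otherwise restricted to eligible samples).
#' @param d0,s0_sq optional overrides of the empirical-Bayes prior; by
#'   default both are estimated from the data via [ebayesMoments()].
#' @return data.frame of per-probe statistics: \code{probe_id}, \code{gene},
#'   \code{logFC} (positive = higher in women), \code{t_mod}, \code{p}
#'   (two-sided), \code{avg_expr}, \code{df_resid}, \code{df_total},
#'   \code{s_sq}, \code{zero_var}; the prior is attached as attribute
#'   \code{"ebayes"}.
#' @export
moderatedTScreen <- function(ds, d0 = NULL, s0_sq = NULL) {
  fit <- fitGeneVariances(ds)
  if (is.null(d0) || is.null(s0_sq)) {
    eb <- ebayesMoments(fit$s_sq, fit$df_resid)
    if (is.null(d0)) d0 <- eb$d0
    if (is.null(s0_sq)) s0_sq <- eb$s0_sq
  }
  df <- fit$df_resid
  stilde <- if (is.infinite(d0)) rep(s0_sq, nrow(fit)) else
    (d0 * s0_sq + df * fit$s_sq) / (d0 + df)
  se <- sqrt(stilde * (1 / fit$n_f + 1 / fit$n_m))
  t <- fit$logFC / se
  dfTot <- d0 + df
  p <- 2 * stats::pt(-abs(t), df = dfTot)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(probe_id = fit$probe_id, gene = fit$gene,
                    logFC = fit$logFC, t_mod = t, p = p,
                    avg_expr = fit$avg_expr, df_resid = df,
                    df_total = dfTot, s_sq = fit$s_sq,
                    zero_var = fit$zero_var,
                    stringsAsFactors = FALSE)
  attr(out, "ebayes") <- list(d0 = d0, s0_sq = s0_sq)
  out
}

#' Collapse probe-level statistics to one row per gene
#'
#' Per gene keeps the probe with the smallest p-value; ties are broken by
#' larger mean intensity, then lexicographic probe id. Probes with an empty
#' gene symbol are dropped. The column \code{sign_conflict} flags genes for
#' which a sibling probe had the opposite fold-change sign.
#'
#' @param stats a per-probe data.frame as returned by [moderatedTScreen()].
#' @return per-gene data.frame with the same statistic columns plus
#'   \code{sign_conflict}.
#' @export
collapseProbes <- function(stats) {
  st <- stats[nzchar(stats$gene), , drop = FALSE]
  if (!nrow(st)) return(cbind(st, sign_conflict = logical(0)))
  ord <- order(st$gene, st$p, -st$avg_expr, st$probe_id)
  st <- st[ord, , drop = FALSE]
  first <- !duplicated(st$gene)
  conflict <- vapply(split(sign(st$logFC), st$gene), function(s)
    length(unique(s[s != 0])) > 1, logical(1))
  out <- st[first, , drop = FALSE]
  out$sign_conflict <- unname(conflict[out$gene])
  rownames(out) <- NULL
  out
}

#' Cross-dataset consensus filter for sex-biased genes
#'
#' A gene passes when it is measured in every dataset, significant
#' (\code{p <= pLoose}) in all of them, highly significant
#' (\code{p <= pStrict}) in at least \code{minStrict}, and its fold change
#' has the same strict sign everywhere (inconsistently sex-biased genes are
#' removed). Per-dataset p-values and fold changes are summarised by their
#' arithmetic means.
#'
#' @param perDataset named list (length >= 2) of per-gene data.frames as
#'   returned by [collapseProbes()].
#' @param pStrict,pLoose,minStrict the consensus thresholds.
#' @return data.frame sorted by ascending \code{mean_p} with per-dataset
#'   \code{p.<id>} and \code{logFC.<id>} columns, \code{mean_p},
#'   \code{mean_logFC}, \code{direction} ("up_in_women"/"up_in_men") and
#'   \code{passed}.
#' @export
consensusFilter <- function(perDataset, pStrict = 0.01, pLoose = 0.05,
                            minStrict = 2) {
  if (length(perDataset) < 2)
    ssStop("need at least 2 datasets", "input")
  ids <- names(perDataset)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- names(perDataset) <- paste0("ds", seq_along(perDataset))
  common <- Reduce(intersect, lapply(perDataset, `[[`, "gene"))
  if (!length(common)) {
    ssWarn("no genes are measured in all datasets", "empty")
    return(data.frame(gene = character(), mean_p = numeric(),
                      mean_logFC = numeric(), direction = character(),
                      passed = logical()))
  }
  pMat <- sapply(perDataset, function(d) d$p[match(common, d$gene)])
  fcMat <- sapply(perDataset, function(d) d$logFC[match(common, d$gene)])
  pMat <- matrix(pMat, ncol = length(ids))
  fcMat <- matrix(fcMat, ncol = length(ids))
  nStrict <- rowSums(pMat <= pStrict)
  allLoose <- rowSums(pMat <= pLoose) == ncol(pMat)
  sameSign <- apply(fcMat, 1L, function(f)
    all(f > 0) || all(f < 0))
  passed <- nStrict >= minStrict & allLoose & sameSign
  meanP <- rowMeans(pMat)
  meanFC <- rowMeans(fcMat)
  out <- data.frame(gene = common, stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    out[[paste0("logFC.", ids[j])]] <- fcMat[, j]
    out[[paste0("p.", ids[j])]] <- pMat[, j]
  }
  out$mean_p <- meanP
  out$mean_logFC <- meanFC
  out$direction <- ifelse(meanFC >= 0, "up_in_women", "up_in_men")
  out$passed <- passed
  out <- out[order(out$mean_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
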