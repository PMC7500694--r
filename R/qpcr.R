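#' Read a long-format Cq table
#'
#' Expects a TSV with columns \code{sample_id}, \code{gene},
#' \code{replicate}, \code{cq} (extra columns are kept).
#'
#' @param path path to the TSV.
#' @param efficiencies named numeric vector of per-gene amplification
#'   factors (default 2.0 for unlisted genes).
#' @param referenceGenes housekeeping genes used for normalization.
#' @return A \linkS4class{CqTable}.
#' @export
readCqTable <- function(path, efficiencies = numeric(),
                        referenceGenes = c("HPRT1", "HMBS")) {
  tab <- utils::read.delim(path, header = TRUE)
  need <- c("sample_id", "gene", "replicate", "cq")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    ssStop(sprintf("Cq table lacks column(s): %s",
                   paste(miss, collapse = ", ")), "format")
  CqTable(tab, efficiencies = efficiencies,
          referenceGenes = referenceGenes)
}

#' Aggregate technical replicates to one Cq per sample and gene
#'
#' Takes the arithmetic mean of replicate Cq values; replicates deviating
#' by more than \code{maxDev} cycles from their replicate mean are flagged
#' (and optionally dropped before averaging).
#'
#' @param table a \linkS4class{CqTable}.
#' @param maxDev deviation threshold in cycles.
#' @param dropOutliers drop flagged replicates (re-averaging the rest)
#'   instead of only flagging them.
#' @return data.frame with columns \code{sample_id}, \code{gene},
#'   \code{cq}, \code{n_replicates}, \code{flagged}.
#' @export
aggregateReplicates <- function(table, maxDev = 0.5, dropOutliers = FALSE) {
  r <- table@records
  key <- paste(r$sample_id, r$gene, sep = "\r")
  grp <- split(seq_len(nrow(r)), key)
  rows <- lapply(grp, function(i) {
    cq <- r$cq[i]
    m <- mean(cq)
    dev <- abs(cq - m) > maxDev
    if (dropOutliers && any(dev) && !all(dev)) {
      cq <- cq[!dev]
      m <- mean(cq)
    }
    data.frame(sample_id = r$sample_id[i[1]], gene = r$gene[i[1]],
               cq = m, n_replicates = length(i), flagged = any(dev),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  samples <- unique(r$sample_id)
  for (g in table@referenceGenes) {
    have <- out$sample_id[out$gene == g]
    missing <- setdiff(samples, have)
    if (length(missing))
      ssStop(sprintf("reference gene %s has no Cq for sample(s): %s", g,
                     paste(missing, collapse = ", ")), "completeness")
  }
  out
}

#' qBase normalized relative quantities
#'
#' Implements the qBase relative-quantification model with the
#' across-sample mean Cq as calibrator: per gene \code{g} and sample
#' \code{s}, the efficiency-corrected relative quantity is
#' \code{RQ(g,s) = E_g^(meanCq_g - Cq(g,s))}, and the normalized relative
#' quantity divides by the geometric mean of the reference-gene relative
#' quantities of the same sample:
#' \code{NRQ(g,s) = RQ(g,s) / geomean_r(RQ(r,s))}. Reference genes are
#' excluded from the output targets. By construction the geometric mean of
#' \code{RQ} across samples is 1 for every gene.
#'
#' @param table a \linkS4class{CqTable}.
#' @param maxDev,dropOutliers passed to [aggregateReplicates()].
#' @return data.frame with columns \code{sample_id}, \code{gene},
#'   \code{rq}, \code{nrq}.
#' @export
qbaseNRQ <- function(table, maxDev = 0.5, dropOutliers = FALSE) {
  agg <- aggregateReplicates(table, maxDev = maxDev,
                             dropOutliers = dropOutliers)
  genes <- unique(agg$gene)
  eff <- table@efficiencies
  missingE <- setdiff(genes, names(eff))
  if (length(missingE) && length(eff))
    ssWarn(sprintf("no efficiency for gene(s) %s; defaulting to 2.0",
                   paste(missingE, collapse = ", ")), "efficiency")
  E <- stats::setNames(rep(2.0, length(genes)), genes)
  E[names(eff)[names(eff) %in% genes]] <- eff[names(eff) %in% genes]
  ## RQ with mean-Cq calibration per gene
  agg$rq <- NA_real_
  for (g in genes) {
    i <- agg$gene == g
    agg$rq[i] <- E[[g]]^(mean(agg$cq[i]) - agg$cq[i])
  }
  ## normalization factor: geometric mean of reference RQs per sample
  refs <- table@referenceGenes
  samples <- unique(agg$sample_id)
  nf <- vapply(samples, function(s)
    geoMean(agg$rq[agg$sample_id == s & agg$gene %in% refs]),
    numeric(1))
  agg$nrq <- agg$rq / nf[agg$sample_id]
  out <- agg[!(agg$gene %in% refs),
             c("sample_id", "gene", "rq", "nrq")]
  rownames(out) <- NULL
  out
}
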