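#' Read a per-subject cohort table
#'
#' TSV with columns \code{subject_id}, \code{sex} ("female"/"male"),
#' \code{group} ("healthy"/"controller"/"progressor") and one numeric
#' column per measure (e.g. \code{DPP4pos_CD4_pct}, \code{CD4_count},
#' \code{viral_load}). Percentage columns (suffix \code{_pct}) must lie in
#' [0, 100]; count columns must be non-negative.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readCohortTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE)
  need <- c("subject_id", "sex", "group")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    ssStop(sprintf("cohort table lacks column(s): %s",
                   paste(miss, collapse = ", ")), "format")
  validateCohort(tab)
  tab
}

validateCohort <- function(tab) {
  if (!all(tab$sex %in% c("female", "male")))
    ssStop("sex must be 'female' or 'male'", "metadata")
  if (!all(tab$group %in% c("healthy", "controller", "progressor")))
    ssStop("group must be healthy/controller/progressor", "metadata")
  for (cl in grep("_pct$", colnames(tab), value = TRUE)) {
    v <- tab[[cl]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      ssStop(sprintf("%s outside [0, 100]", cl), "range")
  }
  for (cl in grep("_count$", colnames(tab), value = TRUE)) {
    v <- tab[[cl]]
    if (any(!is.na(v) & v < 0))
      ssStop(sprintf("%s negative", cl), "range")
  }
  invisible(tab)
}

## Exact null distribution of the rank-sum statistic by the shift
## (count-distribution) recurrence: counts[w + 1] = number of ways to pick
## n1 of the ranks 1..n with rank sum w. Counts are exact in doubles for
## n <= 30 (max count C(30,15) < 2^53).
rankSumCounts <- function(n1, n2) {
  n <- n1 + n2
  maxW <- sum((n2 + 1):n)
  f <- matrix(0, n1 + 1, maxW + 1)
  f[1, 1] <- 1
  for (r in seq_len(n)) {
    for (k in rev(seq_len(min(r, n1)))) {
      src <- f[k, seq_len(maxW + 1 - r)]
      f[k + 1, (r + 1):(maxW + 1)] <- f[k + 1, (r + 1):(maxW + 1)] + src
    }
  }
  f[n1 + 1, ]
}

#' Mann-Whitney U test (exact for small tie-free samples)
#'
#' Computes the Mann-Whitney U statistic for \code{x} versus \code{y} from
#' the ranks of the pooled sample. When there are no ties and
#' \code{n1 + n2 <= exactLimit}, the p-value is exact, computed from the
#' full count distribution of the statistic (shift-algorithm recurrence):
#' for \code{alternative = "greater"} it is the fraction of the
#' \code{choose(n1 + n2, n1)} rank assignments with \code{U* >= U_obs}.
#' Otherwise a normal approximation with tie correction and (optional)
#' continuity correction is used. \code{"greater"} means \code{x} tends to
#' exceed \code{y}.
#'
#' @param x,y numeric vectors (NAs dropped).
#' @param alternative one of \code{"two_sided"}, \code{"greater"},
#'   \code{"less"} (\code{"two.sided"} is accepted as an alias).
#' @param exactLimit largest \code{n1 + n2} for which the exact p-value is
#'   computed in the absence of ties.
#' @param correct apply the continuity correction in the normal
#'   approximation.
#' @return list with \code{statistic} (U for x), \code{p}, \code{n1},
#'   \code{n2}, \code{alternative}, \code{method} ("exact" or
#'   "normal_approx").
#' @examples
#' # complete separation of 7 vs 7 gives the smallest attainable one-sided p
#' mannWhitneyU(8:14, 1:7, alternative = "greater")$p  # 1/3432
#' @export
mannWhitneyU <- function(x, y, alternative = c("two_sided", "greater",
                                               "less", "two.sided"),
                         exactLimit = 30, correct = TRUE) {
  alternative <- match.arg(alternative)
  if (alternative == "two.sided") alternative <- "two_sided"
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1)
    ssStop("both samples must be non-empty", "input")
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  hasTies <- anyDuplicated(pooled) > 0
  if (!hasTies && n1 + n2 <= exactLimit) {
    counts <- rankSumCounts(n1, n2)
    total <- sum(counts)
    ## counts are indexed by W = U + n1(n1+1)/2 starting at minW
    w <- seq_along(counts) - 1
    u <- w - n1 * (n1 + 1) / 2
    pGe <- function(u0) sum(counts[u >= u0]) / total
    pLe <- function(u0) sum(counts[u <= u0]) / total
    p <- switch(alternative,
                greater = pGe(U),
                less = pLe(U),
                two_sided = min(1, 2 * min(pGe(U), pLe(U))))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tieTab <- table(rk)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    cc <- if (correct) 0.5 else 0
    p <- switch(alternative,
                greater = stats::pnorm((U - mu - cc) / sigma,
                                       lower.tail = FALSE),
                less = stats::pnorm((U - mu + cc) / sigma),
                two_sided = {
                  z <- (abs(U - mu) - cc) / sigma
                  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
                })
    method <- "normal_approx"
  }
  list(statistic = U, p = max(p, .Machine$double.xmin), n1 = n1, n2 = n2,
       alternative = alternative, method = method)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho on average-ranked data (ties receive their mean rank) and a
#' p-value from \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on
#' \code{n - 2} degrees of freedom. \code{rho = +/-1} yields a p bounded
#' below by machine resolution.
#'
#' @param x,y paired numeric vectors; pairs with any NA are dropped.
#' @param alternative \code{"two_sided"}, \code{"greater"} or
#'   \code{"less"}.
#' @return list with \code{statistic} (rho), \code{p}, \code{n},
#'   \code{alternative}, \code{method} = "t_approx".
#' @export
spearmanRho <- function(x, y, alternative = c("two_sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) ssStop("need at least 3 complete pairs", "input")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    ssStop("correlation undefined for a constant input vector",
           "degenerate")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  }
  p <- switch(alternative,
              greater = stats::pt(tstat, df = n - 2, lower.tail = FALSE),
              less = stats::pt(tstat, df = n - 2),
              two_sided = 2 * stats::pt(-abs(tstat), df = n - 2))
  list(statistic = rho, p = min(1, max(p, .Machine$double.xmin)), n = n,
       alternative = alternative, method = "t_approx")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment \code{q_(i) = min_(j >= i) m p_(j) / j}, capped
#' at 1 and returned in input order. Input p-values must lie in (0, 1].
#'
#' @param pvals numeric vector of raw p-values.
#' @return numeric vector of q-values.
#' @export
bhAdjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    ssStop("p-values must lie in (0, 1]", "input")
  stats::p.adjust(pvals, method = "BH")
}

#' Compare a measure between the sexes within a clinical group
#'
#' Runs [mannWhitneyU()] on the female versus male values of a measure,
#' one-sided towards higher values in women by default (the direction
#' hypothesised from the expression screen).
#'
#' @param cohort cohort data.frame (see [readCohortTable()]).
#' @param measure column name of the measure.
#' @param group restrict to this clinical group (NULL = all subjects).
#' @param alternative test direction for female vs male values; the default
#'   \code{"greater"} tests for higher values in women.
#' @param ... passed to [mannWhitneyU()].
#' @return the [mannWhitneyU()] result list, with \code{measure},
#'   \code{group} and per-sex medians added.
#' @export
compareBySex <- function(cohort, measure, group = NULL,
                         alternative = "greater", ...) {
  if (!measure %in% colnames(cohort))
    ssStop(sprintf("measure '%s' not in cohort table", measure), "input")
  sub <- if (is.null(group)) cohort else cohort[cohort$group %in% group, ]
  xf <- sub[[measure]][sub$sex == "female"]
  xm <- sub[[measure]][sub$sex == "male"]
  xf <- xf[!is.na(xf)]; xm <- xm[!is.na(xm)]
  if (!length(xf) || !length(xm))
    ssStop(sprintf("group '%s' lacks samples of one sex",
                   paste(group, collapse = "+")), "eligibility")
  res <- mannWhitneyU(xf, xm, alternative = alternative, ...)
  res$measure <- measure
  res$group <- if (is.null(group)) "all" else paste(group, collapse = "+")
  res$median_female <- stats::median(xf)
  res$median_male <- stats::median(xm)
  res
}

#' Correlate marker pairs with BH-adjusted Spearman tests
#'
#' Computes Spearman's rho for each measure pair, optionally separately per
#' sex, and adjusts the emitted family of p-values with
#' Benjamini-Hochberg. The family is exactly the set of rows returned.
#'
#' @param cohort cohort data.frame.
#' @param measurePairs list of length-2 character vectors, or a 2-column
#'   matrix/data.frame of measure names.
#' @param stratifyBySex compute each pair separately for women and men.
#' @param group optional restriction to clinical group(s).
#' @return data.frame with columns \code{measure_x}, \code{measure_y},
#'   \code{sex}, \code{n}, \code{rho}, \code{p}, \code{q}.
#' @export
correlateMarkers <- function(cohort, measurePairs, stratifyBySex = FALSE,
                             group = NULL) {
  if (is.matrix(measurePairs) || is.data.frame(measurePairs))
    measurePairs <- lapply(seq_len(nrow(measurePairs)), function(i)
      as.character(unlist(measurePairs[i, 1:2])))
  if (!is.list(measurePairs)) measurePairs <- list(measurePairs)
  sub <- if (is.null(group)) cohort else cohort[cohort$group %in% group, ]
  strata <- if (stratifyBySex) c("female", "male") else "all"
  rows <- list()
  for (pair in measurePairs) {
    pair <- as.character(unlist(pair))
    bad <- setdiff(pair, colnames(sub))
    if (length(bad))
      ssStop(sprintf("measure(s) not in cohort table: %s",
                     paste(bad, collapse = ", ")), "input")
    for (sx in strata) {
      d <- if (sx == "all") sub else sub[sub$sex == sx, ]
      r <- spearmanRho(d[[pair[1]]], d[[pair[2]]])
      rows[[length(rows) + 1L]] <-
        data.frame(measure_x = pair[1], measure_y = pair[2], sex = sx,
                   n = r$n, rho = r$statistic, p = r$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}
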