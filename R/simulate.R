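## Synthetic-data generators. Every generator is a pure function of its
## arguments and seed: the same call yields byte-identical output, and the
## output satisfies the type invariants of the consuming module.

#' Simulate a multi-study expression screen with spiked sex-biased genes
#'
#' Emulates the structure of the screened microarray studies: per study a
#' probes-by-samples log2 intensity matrix with 1-3 probes per gene, at
#' least ten samples per sex, ages uniform on the inclusion window and all
#' samples healthy. Gene-level values are Normal(baseline_g, noiseSd^2);
#' spiked genes receive a \code{log2fc} shift in female samples (same sign
#' in every study).
#'
#' @param nDatasets number of studies.
#' @param nGenes genes per study (all studies share the gene panel).
#' @param nSpiked number of spiked sex-biased genes.
#' @param log2fc effect size (log2 units) added to female samples of spiked
#'   genes; the default, with the default noise and sample size, mirrors
#'   the regime in which the consensus screen is expected to have high
#'   recall.
#' @param noiseSd residual standard deviation in log2 units.
#' @param nPerSex samples per sex per study.
#' @param spikeSign +1 (up in women) or -1, recycled over spiked genes.
#' @param ageRange inclusive age window for the simulated donors.
#' @param genes optional character vector of gene symbols to use as the
#'   panel (overrides \code{nGenes}).
#' @param spikedGenes optional symbols of the spiked genes (overrides
#'   \code{nSpiked}).
#' @param seed integer seed.
#' @return list with \code{datasets} (named list of
#'   \linkS4class{ExpressionDataset}) and \code{truth} (data.frame
#'   \code{gene}, \code{spiked}, \code{sign}).
#' @export
simExpressionStudies <- function(nDatasets = 3, nGenes = 1000,
                                 nSpiked = 20, log2fc = 1.0,
                                 noiseSd = 0.5, nPerSex = 15,
                                 spikeSign = 1, ageRange = c(17, 43),
                                 genes = NULL, spikedGenes = NULL,
                                 seed = 1) {
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(nGenes))
  nGenes <- length(genes)
  if (is.null(spikedGenes)) {
    if (nSpiked > nGenes)
      ssStop("more spiked genes than genes", "spec")
    spiked <- sort(sample(nGenes, nSpiked))
  } else {
    spiked <- match(spikedGenes, genes)
    if (anyNA(spiked))
      ssStop("spiked gene(s) not in the gene panel", "spec")
    spiked <- sort(spiked)
    nSpiked <- length(spiked)
  }
  sgn <- rep_len(spikeSign, nSpiked)
  baseline <- stats::runif(nGenes, 4, 12)
  effect <- numeric(nGenes)
  effect[spiked] <- log2fc * sgn
  datasets <- vector("list", nDatasets)
  names(datasets) <- sprintf("SIM%02d", seq_len(nDatasets))
  for (d in seq_len(nDatasets)) {
    nppg <- sample(1:3, nGenes, replace = TRUE)
    geneIdx <- rep(seq_len(nGenes), nppg)
    nProbes <- length(geneIdx)
    probeIds <- sprintf("%s_P%05d", names(datasets)[d], seq_len(nProbes))
    sex <- rep(c("female", "male"), each = nPerSex)
    nS <- 2 * nPerSex
    mu <- outer(baseline[geneIdx], rep(1, nS)) +
      outer(effect[geneIdx], as.numeric(sex == "female"))
    vals <- mu + matrix(stats::rnorm(nProbes * nS, 0, noiseSd),
                        nProbes, nS)
    sd <- data.frame(
      sample_id = sprintf("%s_S%03d", names(datasets)[d], seq_len(nS)),
      sex = sex,
      age = sample(ageRange[1]:ageRange[2], nS, replace = TRUE),
      health = "healthy")
    datasets[[d]] <- ExpressionDataset(
      vals, probeIds = probeIds, sampleData = sd,
      probeGene = genes[geneIdx], datasetId = names(datasets)[d])
  }
  truth <- data.frame(gene = genes,
                      spiked = seq_len(nGenes) %in% spiked,
                      sign = effect / ifelse(effect == 0, 1, abs(effect)),
                      stringsAsFactors = FALSE)
  list(datasets = datasets, truth = truth)
}

positiveTemplates <- function() c(
  "Expression of %s was markedly increased in activated lymphocytes from infected donors.",
  "We measured %s levels in peripheral blood and found an association with disease progression.",
  "Silencing of %s reduced cytokine secretion in vitro, consistent with a regulatory role.",
  "Surface staining revealed that %s marks a distinct memory subset in chronic infection.",
  "Serum concentrations of %s correlated with clinical outcome in the prospective cohort.",
  "A polymorphism near %s was associated with viral set point in the genome-wide analysis.")

negativeTemplates <- function() c(
  "The randomized trial compared early versus deferred therapy in %s cohorts across sites.",
  "Sequence context around the motif %s showed no enrichment in the promoter analysis.",
  "Participants were screened at the %s study site before enrolment into the vaccine arm.",
  "The probe set %s failed quality control and was excluded from downstream analysis.",
  "Intracellular camp and calcium signalling were unaffected by antagonist treatment in %s assays.",
  "No association with outcome was observed for the clinical score %s in either cohort.")

#' Simulate a gold-annotated abstract corpus for matcher benchmarking
#'
#' Positive abstracts each embed exactly one surface form of one panel gene
#' (gene and form sampled uniformly, including forms that the lexicon
#' blacklists -- real text does not respect a matcher's blacklist, so such
#' mentions are honest false negatives). Negative abstracts contain only
#' homonym distractors derived from panel forms: lower-case variants,
#' substring traps (the form flanked by letters), and token-scrambled
#' names; a small fraction (\code{homonymRate}) additionally carries a
#' genuine lexical homonym -- a panel surface form used in a non-gene sense
#' -- which no dictionary matcher can reject.
#'
#' @param lexicon a \linkS4class{GeneLexicon} (the gene panel).
#' @param nPositive,nNegative numbers of positive and negative abstracts.
#' @param homonymRate fraction of negative abstracts containing a genuine
#'   homonym of a panel form.
#' @param label corpus label.
#' @param seed integer seed.
#' @return list with \code{corpus} (an \linkS4class{AbstractCorpus}) and
#'   \code{gold} (data.frame \code{pmid}, \code{gene},
#'   \code{is_mentioned} covering every (gene, abstract) pair).
#' @export
simCorpus <- function(lexicon, nPositive = 1000, nNegative = 1000,
                      homonymRate = 0.005, label = "benchmark", seed = 1) {
  if (!length(lexicon@entries)) ssStop("lexicon is empty", "input")
  set.seed(seed)
  forms <- lexiconForms(lexicon, includeBlacklisted = TRUE)
  genes <- lexiconGenes(lexicon)
  posT <- positiveTemplates()
  negT <- negativeTemplates()

  n <- nPositive + nNegative
  pmid <- sprintf("PM%06d", seq_len(n))
  text <- character(n)
  mentioned <- character(n)  # gene truly mentioned, "" for none

  for (i in seq_len(nPositive)) {
    g <- sample(genes, 1)
    gf <- forms$form[forms$gene == g]
    f <- sample(gf, 1)
    text[i] <- sprintf(sample(posT, 1), f)
    mentioned[i] <- g
  }
  makeDistractor <- function() {
    f <- forms$form[sample(nrow(forms), 1)]
    kind <- sample(3, 1)
    if (grepl(" ", f)) {
      toks <- strsplit(f, "[ -]+")[[1]]
      paste(rev(toks), collapse = " ")
    } else if (kind == 1L) {
      tolower(f)
    } else if (kind == 2L) {
      paste0(sample(LETTERS, 1), f, sample(LETTERS, 1))
    } else {
      paste0(f, "X", sample(9, 1))
    }
  }
  for (i in nPositive + seq_len(nNegative)) {
    d <- makeDistractor()
    s <- sprintf(sample(negT, 1), d)
    if (stats::runif(1) < homonymRate) {
      ok <- forms$form[!forms$blacklisted & forms$type == "symbol"]
      hom <- sample(ok, 1)
      s <- paste(s, sprintf(
        "Samples were processed under protocol %s of the biobank.", hom))
    }
    text[i] <- s
  }
  ord <- sample(n)
  corpus <- AbstractCorpus(label, pmid[ord], text[ord])
  gold <- expand.grid(pmid = pmid, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gold$is_mentioned <- mentioned[match(gold$pmid, pmid)] == gold$gene
  list(corpus = corpus, gold = gold)
}

#' Simulate a long-format Cq table with a sex effect
#'
#' Reference-gene Cq values are Normal(refBaseline, 0.2^2) per sample;
#' target Cq values are Normal(baseline - sexEffectDCq * 1[female], 0.3^2);
#' technical duplicates add Normal(0, 0.1^2) jitter. With perfect
#' efficiency (E = 2) a sex effect of 1 cycle corresponds to a 2-fold
#' higher normalized quantity in women.
#'
#' @param nPerSex samples per sex (the validation design used 7 + 7).
#' @param targets target gene names.
#' @param referenceGenes housekeeping gene names.
#' @param sexEffectDCq cycles by which female target Cq is lowered; scalar
#'   or named per target.
#' @param baselineCq target baseline Cq (scalar or named per target).
#' @param refBaselineCq reference-gene baseline Cq.
#' @param nReplicates technical replicates per well.
#' @param seed integer seed.
#' @return list with \code{cq} (a \linkS4class{CqTable}) and \code{samples}
#'   (data.frame \code{sample_id}, \code{sex}).
#' @export
simCqTable <- function(nPerSex = 7, targets = c("DPP4", "FCGR1A", "SOCS3"),
                       referenceGenes = c("HPRT1", "HMBS"),
                       sexEffectDCq = 1.0, baselineCq = 25,
                       refBaselineCq = 20, nReplicates = 2, seed = 1) {
  if (!length(referenceGenes))
    ssStop("at least one reference gene is required", "spec")
  set.seed(seed)
  nS <- 2 * nPerSex
  sampleId <- sprintf("S%02d", seq_len(nS))
  sex <- rep(c("female", "male"), each = nPerSex)
  eff <- stats::setNames(rep_len(sexEffectDCq, length(targets)), targets)
  if (!is.null(names(sexEffectDCq)))
    eff[names(sexEffectDCq)] <- sexEffectDCq
  base <- stats::setNames(rep_len(baselineCq, length(targets)), targets)
  if (!is.null(names(baselineCq))) base[names(baselineCq)] <- baselineCq
  rows <- list()
  for (g in c(referenceGenes, targets)) {
    isRef <- g %in% referenceGenes
    mu <- if (isRef) stats::rnorm(nS, refBaselineCq, 0.2) else
      base[[g]] - eff[[g]] * (sex == "female") + stats::rnorm(nS, 0, 0.3)
    for (r in seq_len(nReplicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sampleId, gene = g, replicate = r,
        cq = mu + stats::rnorm(nS, 0, 0.1), stringsAsFactors = FALSE)
    }
  }
  cq <- CqTable(do.call(rbind, rows), referenceGenes = referenceGenes)
  list(cq = cq, samples = data.frame(sample_id = sampleId, sex = sex,
                                     stringsAsFactors = FALSE))
}

## Beta parameters with mean mu (on [0,1]) and concentration kappa.
betaShapes <- function(mu, kappa) c(mu * kappa, (1 - mu) * kappa)

## Normal-scores correction for pooled rank correlations in a group
## mixture. With group-specific marginal locations, the pooled Spearman of
## two markers has a between-group component on top of the within-group
## copula correlation. Approximating each marginal by a normal on its
## latent scale, pooled Pearson ~ (r + cov_g(a, b)) /
## sqrt((1 + var_g(a)) (1 + var_g(b))) for standardized group offsets a, b;
## we solve this for the within-group latent r that delivers the pooled
## target, and clamp to keep the latent covariance positive definite.
latentWithinRho <- function(rhoPooled, offA, offB, w) {
  tgt <- 2 * sin(pi * rhoPooled / 6)
  va <- sum(w * offA^2); vb <- sum(w * offB^2)
  cab <- sum(w * offA * offB)
  r <- tgt * sqrt((1 + va) * (1 + vb)) - cab
  max(-0.9, min(0.9, r))
}

#' Simulate a per-subject cohort table
#'
#' Emulates the validation cohort: healthy donors, HIV-1 controllers and
#' progressors with DPP4+ and CD38+ T-cell frequencies, CD4 counts and
#' viral loads. Frequencies follow Beta marginals and CD4 count/viral load
#' log-normal marginals scaled to the published group medians. Within each
#' sex, target Spearman correlations between \code{DPP4pos_CD4_pct} and the
#' progression markers -- defined over the pooled infected subjects
#' (controllers + progressors), the population on which the validation
#' correlations are computed -- are injected through a Gaussian copula.
#' Because the group-specific marginal locations themselves induce a
#' between-group correlation component, the within-group latent
#' correlation is set by a closed-form normal-scores correction so that
#' the pooled Spearman lands on the target (the latent Pearson for a
#' Spearman target rho is \code{2 sin(pi rho / 6)}; the correction adds
#' the group-offset covariance algebra). Healthy donors carry no CD4 count
#' or viral load.
#'
#' @param groupSizes named integer vector with entries
#'   \code{healthy_f}, \code{healthy_m}, \code{controller_f},
#'   \code{controller_m}, \code{progressor_f}, \code{progressor_m}.
#' @param dpp4Medians named list per group of c(female, male) median
#'   percentages for \code{DPP4pos_CD4_pct}.
#' @param rhoWomen,rhoMen target pooled Spearman correlations of
#'   \code{DPP4pos_CD4_pct} with \code{CD4_count}, \code{viral_load} and
#'   \code{CD38pos_CD4_pct} within each sex among infected subjects.
#' @param cd4Medians,vlMedians per-group c(female, male) medians of the
#'   log-normal CD4 count (cells/ul) and viral load (copies/ml) marginals.
#' @param sdlogCd4,sdlogVl log-scale standard deviations of the CD4 count
#'   and viral load marginals.
#' @param kappa Beta concentration of the frequency marginals.
#' @param seed integer seed.
#' @return cohort data.frame (see [readCohortTable()] for the layout).
#' @export
simCohort <- function(groupSizes = c(healthy_f = 10, healthy_m = 9,
                                     controller_f = 14, controller_m = 10,
                                     progressor_f = 19, progressor_m = 25),
                      dpp4Medians = list(healthy = c(90.9, 85.76),
                                         controller = c(84, 75.3),
                                         progressor = c(74.4, 74.4)),
                      rhoWomen = c(cd4 = 0.50, vl = -0.30, cd38 = 0.49),
                      rhoMen = c(cd4 = 0, vl = 0, cd38 = 0),
                      cd4Medians = list(controller = c(574, 631),
                                        progressor = c(327, 305)),
                      vlMedians = list(controller = c(2079, 2206),
                                       progressor = c(23298, 37057)),
                      sdlogCd4 = 0.35, sdlogVl = 1.0,
                      kappa = 60, seed = 1) {
  if (any(abs(c(rhoWomen, rhoMen)) >= 1))
    ssStop("target Spearman rho must lie in (-1, 1)", "spec")
  if (any(groupSizes < 1)) ssStop("group sizes must be >= 1", "spec")
  set.seed(seed)
  cd8Medians <- list(healthy = c(61.5, 55.5), controller = c(30, 30),
                     progressor = c(28, 28))
  plhiv <- c("controller", "progressor")

  ## per-sex latent covariance with mixture correction
  sigmaFor <- function(si, rho) {
    w <- vapply(plhiv, function(g)
      groupSizes[[paste0(g, "_", c("f", "m")[si])]], numeric(1))
    w <- w / sum(w)
    muD <- vapply(plhiv, function(g) dpp4Medians[[g]][si] / 100, numeric(1))
    sdD <- sqrt(muD * (1 - muD) / (kappa + 1))
    offD <- (muD - sum(w * muD)) / mean(sdD)
    logC <- vapply(plhiv, function(g) log(cd4Medians[[g]][si]), numeric(1))
    offC <- (logC - sum(w * logC)) / sdlogCd4
    logV <- vapply(plhiv, function(g) log(vlMedians[[g]][si]), numeric(1))
    offV <- (logV - sum(w * logV)) / sdlogVl
    off0 <- rep(0, length(plhiv))
    r <- c(latentWithinRho(rho[["cd4"]], offD, offC, w),
           latentWithinRho(rho[["vl"]], offD, offV, w),
           latentWithinRho(rho[["cd38"]], offD, off0, w))
    Sigma <- diag(4)
    Sigma[1, 2:4] <- Sigma[2:4, 1] <- r
    ## shrink towards independence if the single-factor structure is not PD
    while (min(eigen(Sigma, symmetric = TRUE,
                     only.values = TRUE)$values) <= 1e-8) {
      r <- 0.95 * r
      Sigma[1, 2:4] <- Sigma[2:4, 1] <- r
    }
    Sigma
  }
  SigmaBySex <- list(female = sigmaFor(1L, rhoWomen),
                     male = sigmaFor(2L, rhoMen))

  rows <- list()
  id <- 0L
  for (grp in c("healthy", "controller", "progressor")) {
    for (sx in c("female", "male")) {
      nk <- groupSizes[[paste0(grp, "_", substr(sx, 1, 1))]]
      si <- if (sx == "female") 1L else 2L
      z <- matrix(stats::rnorm(nk * 4), nk, 4) %*% chol(SigmaBySex[[sx]])
      u <- stats::pnorm(z)
      sh <- betaShapes(dpp4Medians[[grp]][si] / 100, kappa)
      dpp4cd4 <- 100 * stats::qbeta(u[, 1], sh[1], sh[2])
      if (grp == "healthy") {
        cd4 <- rep(NA_real_, nk); vl <- rep(NA_real_, nk)
      } else {
        cd4 <- stats::qlnorm(u[, 2], log(cd4Medians[[grp]][si]), sdlogCd4)
        vl <- stats::qlnorm(u[, 3], log(vlMedians[[grp]][si]), sdlogVl)
      }
      sh38 <- betaShapes(0.40, kappa)
      cd38cd4 <- 100 * stats::qbeta(u[, 4], sh38[1], sh38[2])
      sh8 <- betaShapes(cd8Medians[[grp]][si] / 100, kappa)
      dpp4cd8 <- 100 * stats::rbeta(nk, sh8[1], sh8[2])
      cd38cd8 <- 100 * stats::rbeta(nk, betaShapes(0.45, kappa)[1],
                                    betaShapes(0.45, kappa)[2])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("SUBJ%03d", id + seq_len(nk)),
        sex = sx, group = grp,
        DPP4pos_CD4_pct = dpp4cd4, DPP4pos_CD8_pct = dpp4cd8,
        CD38pos_CD4_pct = cd38cd4, CD38pos_CD8_pct = cd38cd8,
        CD4_count = cd4, viral_load = vl,
        stringsAsFactors = FALSE)
      id <- id + nk
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validateCohort(out)
  out
}
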