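---
title: "Methods: consensus screening, literature mining and validation statistics for sex-biased genes"
author: "sexscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus screening, literature mining and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscreen)
```

# Scope and model overview

sexscreen implements a discovery-to-validation pipeline for sex-biased
gene expression in peripheral blood. The guiding idea is that a sex bias
in lymphocyte biology should leave a reproducible trace in whole-blood
expression data from healthy donors, that the biologically relevant
subset of such genes can be ranked by how often they appear in the
literature of a disease area (here HIV and B/T-cell biology), and that
the top candidates can be validated with small-sample nonparametric
statistics on qPCR and flow-cytometry readouts. Each stage is an
exported, separately tested operation; `runPipeline()` chains them over
files.

# The expression screen

## Two-group model and moderated t

Within one study, each probe is modelled as log2 intensity with a mean
per sex and common within-group variance. The contrast is always
female minus male, so positive log fold changes mean higher expression in
women; this sign convention is fixed across every module and output.

Per-probe pooled variances $s^2_g$ on $d_g$ degrees of freedom are
shrunk towards a prior $(d_0, s_0^2)$ estimated across probes by the
method of moments on $z_g = \log s^2_g$. Writing
$e_g = z_g - \psi(d_g/2) + \log(d_g/2)$ (with $\psi$ the digamma
function), the excess spread
$\mathrm{var}(e) - \overline{\psi'(d_g/2)}$ determines $d_0$ through a
trigamma inversion, and $s_0^2$ follows from the mean of $e$. Using $e$
rather than raw $z$ makes the estimate correct when residual degrees of
freedom vary between probes (they do whenever values are missing); when
$d_g$ is constant the two formulations coincide. If the observed spread
of log variances does not exceed what sampling noise alone explains,
$d_0 = \infty$ and every probe is tested against the common variance
$s_0^2$ with a normal reference. The moderated statistic is

$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g},\qquad
  t_g = \frac{\mathrm{logFC}_g}{\sqrt{\tilde s^2_g (1/n_F + 1/n_M)}}
  \sim t_{d_0 + d_g}.$$

`moderatedTScreen()` accepts a `d0` override: `d0 = 0` reduces exactly to
the classical pooled two-sample *t* (the package's oracle-equivalence
test asserts agreement to 1e-12), and `d0 = Inf` makes the ranking of
$|t|$ equal to the ranking of $|\mathrm{logFC}|$ for balanced designs.

Numerical choices: the trigamma inversion uses a Newton iteration from
the starting point $0.5 + 1/y$ with closed-form asymptotes for extreme
arguments and a relative tolerance of 1e-10; p-values are clipped into
$(0, 1]$ at the smallest positive double; zero-variance probes are
retained (their shrunken variance is positive whenever $d_0 > 0$) and
flagged, and probes with fewer than two finite values per sex are
excluded per dataset with a warning.

## Inclusion filter, probe collapse, consensus rule

`filterSamples()` keeps healthy donors with known age in the inclusive
window 17–43 years and requires at least 10 donors per sex — the
eligibility rules of the screened cohorts; bounds and minimum are
arguments. Ages are integers (years); an unknown age excludes the
sample because eligibility cannot be established.

Probe-to-gene collapse keeps, per gene, the probe with the smallest
p-value; ties break by larger mean intensity, then lexicographic probe
id, making the reduction deterministic. A flag records when a sibling
probe disagreed in fold-change sign.

The consensus rule is: $p \le 0.05$ in **all** studies, $p \le 0.01$ in
at least two, and a strictly common fold-change sign; genes missing from
any study are ineligible because the all-studies clause presumes
measurability. Thresholds (`pLoose`, `pStrict`, `minStrict`) are
arguments; raw (unadjusted) per-study p-values enter the rule, which is
the convention the cross-study replication requirement itself protects.
Cross-study summary values are arithmetic means of p and logFC.

# Literature mining

## Dictionary construction

`loadHgncLexicon()` reads an HGNC-style nomenclature TSV and assembles,
per gene, the approved symbol and name plus alias and previous
symbols/names. Three blacklisting rules run automatically: forms shorter
than 2 characters; forms on a stop list of English-word/abbreviation
homonyms (`defaultStopWords()`, extendable); and forms shared by more
than one panel gene (warned about, since such a form cannot be
attributed). The matching mechanics are deliberately conservative,
because the design goal of the matcher is specificity against homonyms:

* symbol-like forms (no internal whitespace) match case-sensitively as
  whole tokens — both boundaries must be non-alphanumeric, so `DPP4`
  matches `(DPP4)` and `DPP4-positive` but not `ADPP4X`, and the
  stop-listed `CAMP` never fires on `cAMP signaling`;
* name-like forms (with whitespace) match case-insensitively with
  hyphen/whitespace interchange (`dipeptidyl peptidase 4` matches
  `Dipeptidyl-peptidase 4`);
* overlapping matches of one gene's forms are resolved longest-match
  first, then leftmost, so each text span counts at most once per gene.

Occurrence tables carry both the number of abstracts with at least one
mention (`abstract_count`, which drives candidate qualification) and the
total mention count.

## Benchmarking the matcher

`simCorpus()` produces a gold-annotated benchmark: positive abstracts
each embed exactly one surface form (sampled uniformly over the panel's
forms — including blacklisted ones, because real text does not respect a
matcher's blacklist, making those mentions honest false negatives);
negative abstracts contain only distractors derived from panel forms
(lower-cased symbols, symbols flanked by letters, token-scrambled
names), and a small fraction (0.5% by default) carries a genuine lexical
homonym that no dictionary matcher can reject. On the packaged 31-gene
panel this yields an expected miss rate near 2% (three of the panel's
~130 forms are auto-blacklisted) and a specificity within a fraction of
a percent of 1 — imperfect by construction, so the benchmark measures
something real. The panel file is synthetic (authored for this package,
labelled so in its filename); it mimics the HGNC column layout.

# Candidate integration

A consensus gene qualifies when it occurs at least once in the HIV
corpus and at least once in the B-cell or T-cell corpus; the `k = 3`
qualifiers with smallest cross-study mean p are selected, with ties
broken by larger $|\overline{\mathrm{logFC}}|$ then symbol.
Gene-set overlap uses the hypergeometric upper tail
$P(X \ge k)$ with BH adjustment across all categories of the supplied
collection; the default universe is the number of distinct genes in the
collection, overridable, since over-representation p-values are only
interpretable relative to a declared universe.

# qPCR quantification

`qbaseNRQ()` implements relative quantification with efficiency
correction and multi-reference normalization. Technical replicates are
averaged (replicates deviating more than 0.5 cycles from their replicate
mean are flagged; dropping them is opt-in). With the across-sample mean
Cq of each gene as calibrator,

$$\mathrm{RQ}(g,s) = E_g^{\overline{Cq}_g - Cq(g,s)},\qquad
  \mathrm{NRQ}(g,s) = \frac{\mathrm{RQ}(g,s)}
  {\left(\prod_{r \in \mathrm{refs}} \mathrm{RQ}(r,s)\right)^{1/|\mathrm{refs}|}}.$$

The mean-Cq calibrator makes the geometric mean of RQ across samples
exactly 1 per gene (asserted to 1e-9 in the tests), and adding a
constant to all Cq values of one gene leaves its NRQ unchanged.
Amplification efficiencies default to $E = 2.0$ (100% per cycle) with a
per-gene override, since efficiencies are rarely reported alongside Cq
tables; the calibrator is the mean across samples rather than a
designated control sample, so no sample choice influences the ratios.
Inter-run calibration and error propagation are out of scope.

# Cohort statistics

`mannWhitneyU()` computes U from pooled ranks. For tie-free samples with
$n_1 + n_2 \le 30$ (configurable) the p-value is exact: the full count
distribution of the rank sum is built by the shift recurrence (a DP over
ranks; counts stay below $2^{53}$ so doubles are exact), and the
one-sided p is the fraction of the $\binom{n_1+n_2}{n_1}$ assignments at
least as extreme; the two-sided p doubles the smaller tail, capped at 1.
Otherwise a normal approximation with tie correction and (default)
continuity correction is used; the tests pin it to within 0.01 of the
exact value at $n_1 = n_2 = 15$ and to `wilcox.test` under ties. The
unpaired rank-sum test is used for all group comparisons — the study
design has no pairing, so the signed-rank variant would not apply.
`compareBySex()` defaults to the one-sided alternative "greater in
women" because that is the direction the expression screen hypothesises.

`spearmanRho()` ranks with tie-averaging and uses the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ reference on $n - 2$ degrees of
freedom; $\rho = \pm 1$ yields a p bounded below by the smallest
positive double. `bhAdjust()` validates inputs in $(0,1]$ and applies
the standard step-up formula (via `stats::p.adjust`); each driver emits
its BH family as exactly the set of rows it returns, so the family is
always visible in the output.

# The synthetic-data module

The generators define the conditions under which the pipeline's
operating characteristics are demonstrated; all are pure functions of
their arguments and a seed.

* `simExpressionStudies()` — by default 3 studies, 1000 genes, 20 spiked
  at log2FC 1.0 (up in women), residual SD 0.5 log2 units, 15 donors per
  sex, 1–3 probes per gene, ages uniform on 17–43, all healthy. Under
  these conditions the consensus screen's mean recall is at least 0.9
  with false-discovery proportion at most 0.1 over 20 seeds, and under
  the null (no spike) it passes fewer than one gene on average — the
  joint three-study rule with sign consistency has a per-gene null rate
  around $10^{-4}$ even with the min-p probe collapse.
* `simCorpus()` — described above; 1000 positives + 1000 negatives by
  default.
* `simCqTable()` — the 7 + 7 validation design with two reference genes:
  reference Cq $\sim N(20, 0.2^2)$, target Cq baseline minus a
  1.0-cycle female effect plus $N(0, 0.3^2)$ noise, duplicate jitter
  $N(0, 0.1^2)$. At $E = 2$, a 1-cycle effect corresponds to a 2-fold
  NRQ ratio, which the simulation recovers within 20%.
* `simCohort()` — group sizes 10/9 (healthy F/M), 14/10 (controllers),
  19/25 (progressors); DPP4+CD4+ frequencies follow Beta marginals with
  concentration 60 matched to the published group medians (90.9/85.76
  healthy, 84/75.3 controllers, 74.4/74.4 progressors — no sex bias in
  progressors); CD4 counts and viral loads are log-normal around the
  published group medians. Spearman targets for DPP4+CD4+ vs CD4 count
  (0.50), viral load (−0.30) and CD4+CD38+ (0.49) in women — and ≈ 0 in
  men — are injected with a Gaussian copula. Copulas are used because a
  Spearman target survives monotone marginal transforms; the latent
  Pearson correlation is $2\sin(\pi\rho_s/6)$. One subtlety is handled
  in closed form: because the marginals differ by clinical group, the
  pooled (controllers + progressors) rank correlation contains a
  between-group component, so the within-group latent correlation is set
  by a normal-scores correction
  $r = \rho_{\mathrm{latent}}\sqrt{(1+\mathrm{var}_g a)(1+\mathrm{var}_g b)} - \mathrm{cov}_g(a,b)$
  for standardized group offsets $a, b$, clamped so the latent
  covariance stays positive definite. With this correction the pooled
  correlation among 33 simulated women lands within ±0.2 of the target
  in roughly 90% of seeds.

What the generators deliberately do **not** emulate: probe-level
microarray artifacts (background, batch, platform differences),
real-text linguistic variety beyond templated sentences and systematic
homonym families, qPCR inter-run drift, and flow-cytometry measurement
error models. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the statistical machinery under the
stated generative model, not robustness to all failure modes of real
data.

# Input formats and degenerate inputs

The series-matrix reader handles the `!Sample_*` header plus matrix
block dialect (gzip accepted), parses sex/age/health from
`!Sample_characteristics_ch1` key:value fields case-insensitively with
configurable keys, and applies the auto-log heuristic: if the 99th
percentile of values exceeds 50 the matrix is floored at 1,
log2-transformed and the transform recorded in the dataset's provenance.
When no health-like key exists in a series at all, samples are assumed
healthy (the common case for healthy-cohort series); an unrecognized
value maps to "other" and is excluded by the filter. Errors are classed
(format, consistency, metadata, eligibility, ...) so callers can react
programmatically; an unparseable sex names the offending sample.

MEDLINE parsing accepts `PMID-`/`TI  -`/`AB  -` fields with
continuation lines, concatenates title and abstract with a single
space, and keeps title-only records; a two-column TSV is accepted as a
lighter dialect. GMT parsing enforces ≥ 3 fields per line (error with
line number), deduplicates members and drops empty sets with a warning.

# Problem sizes used by the test suite

The packaged checks run at sizes chosen to make each property
demonstrable yet quick to verify: the matcher benchmark uses the full
2,000-abstract corpus; consensus parameter recovery uses 20 seeds of the
default 3 × 1000-gene design plus 20 null seeds; exhaustive
enumeration oracles cover all Mann-Whitney sample splits with
$n_1+n_2 \le 12$ and hypergeometric universes with $N \le 12$; the
file-based end-to-end screen uses three studies totalling 246 profiles
with 800 genes.

# Known limitations

* Reproducing the published candidate lists from the original public
  repositories requires downloading those datasets; the package reads
  them once local, but the exact screening-era software options are not
  recoverable, so such reproduction is best-effort by design.
* The matcher is dictionary-based by construction; it cannot
  disambiguate genuine homonyms in context (these appear in the
  benchmark as irreducible false positives) and does not attempt
  ML-based entity recognition.
* The moderated-t machinery covers the two-group contrast only; no
  covariates, batch terms or multi-factor designs.
* BH families are exactly the rows each driver call emits; combining
  results across calls changes the family and is the caller's
  responsibility.
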