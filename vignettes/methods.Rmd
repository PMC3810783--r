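---
title: "Models and methods in longevomics"
author: "longevomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in longevomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longevomics)
```

`longevomics` reimplements, as one tested toolkit, the chain of analyses
used in studies of lifespan-extending interventions in mouse cohorts:
lifespan statistics on survival tables, empirical-Bayes differential
expression on summarized array matrices, cross-experiment gene-set
concordance, ontology-term overrepresentation, and promoter-motif
enrichment. Every stage can be exercised end to end on synthetic inputs
with planted ground truth, so the statistical behaviour of the whole
pipeline — power, calibration, bookkeeping — is itself testable.

This vignette explains each model, its assumptions, the tunable
parameters and their defaults, the numerical choices made where the
design was genuinely open, and what the synthetic data do and do not
emulate.

## Lifespan statistics

Survival data live in a `SurvivalTable`: one row per animal with a group
label, a lifespan in days and an event flag (0 = right-censored).
`kmEstimate()` computes the product-limit (Kaplan-Meier) survival curve
per group (delegating to the `survival` package), and
`medianSurvival()` reads off the median using the convention *smallest
event time at which S(t) drops to 0.5 or below*; when censoring keeps
the curve above 0.5 the median is explicitly undefined (`NA`).
`percentChange()` converts two medians into the familiar
"+46%"-style contrast: $100\,(m_t - m_c)/m_c$, reported both raw and
rounded to the nearest integer. `logrankTest()` is the standard
two-group log-rank test (df = 1).

### The maximal-lifespan quantile test

Median contrasts miss effects confined to the tail of the lifespan
distribution. The Wang/Allison construction (`maxlifeQuantileTest()`)
compares, between two groups, the proportion of animals still alive at
the age at which only 10% of the *pooled* population remains alive:

1. pool all uncensored lifespans and take the empirical 90th percentile
   as the threshold age;
2. count per group how many animals lived *strictly* beyond it;
3. test the resulting 2x2 table with a two-sided Fisher exact test.

Numerical choices, each of which was open:

* **Quantile convention.** The pooled quantile is the order statistic at
  `ceiling(q * n)`. This is determinate under ties; interpolation-based
  definitions would make the "alive beyond" count depend on values that
  no animal attained.
* **Strictness.** "Alive beyond" means strictly greater than the
  threshold, matching the phrase "still alive at the age at which 10%
  remained alive". Ties at the threshold can therefore push the
  non-strict tail fraction above 10%, but the strict fraction never
  exceeds it.
* **Sidedness.** Fisher's test is two-sided (summation of tables no more
  probable than the observed one) — the conservative choice when only
  "p < 0.05" statements are available to compare against.
* **Censoring.** Censored animals have no realised lifespan and are
  excluded, with a warning that reports the count. With fewer than 10
  pooled animals the pooled quantile is too unstable and the function
  refuses.

Each group's own 90th-percentile lifespan and its percent change are
reported alongside, because "maximum lifespan increased by X%"
statements in the literature plausibly refer to that quantity; the
equivalence is not asserted anywhere in code.

## Differential expression

`ExpressionStudy` wraps a `SummarizedExperiment` whose single assay is a
probes-by-samples log2 matrix, with the probe-to-gene map in `rowData`
and the two-group design in `colData`. The pipeline (`runDE()`) is:

1. **Detection filter** (`detectionFilter()`): retain probes whose log2
   intensity exceeds a floor in at least `min_samples` samples (defaults
   `log2(64) = 6`, 1). This is a deliberate, configurable stand-in for
   probe-level present/absent detection calls, which require raw probe
   data that summarized matrices no longer carry.
2. **Moderated t** (`moderatedT()`): per-probe two-group contrast with
   empirical-Bayes variance shrinkage. Writing $s_g^2$ for the pooled
   sample variance on $d_g$ residual df, the posterior variance is
   $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and
   $t_g = \mathrm{log2fc}_g / (\tilde s_g \sqrt{1/n_a + 1/n_b})$ on
   $d_0 + d_g$ df. The hyperparameters $(d_0, s_0^2)$ are estimated by
   closed-form moment matching on the log sample variances (mean and
   excess variance of $\log s_g^2$ against digamma/trigamma moments,
   with a Newton inversion of the trigamma function). This is
   deterministic — no optimizer — and has two testable limits:
   $d_0 = 0$ reproduces the ordinary equal-variance t-test exactly, and
   $d_0 = \infty$ gives every probe the same denominator. When the
   observed log-variances are *under*-dispersed relative to the
   chi-square expectation, the excess-variance estimate is nonpositive
   and the prior df is set to infinity — complete shrinkage is the
   moment-matched answer there.
3. **FDR** (`bhAdjust()`): Benjamini-Hochberg across *all retained
   probes*, before any per-gene collapse, so the multiplicity family is
   the set of tests actually performed.
4. **Sibling-probe collapse** (`collapseProbes()`): arrays carry
   multiple probe sets per gene; one record per gene is kept — the
   minimum-p probe, ties broken by larger |log2fc|, then lexicographic
   probe id, so the result is a deterministic function of the input.
5. **Classification** (`classifyGenes()`): increased/decreased requires
   *jointly* q below the FDR cut (default 0.05) and linear fold change
   $2^{\mathrm{log2fc}}$ outside the [0.67, 1.50] dead zone. The
   alternative ordering (FDR cut first, FC as an afterthought when
   counting) changes nothing here because the rule is a pure
   conjunction.

## Cross-experiment concordance

`rankEnrichment()` asks whether a gene set sits systematically high or
low in another experiment's fold-change ranking, via a Wilcoxon
rank-sum comparison of member versus non-member scores. The exact
rank-sum distribution is used when the smaller group has at most 10
genes and the scores are tie-free; otherwise the normal approximation
with tie correction. The standardized statistic is signed (positive =
members high); p-values are two-sided by default, with one-sided
alternatives available. Set genes missing from an experiment's platform
are dropped per comparison and the surviving count reported. Ranking
ties are broken by gene id so every ranking is reproducible.

`concordanceScreen()` applies this over a panel of experiments and
tallies, per set, how many experiments are significant at `alpha` *with
the sign matching the set's declared direction* — the "significant in
k of m experiments" summary. `overlapCounts()` provides the
complementary Venn-region counts with hypergeometric overlap tests
against a stated universe.

## Term overrepresentation on an ontology DAG

`TermDAG` stores an acyclic child-to-parent term graph plus gene
annotations. Annotations are propagated to all ancestors at
construction time (the true-path rule), so a term's gene count is well
defined before any testing. `conditionalWalk()` then processes terms
children-before-parents: each term is tested with the upper
hypergeometric tail (`hypergeomTail()`), and when a parent is tested,
genes annotated to its already-significant direct children (raw
p < `alpha`) are removed from both the set count and the background
count — a parent is only called on signal its children do not already
explain. Child significance is judged at raw p (no FDR inside the
walk), matching the published conditional algorithm; a BH-adjusted
column over all tested terms is attached to the output for reporting.
Terms with fewer than 3 background carriers are skipped as untestable.
The background for these tests is, by design, the expressed genes not
themselves differentially expressed (`setBackground()`), plus the query
set itself.

## Promoter-motif scanning

A `PWMRecord` pairs a position frequency matrix (4 x L counts) with a
position weight matrix of per-column base *probabilities*:
$p_{b,j} = (c_{b,j} + \epsilon \pi_b) / (\sum_b c_{b,j} + \epsilon)$
with pseudocount $\epsilon = 0.25$ and uniform background $\pi$ by
default. A window's score is the sum of its per-position probabilities.
This probability-sum scheme is chosen because all scores are
nonnegative, which makes "score exceeds 80% of the motif's maximum
attainable score" well posed; log-odds scores can be negative, and a
fractional threshold on them is ill-defined. A range-normalized
threshold ((score - min)/(max - min)) is available via
`score_scale = "range"`. Motifs shorter than 4 bases are rejected at
construction, mirroring dictionary filters that exclude uninformative
sites.

`scanRegion()` slides every window of motif length over the requested
strands (both, by default — upstream regions have no preferred strand
for a double-stranded binding event). Masking is handled at the window
level: any window containing a lowercase (soft-masked) or `N`
(hard-masked) base is ineligible, excluded both from matching and from
the scanned-length covariate. A match requires the score to *strictly*
exceed `min_frac * maxScore` (default 0.80); overlapping matches all
count — occurrences, not a greedy tiling. `scanned_length` is the
number of eligible window start positions summed over scanned strands,
which is exactly the number of Bernoulli trials the enrichment model
below conditions on. `countTable()` assembles the per-(gene, motif)
count/length table for a whole dictionary.

## Semiparametric logistic motif enrichment

For each motif, `fitMotifModel()` fits

$$\mathrm{logit}\,P(y_g = 1) = \beta_0 + \beta_1 x_{1g} + s(x_{2g})$$

where $y_g$ indicates membership of gene $g$ in the target set (e.g.
the increased genes), $x_{1g}$ is the motif's occurrence count in
$g$'s upstream region, and $x_{2g}$ is the scanned length. The length
term matters because masking varies across promoters: without it, a
motif looks "enriched" in any set whose promoters merely have more
scannable sequence. The package demonstrates this in its test suite:
under a null with length confounded with membership, the adjusted
model holds its type-I error while the unadjusted model inflates it.

Numerical choices:

* $s(\cdot)$ is a natural cubic spline basis with fixed df = 4 and
  knots at quantiles of $x_2$. A fixed-df basis is chosen over
  penalized smoothing with data-driven smoothness selection because it
  is deterministic and cheap across a dictionary of hundreds of
  motifs; the df is exposed. When $x_2$ is constant the term drops and
  the fit provably reduces to plain logistic regression of $y$ on
  $x_1$; when the quantile knots degenerate (clumped length
  distributions) the basis falls back to a linear term, then to
  dropping $x_2$.
* The fit is iteratively reweighted least squares with a ridge of
  1e-8 on the normal equations, coefficient-change convergence at
  1e-10, at most 100 iterations. Complete separation (planted motifs
  in small balanced designs can separate perfectly) is flagged and the
  ridge-penalized fit reported with a warning rather than silently
  diverging.
* Enrichment is judged by the Wald Z for $\beta_1$, two-sided, with
  the direction carried separately as $\mathrm{sign}(\beta_1)$.
* `screenDictionary()` fits one model per motif and applies BH across
  *estimable* motifs only; a motif with all-zero counts has no
  estimable $\beta_1$ and is reported but excluded from the FDR
  family. Only genes in `union(target, background)` — the expressed
  genes — enter any model; the caller passes the background
  explicitly.

## Phenotype calculators

Small closed-form quantities defined once and tested: HOMA-IR =
glucose(mg/dl) x insulin(uU/ml) / 405; respiratory quotient
RQ = VCO2/VO2; tolerance-test curves as percent of baseline glucose;
and delta-delta-Ct qPCR fold induction. For the latter, replicate Ct
values are averaged per (sample, gene), normalized within-sample to
the reference gene (dCt), contrasted between conditions (ddCt), and
reported as $2^{-\Delta\Delta Ct}$ — the sign convention under which a
transcript that amplifies earlier (lower Ct) in treated samples yields
a fold greater than 1. Printed renderings of this formula often lose
the minus and the deltas to typography; the implementation follows the
standard relative-quantification method, which is also the only sign
convention consistent with strongly induced genes showing >1000-fold
values.

## The synthetic-data module

Every input the pipeline consumes can be generated with planted truth
from a seeded RNG; the generators are first-class, tested code.

* **Survival cohorts** (`genSurvivalCohort()`): lifespans are Gompertz,
  hazard $h(t) = r e^{\theta t}$ — the standard two-parameter rodent
  mortality law, with an interpretable baseline rate and age-acceleration
  knob; $\theta = 0$ recovers the exponential, which the tests verify by
  Kolmogorov-Smirnov. Demonstration cohort sizes (~40-108 per group)
  match the scale of real aging-cohort designs. Censoring is independent
  uniform truncation below the death time — the simplest non-informative
  mechanism.
* **Expression studies** (`genExpressionStudy()`): log2 matrices with
  per-gene baselines U(7, 12), iid Gaussian residuals, planted
  symmetric shifts, sibling probes that re-target host genes with
  distinct ids, and optionally a block of probes held below the
  detection floor in every sample so that detection-filter accounting
  can be planted exactly. Two noise regimes are used deliberately:
  sd = 0.25 for power/FDR characterization (a realistic per-probe
  noise for a 3-vs-3 design), and sd = 0.1 for bookkeeping mirrors,
  where the point is exact recovery of planted set sizes rather than
  detection difficulty — at any realistic noise the BH step admits
  about $\alpha \cdot R$ false calls by construction, which would blur
  exact set-size arithmetic no implementation could sharpen.
* **Promoters** (`genPromoterSet()`): iid background sequence, one
  contiguous soft-masked block per region covering the masked
  fraction, and motif instances sampled column-wise from the PWM
  planted at non-overlapping unmasked positions of target genes.
* **Ontology** (`genToyOntology()`): terms created in index order,
  each drawing parents among earlier terms — acyclic by construction,
  single root.
* **Ranked experiments** (`genRankedExperiment()`): background scores
  N(0, 1); members of a reference set are shifted by
  `concordance x direction` SD units. One SD per unit of concordance
  is the fixed scale: zero gives an exactly null list (verified by KS
  uniformity of downstream p-values), and 0.8 gives the strong-but-not
  -certain agreement regime used in the cross-experiment screens.
* **qPCR plates** (`genQpcrPlate()`): reference gene at Ct ~ 18, target
  genes offset by a baseline delta, planted log2 fold inductions as
  earlier amplification in treated samples, a per-sample loading offset
  (which the dCt normalization must cancel), and 0.05-cycle technical
  noise.

What the generators do *not* emulate — and therefore what passing tests
do not show about real data: array-specific artifacts (spatial effects,
probe sequence bias, RMA preprocessing), heavy-tailed or
variance-heterogeneous expression noise beyond what the shrinkage
estimator sees, realistic promoter composition (repeats, CpG islands,
codon structure), real ontology topologies, and inter-animal frailty
beyond the Gompertz law. Results on real data depend on those; the
synthetic suite establishes correctness of the statistics and the
plumbing, not biological generality.

## Orchestration and problem sizes

`runPipeline(pipelineConfig(seed, out_dir))` executes the stages in
dependency order (generation, lifespan statistics, DE, concordance,
term enrichment, motif scan, motif enrichment, phenotypes), writes
plain-text artifacts (TSV/GMT/FASTA/PFM/JSON) stamped with the seed and
a configuration hash, and is byte-identical under reruns of the same
configuration. Disabled upstream stages produce dependency errors that
name the missing stage. All readers report malformed lines with file
and line number; all writers round-trip losslessly (property-tested
with fuzzed tables).

Simulation sizes in the test suite were chosen to make Monte-Carlo
margins small relative to the thresholds being asserted while keeping
the suite quick: 200-300 replicates for power and null-calibration
checks, 20 seeds for DE recovery, 1000 random sequence/PWM pairs for
scanner-oracle equality, 500 motifs for screen-level type-I
calibration, and exhaustive Fisher-vs-enumeration agreement over all
2x2 tables with margins up to 18 plus a random sample of larger-margin
tables up to 30. The bookkeeping mirror runs at the full 45,101-probe
scale, which is cheap for a 6-sample design.

## Known limitations

* The moderated-t module fits a single two-group contrast; multi-factor
  designs are out of scope.
* The detection filter is a summarized-matrix surrogate; it cannot
  reproduce probe-level detection calls, only their accounting.
* The conditional walk conditions on *direct* significant children
  only, as the published algorithm does; deeper descendants influence a
  term only through propagation.
* Exact Wilcoxon enumeration is limited to small groups without ties;
  beyond that the tie-corrected normal approximation is used (the two
  agree to well under 0.01 by group size 30, which the tests assert).
* `percentChange()` uses standard rounding for its integer rendering;
  published integer percentages are not always internally consistent in
  their rounding convention, so the raw one-decimal value is the
  authoritative output.
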