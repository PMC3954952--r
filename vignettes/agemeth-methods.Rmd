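---
title: "Methods: two-group methylation analysis with agemeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-group methylation analysis with agemeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemeth)
```

# The problem

DNA methylation at CpG dinucleotides changes with age, and skeletal muscle
— a postmitotic tissue — shows a predominantly *hyper*methylated profile in
older adults. Array studies of this question share one design: beta values
(the methylated fraction of signal, in $(0,1)$) at hundreds of thousands of
CpG probes, measured in a young and an old group of roughly two dozen
samples each. `agemeth` packages the full downstream analysis of such a
design: calling differentially methylated CpGs (dmCpGs), locating them
relative to genomic features, relating per-gene methylation changes to
expression changes, and screening single probes as age classifiers. A
seeded generator produces synthetic studies with known ground truth so
every stage can be validated end to end.

# Models and procedures

## dmCpG calling

Betas are logit-transformed to M-values, $M = \log_2\!\big(\beta/(1-\beta)\big)$,
the variance-stabilized scale on which array methylation differences are
usually tested; betas are clipped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-6}$, so the transform stays finite. Each probe is
tested with a Welch (unequal-variance) two-sample $t$, signed old minus
young so a positive statistic means hypermethylation with age. Welch is
used rather than a pooled-variance or moderated test because group
variances on the M scale differ systematically with the mean, and at
$n = 24+24$ per-probe variance estimates are stable enough that shrinkage
buys little. The null simulations in the test suite confirm calibration:
the pooled fraction of raw $p \le 0.05$ over 20 replicates of 20,000 null
probes stays within $0.05 \pm 0.01$.

Multiple testing is controlled by Benjamini–Hochberg at $q = 0.05$
(configurable). A called probe's direction — hyper or hypo — comes from the
sign of the group-mean difference. Probes with any missing beta are dropped
with a count in the run summary; no imputation is attempted.

Degenerate probes (zero variance in both groups) are defined away rather
than propagated: equal means give $t = 0, p = 1$; unequal constant groups
are flagged and reported as infinitely significant separation.

## Region catalog and enrichment

All coordinates are 0-based and half-open internally (the BED convention);
GFF3 input is converted on read. The catalog holds, as merged interval
sets:

* **intragenic / intergenic** — the union of gene bodies and its
  complement; exhaustive and exclusive for every probe.
* **gene 5′/central/3′ segments** — each gene body split by configurable
  fractions (default equal thirds) following the direction of
  transcription; boundaries fall at
  $\lfloor \mathrm{cumfrac} \times L \rfloor$ bases from the 5′ end. Genes
  shorter than 3 bases cannot hold three segments and are labeled central
  and flagged. Equal thirds are a package decision: the fractions are the
  natural reading of "5′ / central / 3′" when no further definition is
  available, and they are exposed as a parameter.
* **TSS/TES windows** — $\pm w$ around the transcription start and end
  sites for each configured $w$ (defaults 200 and 1500, the array
  annotation convention), clipped at chromosome bounds. On the minus
  strand the TSS is the last transcribed base (`end - 1`).
* **CpG islands and shores** — islands are merged first; shores are the
  flanking 2000 bp on each side with island bases excised, so a shore base
  is never an island base even between close islands. Islands and shores
  are each crossed with promoter / intragenic / intergenic context.
* **promoter classes** — the $\pm 1500$ bp window around each TSS is
  classified by whether it overlaps (by at least one base) a CpG island
  and/or a GC-skew region, giving the four classes CGI±skew / noCGI±skew.
* **chromosomes** — every probe carries exactly one `chr:` category.

GC skew is computed per sliding window as $(G - C)/(G + C)$ (windows with
no G or C are undefined) and skew regions are maximal runs of at least
`min_run` windows with constant sign and $|skew| \ge$ threshold (defaults:
window 200, step 50, threshold 0.1, min_run 3). Precomputed skew intervals
can be supplied as BED instead of a FASTA, since published skew calls are
often the more reproducible input.

Enrichment per category is the observed/expected log2 ratio
$$\log_2 \frac{n^{dm}_{region} / n^{aCpG}_{region}}{n^{dm}_{total} / n^{aCpG}_{total}},$$
with a $-\infty$ sentinel when the region holds no dm probes (kept in
tables, dropped from plots). Significance is a two-sided exact
hypergeometric test — under the null the dm set is a uniform draw without
replacement from the array probes — summing the probabilities of all
outcomes no more likely than the one observed. The exact construction was
chosen because it is enumerable: the test suite checks every configuration
with a universe up to 12 against exhaustive subset enumeration. No
correction is applied across categories by default (per-category
$P < 0.05$ is the reporting convention mirrored here); a flag enables BH
across rows.

## Gene summaries and expression concordance

Probes are joined to genes through the catalog; per gene and per region
category (intragenic, the three segments, promoter, CGI-promoter) the
package counts hyper and hypo calls and total array probes. The
designation — hyper-only, hypo-only, mixed, none — is *per region*, so a
gene may be hyper-only intragenically while mixed elsewhere; this matches
the stratified way such results are reported. Minimum-count gene sets at
thresholds $\{1, 2, 4, 8, 16\}$ are cumulative (count $\ge k$), hence
nested; an exclusive-bin view can be derived by set difference if wanted.
Gene sets are cross-tabulated against expression-change labels
(`up`/`down`/`unchanged`); genes absent from the label file count as
unchanged with a logged warning, because an expression study that did not
report a gene is most often one that saw no change. Set overlaps are tested
with the upper-tail hypergeometric.

The per-gene correlation between dm counts and array-probe counts
(Pearson) is reported over genes with at least one intragenic dmCpG.

## Single-probe age classifier

Every probe is scored as a stepwise-constant (decision-stump) classifier:
the threshold is chosen among midpoints between consecutive sorted unique
values plus $\pm\infty$, with the direction (old-above / old-below)
minimizing training error. Ties are broken deterministically — lowest
threshold, then old-above — so results are bit-reproducible.
Misclassification is estimated by leave-one-out cross-validation: the
stump is refit on each $n-1$ subset and the held-out sample classified.
Leave-one-out was chosen over $k$-fold because it is deterministic (no
fold-seed ambiguity) and the fit is cheap at $n = 48$.

Two flags summarize the screen. A probe is a **universal separator** when
the two groups' raw value ranges do not overlap at all; it is
**high-probability** when its cross-validated error is at or below a bound
(default 0.05, about two of 48 samples — the quantitative stand-in for
"nearly complete separation"). Three numerical subtleties are documented
because they are easy to get wrong:

* Training error is always label-symmetric, but LOOCV is not *exactly*
  symmetric on probes whose best stump has error 0.5 — the fixed tie-break
  picks a side of an uninformative rule. Informative probes are unaffected.
* Midpoint thresholds are not equivariant under the (nonlinear) logit, so
  cross-validated error can differ slightly between the beta and M scales;
  training error and the separation flag cannot. The screen runs on
  M-values by default.
* Complete separation does not *logically* force zero LOOCV error — with a
  margin smaller than the within-group order-statistic gaps, a held-out
  extreme point can cross the refit threshold. At realistic margins (the
  planted separators in the generator) LOOCV is zero, and the test suite
  asserts exactly that.

# The synthetic-data generator

The generator's defaults are the study conditions the pipeline targets:
24 young vs 24 old samples; CpG islands at 60% of gene promoters; planted
dm probes split 92:8 hyper:hypo; a 0.2 beta-unit group-mean shift. Around
them sit package choices a methylation analyst would call realistic:

* **Toy genome** — 4 chromosomes of 1.5 Mb, 500 non-overlapping stranded
  genes of 2–8 kb with at least 4 kb between them, islands of 0.3–1.5 kb
  at exactly the configured fraction of promoters plus extra
  intra-/intergenic islands kept clear of all promoters (so the promoter
  fraction is forced by construction), GC-skew intervals at 40% of
  promoters. 20,000 probes, 35% inside islands, all at unique positions.
  These sizes keep per-gene probe counts (tens) in the same regime as a
  450K-style array while running in seconds.
* **Beta noise** — per-sample betas are beta-distributed around the
  probe's group mean with concentration 50 (per-sample SD ≈ 0.06 at
  mid-range betas), respecting the $(0,1)$ support. Baselines are bimodal:
  island probes center on 0.15, others on 0.80, drawn with concentration
  30. Group means are clipped to $[0.02, 0.98]$; planted effects that hit
  the clip are attenuated and flagged in the ground truth.
* **Within-gene clustering** — dm probes are selected by weighted sampling
  without replacement. Besides optional per-category bias multipliers
  (used to plant region enrichment), each gene carries a susceptibility
  factor (gamma, mean 1, shape 0.35) and a target segment whose probes get
  50× weight. Both components have mean one across genes, so
  category-level expected densities still track the configured bias; what
  they add is the empirical signature of aging-muscle data, where single
  genes carry dozens of same-direction sites concentrated in one region.
  Directions are drawn per gene by default (92% hyper), per probe
  optionally — the per-probe regime is the one whose realized hyper
  fraction is exactly binomial, and the direction-recovery acceptance test
  uses it for that reason.
* **Expression labels** — each gene's label follows the inverse
  methylation-expression rule with the 3′ exception: hypo genes tend
  `up`, hyper genes tend `down` unless the majority of their hyper sites
  sit in the 3′ segment, in which case `up`. The concordance probability
  is $1 - (1 - c_1)\rho^{k-1}$ with $c_1 = 0.6$, $\rho = 0.6$ for a gene
  with $k$ dm sites, so concordance strengthens with the number of sites;
  non-concordant genes are mostly `unchanged` (75%) rather than opposite.
  Genes without dm change with probability 0.05.
* **Seeding** — one master seed; each stage derives a child seed
  deterministically, so a genome can be held fixed while methylation
  replicates vary.

What the generator deliberately does **not** model: Infinium I/II probe
chemistry, batch and position effects, cell-type composition, sex
chromosomes, spatially autocorrelated methylation outside the planted
gene clustering, and measurement error in the expression labels. Passing
tests therefore demonstrate that the statistical machinery is correct and
calibrated under a clean version of the design — not that any particular
biological dataset would yield the same headline numbers. In particular
the classifier screen flags far more universal separators on default
synthetic data than a real cohort would show, because planted 0.2-beta
effects at noise SD ≈ 0.06 are generous by real-data standards.

# Problem sizes used in the checks

The packaged tests run the generator at 20,000 probes / 500 genes for the
statistical checks (type-I calibration over 20 null replicates, 92:8
direction recovery, 20 replicates of planted 4× 3′ bias, universal-probe
recovery, concordance pattern, byte-identical pipeline determinism), 100
random single-chromosome genomes of 20–50 kb against a per-base membership
oracle, exhaustive hypergeometric enumeration up to universe 12, and
exhaustive stump/LOOCV enumeration on matrices of up to 10 samples and 20
probes. These sizes were chosen so the whole suite completes in minutes
while leaving every tolerance binomially comfortable.

# Known limitations

* The enrichment test treats probes as exchangeable draws; it does not
  preserve the spatial autocorrelation of methylation along the genome, so
  on real data its p-values are anti-conservative for categories made of
  few long regions. A permutation scheme preserving probe adjacency would
  be the upgrade path.
* Gene models are single-isoform intervals; no liftover, no real array
  manifest parsing.
* The classifier is intentionally univariate — it screens probes, it does
  not build a multivariate age predictor.
* Expression labels are an input; the package does not call differential
  expression.

# A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1)
report <- run_pipeline(cfg, "agemeth_run")
# report.txt / report.json summarize: probes tested, dmCpGs called and the
# hyper fraction, enrichment rows, genes summarized, universal and
# high-probability probe counts.
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` reruns the
same computation from scratch (plus a matched null run and a planted-bias
run) and writes the headline quantities as JSON.
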