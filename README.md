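# agemeth

Differential DNA methylation and single-probe age classification for
two-group (young vs old) CpG methylation array studies.

Skeletal muscle and other tissues accumulate DNA methylation changes with
age; array studies of this question compare beta values — the methylated
fraction of signal at each CpG probe, β ∈ (0,1) — between a young and an
old cohort of a few dozen samples each. `agemeth` implements the complete
downstream analysis of that design for analysts who want every stage
scripted, seeded, and testable:

1. **dmCpG calling** — betas → M-values (`M = log2(β/(1−β))`), per-probe
   Welch *t* signed old − young (positive = hypermethylated with age),
   Benjamini–Hochberg control, directional calls.
2. **Region catalog & enrichment** — gene bodies split into 5′/central/3′
   segments along the direction of transcription, TSS/TES windows, CpG
   islands, 2 kb island shores, GC-skew intervals and the four promoter
   CGI-by-skew classes; per category the observed/expected ratio
   `log2((n_dm_region/n_aCpG_region)/(n_dm_total/n_aCpG_total))`
   with an exact two-sided hypergeometric test.
3. **Expression concordance** — per-gene, per-region dmCpG counts with
   hyper-only/hypo-only designations, nested minimum-count gene sets
   (≥1, 2, 4, 8, 16 sites), cross-tabulation against expression-change
   labels, upper-tail hypergeometric overlap tests.
4. **Age classifier screen** — every probe fit as a stepwise-constant
   (decision-stump) classifier with deterministic tie-breaking,
   misclassification estimated by leave-one-out cross-validation; flags
   for *universal separators* (the groups' value ranges do not overlap)
   and *high-probability predictors* (LOOCV error ≤ 0.05).
5. **Synthetic studies** — a seeded generator producing a toy annotated
   genome, a 24-vs-24 beta matrix with a planted 92:8 hyper:hypo split and
   within-gene site clustering, and expression labels following the
   inverse methylation–expression rule with the 3′-hypermethylation
   exception. Ground truth is returned, so recovery is measurable.

Standard formats are used at the boundaries: BED/GFF3 via `rtracklayer`,
FASTA via `Biostrings`, everything tabular as TSV.

## Worked example

```r
library(agemeth)
cfg <- pipeline_config(seed = 1)       # defaults: 24+24 samples, 20000 probes
report <- run_pipeline(cfg, "agemeth_run")
```

`agemeth_run/report.txt` from this exact call:

```
agemeth 0.1.0  (seed 1)
simulate : 20000 probes, 500 genes, 450 CGIs, 1000 planted dm (389 clipped)
call-dm  : 20000 tested, 1050 called (935 hyper / 115 hypo, hyper fraction 0.890)
annotate : 25 categories
enrich   : 75 rows
concord  : 500 genes summarized, 271 with intragenic dm, count correlation 0.355
classify : 423 universal separators, 613 high-probability predictors
```

Reading it: of 20,000 probes, 1,050 were called differentially methylated
at q ≤ 0.05, 89% hypermethylated with age — recovering the planted 92:8
split (the generator plants 1,000 dm probes; 389 had their 0.2-beta shift
attenuated at the (0.02, 0.98) mean clip). 271 genes carry at least one
intragenic dmCpG. The enrichment table from the same run shows the planted
spatial structure:

```
    category n_dm_in_region log2_ratio   p_value direction
         CGI            427     0.0497  3.47e-01      over
   CGI-shore            202     0.1194  1.84e-01      over
 gene-3prime            219     0.9067  7.08e-21      over
  intergenic            149    -2.0185 3.48e-196     under
  intragenic            901     1.0135 3.48e-196      over
```

dmCpGs concentrate inside genes (log2 ratio +1.01) and are depleted
intergenically (−2.02), because the generator's per-gene susceptibility
clusters differential sites within genes. Per-probe tables (`dm.tsv`,
`classifier.tsv`), gene summaries (`gene_dm.tsv`), the concordance
cross-tabulation (`concordance.tsv`) and the ground truth (`truth.tsv`)
are written alongside.

Individual stages are plain functions (`call_dmcpg()`,
`build_region_catalog()`, `assign_probe_categories()`,
`enrichment_table()`, `summarize_genes()`, `concordance_table()`,
`screen_probes()`) and accept data read from TSV/BED with the `read_*`
helpers, so real array exports can be substituted for any synthetic stage.
A thin command-line front end with the same stages as subcommands is
installed at `inst/cli/agemeth`.

## Vignette

`vignettes/agemeth-methods.Rmd` documents the models, the parameter
defaults and their rationale, the generator's design and what it does and
does not emulate, numerical edge cases (tie-breaking, clipping, degenerate
probes) and known limitations.
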