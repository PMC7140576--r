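---
title: "Detecting and classifying split-gene misannotations with splitgenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying split-gene misannotations with splitgenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitgenes)
```

## The problem

When several independent genome assemblies of one species (or of closely
related species) are annotated independently, the same locus is often modelled
differently: one annotation calls it a single gene while another calls it two
or more genes. These *split-gene misannotations* distort functional
prediction, expression estimates, and every downstream analysis keyed to gene
identifiers. `splitgenes` compares pairs of annotations to find such loci and
uses bulk RNA-seq evidence to decide which model — one merged gene or several
split genes — the data support.

The method has two stages.

### Stage 1: syntenic homology

Candidates come from sequence, not expression. Inputs are the two GFF3
annotations, whole-genome alignment blocks (nucmer `show-coords` output), and
all-by-all transcript BLAST hits in both directions, computed on the
representative transcript of each gene (the one with the longest total CDS;
ties break by lexicographic transcript ID so results are reproducible).

Hits are filtered to e-value < 1e-4, reduced to the best hit per gene pair
(smallest e-value, ties by aligned length), and required to fall inside a
syntenic block extended by ±500 kb on each side. "Inside" means the gene span
*overlaps* the extended block rather than being contained in it — genes
straddling a block edge should not silently vanish. Each query gene is then
classified as having none, a single, or multiple corresponding subject genes,
and the two BLAST directions are reconciled: a one-to-many relation (one
merged gene vs ≥ 2 split genes) is only kept when each of the multiple genes
points back *exclusively* to the single gene.

One-to-many relations contain both genuine split-gene candidates and tandem
duplicates. They are distinguished on the subject transcript: with L2 the
total aligned space (union of all hit intervals) and L1 the space covered by
two or more distinct query genes, tandem duplicates have large L1/L2 while
genuinely split genes align to disjoint regions. A candidate is kept when
L1/L2 < 0.1 (strictly). L2 is the union of aligned intervals, not the
min-to-max span; with gappy alignments a span-based denominator would
understate the overlap fraction.

Remaining candidacy filters: the split genes must be pairwise non-overlapping,
on the same strand, proximal (per-chromosome rank spread of at most five gene
models), and every involved gene — split and merged — must be expressed.
Failing candidates are retained in the output with per-filter flags rather
than dropped, so exclusion statistics stay computable; only fully passing
candidates are *testable*. Proximity is measured on genomic rank order rather
than on gene-identifier suffixes: identifier numbering conventions are
assembly-specific and fragile, whereas rank order is derivable from any
annotation.

### Stage 2: the M2f statistic

If the split annotation is correct, the component genes are distinct
transcription units and their expression should diverge across tissues; if
the merged annotation is correct, the "two genes" are fragments of one unit
and should co-vary. M2f ("mean two-fold expression change across tissues")
quantifies this:

1. Exon-level read counts are filtered (exons < 50 bp are removed — they
   cannot be quantified reliably with 50 bp reads) and normalized to TPM per
   library: each exon's count is divided by its length and the rates are
   rescaled to sum to 10^6.
2. A gene's expression per library is the arithmetic mean of its exons' TPM.
   Genes whose mean across libraries is below 0.01 TPM are treated as
   unexpressed. The floor is applied to the across-library mean (rather than
   per library) because candidacy requires the gene to be expressed in the
   dataset as a whole.
3. For a candidate set of k ≥ 2 genes, within each library the absolute log2
   fold change |log2((a + ε)/(b + ε))| is averaged over all unordered gene
   pairs; M2f is the flat mean of these values across libraries, with
   biological replicates entering as independent libraries.

Only the libraries of the genotype whose annotation holds the *split* models
are used: those are the expression patterns that drove that annotation, and
mixing genotypes would confound misannotation with genuine between-genotype
differential expression.

The pseudocount ε defaults to 0.01 TPM (the expression floor). Zero values in
individual libraries are common even for expressed genes, and a symmetric
additive pseudocount bounds the statistic without changing its ordering;
ε = 0 is supported and used by the closed-form tests. Genes that are entirely
unexpressed are excluded before M2f rather than patched by ε — handling them
inside the statistic introduces artifacts.

### Stage 3: empirical nulls and calls

M2f has no useful parametric null, so two are simulated from the data, after
removing every candidate gene:

* **Split null** ("really one gene"): 20% of the remaining genes with at
  least four exons are sampled without replacement and each is split at a
  uniformly random internal exon junction leaving at least two exons per
  side; each half's expression is the mean of its exons' TPM and the M2f of
  the two halves is recorded. The random split point is an exon *junction*,
  not a base-pair position: the four-exon eligibility rule only makes sense
  if each half keeps at least two exons, and the exon count data cannot
  support bisected exons.
* **Merged null** ("really two genes"): 30% of the remaining genes are
  sampled without replacement and each is paired with its adjacent upstream
  neighbor — the gene of next-lower rank on the same chromosome, in genome
  coordinates and ignoring strand, since coordinate adjacency is how merged
  misannotations arise physically. M2f is computed on the two original loci.
  Anchors without an eligible neighbor (rank 0, excluded, or unexpressed) are
  skipped and the realized sample size is reported.

The 90th percentile of the split null (`t_split`) and the 10th percentile of
the merged null (`t_merge`) become the decision thresholds, pooled across
annotations by default. Percentiles use linear interpolation between order
statistics (the quantile type-7 convention), stated explicitly because the
threshold values depend on it. A candidate with M2f > `t_split` is called
`split_supported`, M2f < `t_merge` is `merge_supported`, and anything between
— or exactly equal to a threshold — is `ambiguous`; the inequalities are
strict on both sides. When three annotations are available the calls for a
shared anchor gene from the two pairwise comparisons can be cross-tabulated
(`cross_compare`) and candidates corroborated across comparisons
(`corroborate`); the package reports both calls per anchor without forcing a
reconciliation, since a decisive call in one comparison does not overrule an
ambiguous one in the other.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_evalue` | 1e-4 | — | strict BLAST hit cutoff |
| `margin_bp` | 500000 | bp | syntenic block extension on each side |
| `window` | 5 | gene models | rank-proximity window for split genes |
| `tandem_max` | 0.1 | fraction | strict upper bound on L1/L2 |
| `min_exon_len` | 50 | bp | exons shorter than the read length are unreliable |
| `floor` | 0.01 | TPM | expression floor, mean across libraries |
| `epsilon` | 0.01 | TPM | M2f pseudocount, equal to the floor |
| `split_fraction` | 0.20 | fraction | genes sampled into the split null |
| `merged_fraction` | 0.30 | fraction | genes sampled into the merged null |
| `min_exons_for_split` | 4 | exons | eligibility for artificial splitting |

## The synthetic data generator

`fixture_config()` / `generate_annotation_pair()` / `generate_expression()`
fabricate a pair of annotations with known truth: one-to-one genes, tandem
duplicates (hits overlapping ≥ 10% of the subject's aligned space, by
construction), truly split and truly merged candidate loci, and geometry that
violates the strand or overlap filters. The expression model: every *true*
gene draws one per-tissue log2 profile — a shared baseline plus iid
per-tissue effects of sd σ/√2 — so any two distinct genes differ per tissue
by N(0, σ²) while all exons (and all misannotated fragments) of one true gene
share a profile exactly. Expected exon counts scale with exon length, and
observed counts are negative binomial (dispersion 0.1 by default, a standard
bulk RNA-seq noise level); replicates are iid given tissue. At σ = 0 every
expected fold change collapses to zero, which pins down the limiting
behavior of M2f.

The generator emulates the *statistical* structure the classifier relies on —
profile sharing within a true gene, divergence between distinct genes,
length-scaled counting noise — and deliberately not read-level reality:
no mapping bias, no isoform structure beyond one representative transcript,
no genotype-specific mapping artifacts, identical baseline abundance for all
genes. Passing recovery tests on fixtures therefore demonstrates that the
statistic and thresholds behave as designed under the assumed noise model,
not that real maize-scale annotations would yield any particular rate.

```{r example}
cfg <- fixture_config(n_one_to_one = 60, n_true_split = 25, n_true_merged = 25,
                      n_tissues = 10, n_replicates = 2, sigma = 1.5, seed = 1)
fx <- generate_annotation_pair(cfg)
ex <- generate_expression(fx)
res <- suppressWarnings(analyze_fixture(fx, ex))
res$thresholds
recovery_rates(res)
```

## Numerical and design notes

* Internal coordinates are 0-based half-open everywhere; GFF3, show-coords,
  and BLAST tables (all 1-based inclusive) are converted at the I/O boundary.
* Representative-transcript ties, hit-deduplication ties, and exon ordering
  all have deterministic tie-breaks, so identical inputs and seeds give
  byte-identical outputs.
* With small null samples `t_merge` can exceed `t_split`; the thresholds
  object warns, because in that regime no call is ambiguous and the two null
  hypotheses are not separated. The validation studies here use a few
  hundred null draws per annotation (20%/30% of roughly 800 background
  genes), which is enough for stable 10th/90th percentiles; `n` is always
  carried alongside each threshold.
* Candidates failing filters keep their per-filter flags; tandem ratio
  exactly 0.1, e-values exactly at the cutoff, exons of exactly 49 bp, and
  means exactly at the floor are all resolved by the strict-inequality
  conventions documented above and asserted in the tests.
* Degenerate inputs (empty hit tables, header-only coords files, all-zero
  libraries, genes losing all exons to the length filter) return empty or
  flagged results rather than errors; genuinely malformed inputs (orphan
  exons, unmapped transcript IDs, non-numeric coordinates) are hard errors
  naming the offending record.

## Validation workload sizes

The packaged tests and the acceptance script run a recovery study of 500
truly split plus 500 truly merged candidates over 800 background genes with
10 tissues × 2 replicates (matched-null thresholds computed from the same
data), plus a monotonicity sweep of 100 true-split candidates at each
divergence level σ ∈ {0, 0.5, 1, 2}. These sizes give stable medians and
percentile thresholds while keeping a full run in well under a minute on one
CPU.

## Known limitations

* Consistently misannotated loci (wrong in *all* annotations) are invisible:
  they look one-to-one.
* Genes annotated in only one genome cannot be tested.
* Candidates with unexpressed members are flagged untestable, not called.
* A multi-isoform gene whose predominant isoform is a truncation of the
  longest one can mimic a split gene; the nulls absorb part of this effect
  (simulated genes carry the same isoform mix as candidates) but not all.
* The tool flags and classifies; it does not rewrite GFF3 models. Candidate
  coordinates and calls are intended to feed manual curation.
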