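---
title: "Methods: QTL gene prioritization and the breed-group fixation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL gene prioritization and the breed-group fixation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixscreen)
```

`fixscreen` chains five stages: set algebra over trait–gene annotations,
interaction-network prioritization, differential-expression (DE)
integration, coding-effect annotation of SNPs, and a categorical
between-group fixation screen. This vignette records the model behind
each stage, the parameters that matter, the conventions and tie-breaks we
fixed where tools disagree, and what the synthetic-data generator does
and does not emulate.

## The scientific setting

The pipeline targets the milk-fat QTL problem in cattle: genes annotated
to milk fat yield (MFY) and fat percentage (MFP) are collected from a
QTLdb-style extract, narrowed to the ones that are both central in a
protein-interaction network and differentially expressed between a
high-fat and a low-fat breed, and finally their coding SNPs are screened
across two breed groups — high milk yield (8 animals) versus low milk
yield (6 animals) — for sites fixed in one group but variable in the
other. Such sites are the candidates for breed-differentiating causal
variants.

## Gene-set stage

Trait–gene extracts list one row per (gene, QTL) association, so genes
recur. `deduplicate_genes()` collapses to one record per identifier and
**merges** the trait sets. The source workflows say only that duplicates
were removed; we merge rather than keep-first because merging loses no
annotation and makes the result independent of row order. Gene identity
is the raw identifier string, case-sensitive; no symbol-to-ID mapping is
attempted, because silent symbol matching is a classic source of
phantom overlaps. `venn_counts()` is plain inclusion–exclusion;
`exclusive_trait_genes()` uses exact set equality (a gene annotated to
MFY, MFP *and* MY is not "MFY and MFP only").

## Network stage

`build_network()` thresholds a scored edge list at `min_score` (default
0.5, the conventional medium-confidence STRING cutoff, with millesimal
0–1000 scores auto-detected and rescaled), drops self-loops, and keeps
the maximum score over duplicate pairs. Isolated endpoints of dropped
edges are not retained: a gene enters the analysis only through a
retained interaction.

Centralities follow one fixed convention, because tools genuinely
differ here: degree is the unweighted incident-edge count, and
betweenness is **unnormalized shortest-path node betweenness on the
unweighted graph, endpoints excluded, each unordered pair counted
once** (a star's center scores `choose(n_leaves, 2)`; every leaf of a
tree scores 0). Confidence scores are used only for thresholding, never
as path weights — nothing in the source workflow weights paths. The
implementation delegates to igraph; the test suite checks it against an
exhaustive all-shortest-paths enumeration on sampled graphs of up to 8
nodes.

Hubs are the top `k_hub` (default 50) nodes by degree. "Bottleneck" is
ambiguous in the literature between a betweenness ranking and a
tree-based statistic computed on top of a degree cutoff; we rank by
betweenness with an **optional degree-percentile prefilter** (default
0.20: candidates must sit at or above the 80th percentile of degree,
computed with `stats::quantile()` type 7). This captures both readings:
`degree_prefilter = 1` (or `NULL`) is the pure betweenness ranking. The
exact tree-based bottleneck statistic is deliberately not implemented —
it is not described precisely enough in the sources we follow to clone
faithfully, and guessing would be worse than flagging.

All top-*k* selections sort descending with ties broken by gene
identifier ascending, so ranked lists are reproducible; how the original
analyses cut ties at rank 50 is unknowable, and any deterministic rule
is equally defensible. Hub and bottleneck lists are cut **before**
intersecting with the DE table (cut-then-intersect); the alternative
order is not distinguishable from the published counts.

## DE integration

`filter_de()` keeps rows with `p_value < alpha` (strict, matching the
usual "p < 0.05" phrasing; default `alpha = 0.05`) and
`|log2fc| >= min_abs_lfc` (default 0 — reference analyses of this kind
apply no fold-change cut to QTL genes). Raw p-values are the default
because the reference tables report raw p-values; a Benjamini–Hochberg
mode (`adjust = TRUE`) is provided but off by default. The DE model
itself (DESeq2 or similar) is consumed as a results table, never refit.
`integrate_de()` then restricts to the hub/bottleneck union and counts
directions by the sign of log2FC, with zero counted as neither.

## Variant annotation

Coordinates are 1-based inclusive throughout (VCF convention); interval
membership includes both boundaries. The SNP filter keeps sites whose
REF and every ALT are single bases; the quality filter is **strict**
(`qual > 20`), and sites with a missing QUAL pass it, because
caller-intersected exports often drop QUAL. Caller intersection keys on
(chrom, pos, ref, sorted ALT set): the same position with a different
alternate allele is a different variant. Multi-allelic SNPs are retained
through per-gene counting (the SNP vs biallelic-SNP distinction in the
summary table) but excluded from effect annotation and the fixation
screen, which are defined on biallelic sites.

`annotate_coding_effect()` replaces the usual SnpEff step with a
transparent codon-level annotator: one transcript per gene (the sources
report a single protein position per variant), CDS segments in genomic
order, minus-strand genes handled by complementing alleles and counting
CDS offsets from the 3′ genomic end. The affected codon is translated
with the standard nuclear code before and after substituting the
alternate base; a change to a stop is STOP_GAINED (never counted as
non-synonymous), a change from a stop is STOP_LOST, and positions
outside the CDS are NONCODING. The annotator validates the VCF REF
against the genome and errors on CDS lengths not divisible by three
rather than guessing a frame.

## The fixation screen

A group is **fixed** at a site when all of its called animals are
homozygous for the same allele *and* at least `min_called` animals are
called. A uniformly heterozygous group is not fixed — every fixed cell
in the reference pattern tables is homozygous, and heterozygous
uniformity is transient under Mendelian segregation anyway.
`min_called = 2` by default: the reference tables classify a column with
5 of 8 group members called, so the classifier must tolerate
missingness, but declaring fixation from a single animal is too weak.

**Variable** is judged against the other group's fixed homozygous
genotype and is allele-agnostic: an observed allele outside the declared
REF/ALT pair (the transcribed tables contain one such cell) still counts
as variable. The categories are purely categorical; no allele-frequency
test, FST or haplotype statistic is computed, because the rule being
reproduced is categorical, and dressing it in a test statistic would
change its meaning.

One transcribed column (ZBTB16 at 59,718,206) shows a low-yield animal
homozygous for the alternate allele inside the nominally fixed low-yield
group; under the stated rule that site is `VARIABLE_BOTH`, and the
package reports it as such rather than special-casing the column. The
discrepancy is asserted in the test suite as documented behaviour.

## The synthetic-data generator

The generator exists so every stage has inputs with known truth:

* `simulate_universe()` realizes the MFY/MFP Venn **exactly**
  (default 161/125/131, union 417), with other trait codes sprinkled at
  random.
* `simulate_network()` grows a preferential-attachment-style simple
  graph (default 403 nodes, 671 edges — the sparsity regime of the
  reference network) in which planted hubs receive a large attachment
  bonus, and scores are uniform on [0.5, 1].
* `simulate_de()` gives targets |log2FC| ~ Normal(2.5, 0.6) with random
  sign — the magnitude range of the reference DE table (|log2FC| ≈ 1–7)
  — and p-values uniform below 0.01; background genes get
  Normal(0, 0.4) and uniform p-values.
* `simulate_cohort()` writes an mRNA-sense CDS per gene into a random
  genome (so every planted codon is known by construction, independent
  of the annotator it is used to check), then plants biallelic missense
  SNPs whose genotypes realize each requested category for the default
  8-vs-6 cohort, mirroring the observed pattern counts (14 fixed-in-high,
  9 fixed-in-low, 1 variable-in-both). The reference allele is the fixed
  group's allele, genotypes are written unphased, and QUAL is always
  above 20. Missing calls are injected only on homozygous calls — a
  variable group always keeps a heterozygous carrier — and never push a
  group below `min_called`, so planted categories remain recoverable by
  design: with missingness, classification can degrade to
  `INSUFFICIENT_DATA` but never to a wrong informative category.

Each generator reseeds deterministically from `config$seed` (fixed
offsets per generator), so identical configs give byte-identical
outputs.

What the generator does **not** emulate: read-level data (no FASTQ,
coverage or base-quality model), linkage disequilibrium or demographic
structure between the planted sites, isoforms, indels, and caller
disagreement beyond what `intersect_callsets()` is tested with. Passing
recovery tests therefore demonstrates the correctness of the set
algebra, centrality conventions, coordinate/strand arithmetic and the
classification rule — not robustness to alignment or calling artefacts,
which are upstream of this package's scope.

## Problem sizes and runtime choices

The test suite and the acceptance script run everything at desk scale:
betweenness is cross-checked by exhaustive path enumeration on graphs of
at most 8 nodes; classifier and annotator recovery replay 20 simulated
cohorts of 10 planted sites each (8 genes on an 8 kb genome); the
network stage of the end-to-end test uses the full default 403/671
shape. Genome-scale quantities from the motivating analyses (tens of
millions of raw SNPs) require the original sequencing data and are out
of reach of — and out of scope for — a self-contained package; the
fixtures and simulators are the substitute evidence.

## Known limitations

* One transcript per gene; no splice, UTR or regulatory consequence
  classes.
* No statistical test of differentiation accompanies the categorical
  screen; a site can be "fixed vs variable" by drift in 14 animals.
* The degree-percentile prefilter interacts with `k_bottleneck`: with a
  small network the prefilter can leave fewer than `k` candidates, in
  which case fewer genes are returned (by design, never padded).
* Hand-transcribed fixture tables inherit any printing errors of their
  source; anomalies we detected are preserved and documented rather than
  corrected.
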