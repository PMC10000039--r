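# fixscreen

Candidate-gene prioritization and breed-group SNP fixation screening for
milk-fat quantitative trait loci (QTL).

Dairy breeds differ markedly in milk fat yield and percentage, and part of
that difference is expected to sit in coding variants of fat-QTL genes.
`fixscreen` implements, as a tested and reusable R pipeline, the inference
chain used to go from trait-gene annotation tables to a short list of
candidate causal variants:

1. **Set algebra over trait-gene annotations** — deduplicate QTLdb-style
   extracts, count fat-yield (MFY) vs fat-percentage (MFP) gene sets by
   inclusion–exclusion, and pull out genes exclusive to a trait
   combination.
2. **Interaction-network prioritization** — build a simple undirected
   graph from a STRING-style scored edge list (confidence ≥ 0.5 by
   default), then select *hub* genes (top *k* by degree) and *bottleneck*
   genes (top *k* by betweenness centrality, optionally restricted to the
   top 20% of the degree distribution). Betweenness is unnormalized
   shortest-path node betweenness on the unweighted graph, endpoints
   excluded, each unordered pair counted once.
3. **Differential-expression integration** — intersect a DESeq2-style
   results table (filtered at p < α, default 0.05) with the
   hub/bottleneck union to get the differentially expressed hub and
   bottleneck genes.
4. **Variant annotation** — read multi-sample VCFs, keep quality-passing
   SNPs (Q > 20, indels discarded), intersect callsets from independent
   callers on (chrom, pos, ref, alt-set), assign sites to gene intervals,
   and classify coding effects by strand-aware codon substitution and
   translation (NONSYNONYMOUS / SYNONYMOUS / STOP_GAINED / STOP_LOST /
   NONCODING).
5. **Fixation screen** — the headline classifier. For each biallelic
   nsSNP site, each breed group is summarized as *fixed* (all called
   animals homozygous for one allele, with at least `min_called = 2`
   animals called) or not, and the site is categorized:

   | category | rule |
   |---|---|
   | `FIXED_HIGH_VARIABLE_LOW` | high-yield group fixed, low-yield group carries a differing genotype |
   | `FIXED_LOW_VARIABLE_HIGH` | the mirror image |
   | `FIXED_BOTH_CONCORDANT` / `_DISCORDANT` | both groups fixed, same / different allele |
   | `VARIABLE_BOTH` | neither group fixed |
   | `INSUFFICIENT_DATA` | a group falls below `min_called` |

A synthetic-data generator (`simulate_universe()`, `simulate_network()`,
`simulate_de()`, `simulate_cohort()`) produces every input with known
ground truth — including a two-group cohort of 8 high-yield and 6
low-yield animals with planted per-site categories — so the whole chain
is testable without any external download. Machine-readable transcriptions
of the reference result tables ship in `inst/extdata/` and load via
`load_fixture()`.

## Worked example

Intersect the reference DE table with its hub/bottleneck lists, then
screen the fixed-in-high genotype matrix:

```r
library(fixscreen)

t1  <- load_fixture("table1")
pri <- list(hubs        = unique(t1$gene_id[t1$section == "hub"]),
            bottlenecks = unique(t1$gene_id[t1$section == "bottleneck"]))
de  <- unique(tibble::as_tibble(t1[, c("gene_id", "log2fc", "p_value")]))
tab <- integrate_de(pri, filter_de(de, alpha = 0.05))
glance(tab)
#> # A tibble: 1 × 6
#>   n_union n_hub n_bottleneck n_both  n_up n_down
#>     <int> <int>        <int>  <int> <int>  <int>
#> 1      25    17           18     10    11     14

report <- screen_fixation(load_fixture("table3"), load_fixture("group_map"))
report
#> <fixation_report> 14 sites
#>
#> FIXED_HIGH_VARIABLE_LOW
#>                      14
dplyr::count(tidy(report), gene)
#> # A tibble: 8 × 2
#>   gene        n
#>   <chr>   <int>
#> 1 ANK1        2
#> 2 CACNA1C     1
#> 3 GHR         2
#> 4 ITGA1       1
#> 5 LPIN1       3
#> 6 NT5E        2
#> 7 TLR4        2
#> 8 ZBTB16      1
```

The 25 differentially expressed hub/bottleneck genes (10 with both
characteristics) and the 14 sites fixed in the high-yield group across 8
genes are the pipeline's headline outputs. `autoplot()` methods draw the
degree–betweenness scatter, the volcano plot and the genotype-pattern
tile matrix; `run_pipeline(pipeline_config(...))` orchestrates all five
stages over files and writes the report TSVs.

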