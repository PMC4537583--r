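# tapasTS

Alternative splicing lets one gene encode several protein isoforms, but
almost none of the minor isoforms of a gene carry any functional
annotation. `tapasTS` is an R toolkit for finding the minor isoforms most
likely to matter — those whose expression over a developmental time
course *switches* away from the gene's dominant isoform — and for
characterising what they might do. It is aimed at people analysing
transcript-level expression over ordered conditions (developmental
stages, time courses) with standard genomics inputs: an FPKM matrix, GTF
transcript models, an OBO ontology with GAF annotations, and interaction
edge lists.

## The score at the core

For a primary isoform profile *p* and a minor isoform profile *q*
(non-negative vectors over *T* stages), let *s₁ ≥ s₂* be the singular
values of the 2 × *T* matrix stacking *p* over *q*. The Time-course
Switch score is

    TS = 2 (1 − s₁ / (s₁ + s₂)) = 2 s₂ / (s₁ + s₂)  ∈  [0, 1]

TS is 0 for proportional profiles, 1 for orthogonal equal-norm profiles,
and rises both with shape divergence and with magnitude balance — unlike
1 − Pearson, which ranks a flat, barely expressed isoform as maximally
"different". Genes whose primary–secondary pair scores TS > 0.5 are
called high-TS genes.

Around the score, the package provides:

* isoform designation (primary / secondary / minor) with the >1 FPKM
  multi-protein-gene filter;
* exon-gain and intron-retention classification between isoform pairs
  from GTF models, with conservation-index flagging;
* Resnik GO semantic similarity (term-level and gene-level) from
  OBO + GAF;
* **TAPAS** (Transcript Annotation Pipeline for Alternative Splicing):
  co-expression clustering around query isoforms (Pearson > 0.7),
  functional links via experimental PPIs, STRING scores (> 800) and GO
  similarity (> 6), and an average-similarity coherence filter (mean
  pairwise gene similarity ≥ 2.5 over the 20 closest annotated members);
* the accompanying statistics: one-sided Fisher and Mann–Whitney tests,
  Benjamini–Hochberg correction, GO enrichment with term-size filtering,
  TS permutation nulls, Euclidean-matched bias-control pairing and
  stratified enrichment;
* seeded synthetic-data generators for every input format, so the whole
  pipeline is testable offline.

## Worked example

Simulate a 30-gene developmental series with planted switches, designate
isoforms, and score them:

```r
library(tapasTS)

sim   <- simulate_expression(sim_config(n_genes = 30, noise_sigma = 0.3,
                                        seed = 42))
genes <- filter_multiprotein_genes(sim$matrix, sim$proteins)
res   <- ts_scores_for_genes(genes, sim$matrix)
head(res, 5)
#>   gene_id minor_transcript_id         ts is_high_ts
#> 1   G0001            TG0001.2 0.61593783       TRUE
#> 2   G0002            TG0002.2 0.25718640      FALSE
#> 3   G0003            TG0003.2 0.02947211      FALSE
#> 4   G0004            TG0004.3 0.18512460      FALSE
#> 5   G0005            TG0005.2 0.16270099      FALSE
sum(res$is_high_ts)
#> [1] 5
```

Each row scores one gene's primary–secondary pair: G0001's secondary
isoform diverges strongly in shape at comparable expression (TS = 0.62,
high-TS), G0003's is a near-replica of its primary (TS = 0.03).

Run TAPAS on a planted five-module scenario with three decoy queries:

```r
sc  <- simulate_tapas_scenario(seed = 7)
tap <- run_tapas(c(sc$queries, sc$decoys), sc$matrix, sc$net,
                 sc$dag, sc$ann)
tap
#> TAPAS result: 8 queries
#> verdict
#> discarded goss_pass    linked
#>         3         2         3
#> 15 functional edges
```

The five planted queries resolve — three through direct functional links
(experimental or STRING), two through the coherence fallback (mean member
similarity 2.81 ≥ 2.5) — and all three decoys are discarded. The
validation step confirms passed clusters sit far closer to their query
gene than size-matched random controls:

```r
validate_filtering(tap$clusters, goss_context(sc$dag, sc$ann),
                   n_random = 50, seed = 7)
#> TAPAS filtering validation (mean query-gene GOSS per cluster)
#>   median passed:    2.813
#>   median discarded: 0
#>   median random:    0
#>   one-sided Mann-Whitney p (passed > random): 7.8552e-07
```

A thin command-line wrapper for the common steps ships in
`inst/cli/tapas-ts.R` (subcommands `simulate`, `designate`, `score`,
`events`, `run`).

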