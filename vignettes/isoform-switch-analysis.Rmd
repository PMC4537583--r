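---
title: "Scoring isoform switches and inferring functional neighbourhoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring isoform switches and inferring functional neighbourhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapasTS)
```

## The problem

Most multi-isoform genes express one transcript — the *primary isoform*,
the one with the highest mean expression over a developmental time course —
far above the others. Whether any given *minor isoform* (a transcript
encoding a protein different from the primary's) does something
biologically distinct is rarely annotated anywhere. A useful expression
signal of distinct function is a *switch*: the minor isoform is expressed
at levels comparable to the primary but at different times. This package
scores that signal, classifies the splicing events behind it, and
characterises the functional neighbourhood of the interesting isoforms by
co-expression and functional links.

The motivating setting is bulk RNA-seq over an ordered developmental
series, such as the staged *Drosophila* embryo-to-adult series with
transcript-level FPKM quantification, but nothing in the package is
specific to fly: any transcript-by-stage expression matrix, transcript
models in GTF, an OBO ontology and a GAF annotation file will do.

## The TS score

For a primary profile $p$ and minor profile $q$ (two non-negative vectors
over $T$ stages), stack them into the $2 \times T$ matrix $X$ and take its
singular values $s_1 \ge s_2 \ge 0$:

$$ TS \;=\; 2\left(1 - \frac{s_1}{s_1 + s_2}\right) \;=\; \frac{2\,s_2}{s_1 + s_2} \in [0, 1]. $$

Proportional profiles give a rank-1 $X$, hence $TS = 0$; orthogonal
profiles of equal norm give $s_1 = s_2$, hence $TS = 1$. The score rises
both as the *shapes* diverge (at fixed norms, it is non-decreasing in the
sine of the angle between the profiles) and as the *magnitudes* balance
(at a fixed angle, non-decreasing in the norm ratio). That double
sensitivity is the point: a flat, lowly expressed minor isoform has a
maximally dissimilar *shape* (1 − Pearson can be large) yet is probably
noise, and the TS score correctly ranks it low because its magnitude is
negligible.

```{r ts-example}
primary <- c(9, 7, 3, 1, 0.5, 0.2)
switch_minor  <- c(0.3, 0.6, 2, 6, 8, 7)   # different peak, similar magnitude
replica_minor <- primary * 0.4             # same shape
flat_minor    <- rep(0.4, 6)               # low-level noise
c(switch = ts_score(primary, switch_minor),
  replica = ts_score(primary, replica_minor),
  noise = ts_score(primary, flat_minor))
```

Assumptions and numerical choices:

* Profiles enter **raw**, without log transform or per-row normalisation —
  a log transform would suppress exactly the magnitude sensitivity the
  score exists for. A `log1p` option is available but off by default.
* Stages are an ordered categorical axis; the score never interpolates
  in time. Permuting the stages of *both* rows together leaves TS
  unchanged.
* A pair in which both profiles are all-zero is a 0/0 and raises an
  error rather than returning 0 — silent zeros would hide upstream
  filtering mistakes. A single all-zero profile also errors (it should
  have been removed by the expression filter).
* A gene is called **high-TS** when the TS of its primary–secondary pair
  strictly exceeds 0.5. The threshold is a tunable argument; 0.5 marks
  the point where the shape difference is unambiguous while keeping a
  usefully large gene set. The gene-level score uses the
  primary–secondary pair; all primary–minor pairs can be scored with
  `pairs = "all"`.

## Designating isoforms

`filter_multiprotein_genes()` applies two filters before any scoring:
a transcript must exceed 1 FPKM in at least one stage (strict `>`), and a
gene must retain at least two transcripts with *distinct protein
sequences* (exact string equality of the supplied protein sequences; no
alignment-based fuzziness). Mean expression is the unweighted arithmetic
mean over all stages of the retained transcript's full profile. The
primary isoform is the transcript with the maximum mean (ties broken
lexicographically by transcript id, so results are reproducible); the
secondary is the highest-mean transcript with a different protein; minors
are all transcripts with a different protein. All retained transcripts
must have a protein key — a transcript without one is an input error, not
a silent skip.

## Splice events

Between a primary and a minor transcript model (1-based inclusive GTF
coordinates, kept that way everywhere):

* **exon gain** — a minor exon sharing no base with any primary exon;
* **intron retention** — a minor exon whose interval fully contains a
  primary intron (pure containment; the minor exon is not additionally
  required to reach both flanking exons). One minor exon can retain
  several introns.

Exon *loss* is the same classification with arguments swapped
(`symmetric = TRUE`). Events can be flagged against an exon
conservation-index table: exact coordinate match preferred, else the
maximal-overlap record, with `ci >= 5` as the default conserved call
(the CI distribution is bimodal and 5 separates the modes; both the
cutoff and the `>=` convention are configurable, and an event with no
record keeps `conserved = NA` rather than `FALSE`).

## GO semantic similarity

Resnik similarity with information content
$IC(t) = -\ln(n_t / N)$, where $n_t$ is the number of genes annotated to
$t$ after true-path propagation and $N$ the number of genes with at least
one annotation in the namespace. Design choices: natural log (with the
default cutoffs, a direct GO link at similarity > 6 requires a shared
term covering fewer than $e^{-6} \approx 0.25\%$ of the corpus, and the
fallback mean cutoff of 2.5 corresponds to $\approx 8\%$ — sensible
specificities for a corpus of order $10^4$ genes; the base is
configurable); only `is_a` edges are traversed; the corpus is the
annotated genes, not the genome, so IC is a probability within the corpus.
Term-pair similarity is the IC of the most informative common ancestor;
gene-pair similarity is the maximum over the genes' annotation term pairs
(computed equivalently as the max IC over the intersection of propagated
term sets). ND-evidence and NOT-qualified annotations are removed at
load time. Because absolute IC values are corpus-dependent, the 6 and
2.5 cutoffs are configuration, not constants.

## TAPAS

For each query isoform (typically the high-TS minors):

1. **Cluster** — all transcripts from *other* genes with Pearson
   correlation strictly above 0.7 to the query profile (raw FPKM,
   consistent with the TS choice). The query's own gene is never a
   member.
2. **Link** — a member gene is functionally linked to the query gene by
   an experimental interaction, a STRING score strictly above 800, or a
   gene-pair similarity strictly above 6. Any link makes the cluster
   `linked`.
3. **Fallback** — otherwise, take the `k = 20` closest member genes
   carrying GO terms ("closest" = highest correlation among members, not
   the whole transcriptome) and compute the mean pairwise gene-pair
   similarity over all unordered pairs, query gene excluded. Mean at or
   above 2.5 passes (`goss_pass`), below discards; fewer than two
   annotated members discards with reason "insufficient annotation".
   The boundary is inclusive (`>=`) by package convention and
   configurable.

Where several isoforms of one foreign gene pass the correlation cut, the
gene is counted once for similarity computations while the edge list
reports its best-correlated isoform. Functional links are reported
query–member only: the network's purpose is characterising the query
(member–member links would describe the module, not the isoform).

`validate_filtering()` checks the filter does what it should: the mean
similarity between member genes and the query's parent gene must be
higher for passed clusters than for size-matched random-membership
controls (seeded), summarised by group medians and a one-sided
Mann–Whitney p-value.

## The statistics harness

* `fisher_one_sided()` — hypergeometric upper tail (enrichment
  direction); empty margins give p = 1 with a warning.
* `mann_whitney_one_sided()` — exact enumeration for small untied
  samples (min(n, m) ≤ 8, n + m ≤ 20), else tie-corrected normal
  approximation without continuity correction, so identical samples give
  exactly 0.5.
* `bh_correct()` — step-up Benjamini–Hochberg.
* `go_enrichment()` — per-term one-sided Fisher on propagated
  annotations; terms with fewer than 10 background genes are not tested.
* `permute_ts_null()` — TS scores permuted across genes with event
  annotations fixed; empirical p is (r + 1)/(n + 1), never zero.
* `euclidean_match()` — each high-TS gene takes the unused control gene
  with the nearest gene-level (isoform-summed) profile; genes are
  processed in decreasing total expression (ties lexicographic), so the
  "iterative" pairing is deterministic. Distance ties go to the
  lexicographically first control.
* `stratified_enrichment()` — the same Fisher test inside a restricted
  universe (only singletons, domain genes removed, old genes only, ...),
  for confounder control.

## What the synthetic data does and does not emulate

`simulate_expression()` generates 30-stage series (the length of the
staged embryo→adult series it mimics) with Gaussian-bump primary
profiles — the simplest shape family that reproduces the "different shape
vs same shape" contrast — and three minor archetypes: `switch`
(well-separated bump, peak ratio 0.3–1.0), `replica` (scalar multiple,
ratio 0.05–0.5) and `noise` (flat, 0.5–2 FPKM). Noise is multiplicative
log-normal, preserving non-negativity and giving the magnitude-
proportional scatter typical of FPKM estimates. Primary peaks are drawn
log-uniformly from 20–200 FPKM. `simulate_gene_models()`,
`simulate_go()` and `simulate_network()` plant splice events, annotation
modules of exactly known IC, and interaction edges;
`simulate_tapas_scenario()` composes them into a five-module end-to-end
fixture with decoy queries.

What passing on these fixtures shows: the implementation computes the
intended quantities exactly (oracle agreement), and the method separates
planted signal from planted background under calibrated noise. What it
does **not** show: performance on real data, where profiles are not
single bumps, quantification error is correlated across isoforms of a
gene, annotation is biased toward well-studied genes, and interaction
networks have hubs. Absolute numbers (the fraction of high-TS genes, IC
cutoffs) transfer to real corpora only after recalibration.

Problem sizes used by the test-suite checks, chosen to make each
statistical property measurable while keeping the suite quick: 1000
random profile pairs for the TS oracle, 500 random gene models for the
event classifier, 100 random ontologies for the similarity oracle, 200
replicate seeds for permutation-p uniformity, and 100-gene expression
simulations for detection power.

## Known limitations

* The TS score is defined for a profile *pair*; there is no multi-row
  generalisation here, and comparisons beyond Pearson and Euclidean are
  left to the user.
* Alternative transcription initiation/termination events are not
  classified; only whole-exon gain and full intron retention are.
* `load_obo()` is a minimal OBO 1.2 reader (id/name/namespace/is_a/
  is_obsolete); relationship types other than `is_a` are ignored by
  design.
* Gene labels (essentiality, singleton status, domain content, age) are
  consumed as user-supplied tables; the package does not regenerate them
  from their source databases.
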