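Package: tapasTS
Title: Time-Course Switch Scores and Functional Neighbourhoods for
    Alternative Protein Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks minor protein isoforms of multi-protein genes by the
    divergence of their developmental expression profiles from the primary
    isoform, using a singular-value-decomposition based Time-course Switch
    (TS) score. Classifies exon-gain and intron-retention events between
    isoform pairs from transcript models, optionally filtered by exon
    conservation index. Computes Resnik GO semantic similarity between
    terms and genes, and runs the TAPAS algorithm, which builds
    co-expression clusters around query isoforms, attaches functional
    links from protein interactions, STRING scores and GO similarity, and
    applies an average-similarity coherence filter. Includes the
    enrichment and bias-control statistics used alongside these tools
    (one-sided Fisher and Mann-Whitney tests, Benjamini-Hochberg
    correction, TS-permutation nulls, Euclidean-matched gene pairing) and
    a synthetic-data generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
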