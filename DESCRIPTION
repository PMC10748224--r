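Package: hrrgcn
Title: Highest-Reciprocal-Rank Gene Co-Expression Networks with Markov
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene co-expression networks for staged bulk RNA-seq
    experiments using highest reciprocal rank (HRR) edge ranking on Pearson
    correlations, detects clusters with a from-scratch Markov Cluster
    Algorithm (MCL), filters clusters by hypergeometric annotation
    enrichment with Benjamini-Hochberg FDR control, merges clusters with
    similar stage-expression profiles into modules, ranks intramodular
    connectivity to call hub and key genes, and extracts transcription
    factor subnetworks around key genes. Includes a seeded synthetic
    staged-transcriptome generator with planted modules so the whole
    pipeline can be exercised and benchmarked without external data, plus
    2^-ddCt qPCR utilities for validating expression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
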